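#' Syndrome-stratified biomarker regression with IVW meta-analysis
#'
#' Fits, within each syndrome group (MCI, dementia), the ordinary
#' least-squares model `level ~ exposure + age_lp + lp_gap + apoe`
#' (exposure = sign-harmonised mLRR-Y, age at lumbar puncture, the
#' sampling-to-LP gap in years, and the APOE score), then pools the
#' per-group exposure effects with a fixed-effect inverse-variance
#' meta-analysis. Samples with an LP gap above `max_gap` years are
#' excluded up front.
#'
#' @param data Data frame with the analyte level, exposure and covariate
#'   columns plus a `syndrome` column.
#' @param analyte Name of the level column.
#' @param exposure Name of the (harmonised) exposure column.
#' @param groups Syndrome labels to stratify on.
#' @param max_gap Maximum sampling-to-LP gap (years).
#' @param covariates Covariate column names.
#' @return List with `per_group` (AssocResult rows) and `meta`
#'   (a `meta_result`).
#' @export
fit_biomarker <- function(data, analyte, exposure,
                          groups = c("MCI", "dementia"), max_gap = 5,
                          covariates = c("age_lp", "lp_gap", "apoe")) {
  data <- data[!is.na(data$lp_gap) & data$lp_gap <= max_gap, , drop = FALSE]
  rows <- lapply(groups, function(g) {
    sub <- data[data$syndrome == g, , drop = FALSE]
    use <- c(analyte, exposure, covariates)
    sub <- sub[stats::complete.cases(sub[use]), , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(empty_assoc_result("linear", analyte, g, "empty group"))
    }
    if (stats::sd(sub[[exposure]]) == 0) {
      stop("zero exposure variance in group ", g, call. = FALSE)
    }
    fml <- stats::reformulate(c(exposure, covariates), response = analyte)
    fit <- stats::lm(fml, data = sub)
    new_assoc_result("linear", analyte, g, fit, exposure, nrow(sub),
                     covariates)
  })
  per_group <- do.call(rbind, rows)
  meta <- ivw_meta(per_group$estimate, per_group$se, per_group$stratum)
  list(per_group = per_group, meta = meta)
}

#' Proteome-wide association scan
#'
#' One linear regression per analyte per fluid of protein level on the
#' exposure, adjusted for age at LP, the sampling-to-LP gap and APOE
#' score; the `"tau_adjusted"` variant additionally adjusts for CSF total
#' tau. Benjamini-Hochberg FDR is controlled within each fluid x variant
#' family, and the genomic-control inflation factor of the family's
#' z-scores is reported.
#'
#' @param panel Long protein table: `sample`, `fluid`, `analyte`, `level`.
#' @param covars Per-sample covariate table: `sample`, the exposure
#'   column, `age_lp`, `lp_gap`, `apoe`, and `csf_tau` for the adjusted
#'   variant.
#' @param exposure Name of the exposure column in `covars`.
#' @param variants Model variants to run.
#' @param min_obs Minimum observations per analyte; analytes below it are
#'   skipped and logged in the `"skipped"` attribute.
#' @return `ScanResult` data frame: `analyte`, `fluid`, `variant`, `n`,
#'   `beta`, `se`, `z`, `p`, `q`, with per-family inflation factors in
#'   attribute `"lambda"`.
#' @export
proteome_scan <- function(panel, covars, exposure = "loy_exposure",
                          variants = c("base", "tau_adjusted"),
                          min_obs = 10) {
  variants <- match.arg(variants, several.ok = TRUE)
  skipped <- character(0)
  res <- list()
  for (variant in variants) {
    covnames <- c("age_lp", "lp_gap", "apoe")
    if (variant == "tau_adjusted") covnames <- c(covnames, "csf_tau")
    for (fluid in unique(panel$fluid)) {
      pf <- panel[panel$fluid == fluid, , drop = FALSE]
      for (an in unique(pf$analyte)) {
        pa <- pf[pf$analyte == an, c("sample", "level"), drop = FALSE]
        d <- merge(pa, covars, by = "sample")
        d <- d[stats::complete.cases(d[c("level", exposure, covnames)]), ,
               drop = FALSE]
        if (nrow(d) < min_obs) {
          skipped <- c(skipped, sprintf("%s/%s/%s", fluid, an, variant))
          next
        }
        fit <- stats::lm(stats::reformulate(c(exposure, covnames),
                                            response = "level"), data = d)
        co <- summary(fit)$coefficients
        res[[length(res) + 1L]] <- data.frame(
          analyte = an, fluid = fluid, variant = variant, n = nrow(d),
          beta = co[exposure, 1], se = co[exposure, 2],
          z = co[exposure, 1] / co[exposure, 2], p = co[exposure, 4],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no analyte had enough observations",
                         call. = FALSE)
  out$q <- NA_real_
  lambda <- list()
  for (fluid in unique(out$fluid)) {
    for (variant in unique(out$variant)) {
      fam <- out$fluid == fluid & out$variant == variant
      if (!any(fam)) next
      out$q[fam] <- bh_fdr(out$p[fam])
      lambda[[paste(fluid, variant, sep = ".")]] <-
        inflation_lambda(out$z[fam])
    }
  }
  rownames(out) <- NULL
  attr(out, "lambda") <- unlist(lambda)
  attr(out, "skipped") <- skipped
  out
}

#' Genomic-control inflation factor of a set of z-scores
#'
#' `lambda = median(z^2) / qchisq(0.5, 1)`, the median chi-square
#' convention: under the null the squared z-scores are chi-square with
#' one degree of freedom, so lambda ~ 1; lambda > 1 indicates systematic
#' inflation of the test statistics.
#'
#' @param z Numeric vector of z-scores (at least 20 for a stable
#'   estimate; fewer triggers a warning).
#' @return The inflation factor.
#' @export
#' @examples
#' set.seed(1); inflation_lambda(rnorm(1000))
inflation_lambda <- function(z) {
  z <- z[!is.na(z)]
  if (length(z) == 0) stop("no z-scores provided", call. = FALSE)
  if (length(z) < 20) {
    warning("fewer than 20 z-scores; inflation estimate is unstable")
  }
  stats::median(z^2) / stats::qchisq(0.5, df = 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR-adjusted p-values (`stats::p.adjust(method = "BH")`),
#' validated to lie in \[0, 1\].
#'
#' @param p Numeric vector of p-values.
#' @return q-values, same length/order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
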