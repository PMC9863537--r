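#' APOE genotype score
#'
#' Codes an APOE genotype as a continuous score in \[-2, 2\]: each e2
#' allele contributes -1 and each e4 allele +1 (e3 is neutral), i.e.
#' `count(e4) - count(e2)`.
#'
#' @param genotype Character vector of genotypes like `"e3/e4"` (any
#'   separator of `/`, `|` or none; case-insensitive), or a 2-column
#'   matrix of alleles.
#' @return Integer vector of scores.
#' @export
#' @examples
#' apoe_score(c("e3/e3", "e2/e4", "e4/e4"))
apoe_score <- function(genotype) {
  if (is.matrix(genotype)) {
    genotype <- paste(genotype[, 1], genotype[, 2], sep = "/")
  }
  g <- gsub("[^0-9e]", "", tolower(genotype))
  alleles <- regmatches(g, gregexpr("e[0-9]", g))
  ok <- lengths(alleles) == 2 &
    vapply(alleles, function(a) all(a %in% c("e2", "e3", "e4")), TRUE)
  if (any(!ok)) {
    stop("unknown APOE genotype: ", genotype[!ok][1], call. = FALSE)
  }
  vapply(alleles, function(a) sum(a == "e4") - sum(a == "e2"), 0L)
}

new_assoc_result <- function(model, exposure, stratum, fit, term, n,
                             covariates, separation = FALSE) {
  co <- summary(fit)$coefficients
  if (!term %in% rownames(co)) {
    stop("term '", term, "' absent from fitted model", call. = FALSE)
  }
  est <- co[term, 1]
  se_col <- intersect(c("se(coef)", "Std. Error"), colnames(co))[1]
  se <- co[term, se_col]
  p <- co[term, ncol(co)]
  data.frame(model = model, exposure = exposure, stratum = stratum,
             n = n, estimate = est, se = se,
             ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
             z = est / se, p = p,
             covariates = paste(covariates, collapse = "+"),
             separation = separation,
             stringsAsFactors = FALSE)
}

empty_assoc_result <- function(model, exposure, stratum, reason) {
  data.frame(model = model, exposure = exposure, stratum = stratum,
             n = NA_integer_, estimate = NA_real_, se = NA_real_,
             ci_lo = NA_real_, ci_hi = NA_real_, z = NA_real_, p = NA_real_,
             covariates = reason, separation = FALSE,
             stringsAsFactors = FALSE)
}

#' Logistic case-control association model
#'
#' Maximum-likelihood logistic regression of a binary outcome on an
#' exposure plus covariates, the case-control arm of the association
#' suite. Effects are reported on the log-odds scale (`estimate`) with
#' Wald 95% CI; exponentiate for odds ratios. Quasi-separation is
#' detected from the glm warning and flagged in the `separation` column
#' rather than silently returned.
#'
#' @param data Data frame containing all model columns.
#' @param exposure Name of the exposure column. If it is an mLRR-Y
#'   variable it must already be sign-harmonised (see
#'   [harmonise_mlrry()]).
#' @param outcome Name of the binary outcome column (0/1).
#' @param covariates Covariate column names.
#' @param pcs Optional PC column names to screen with [select_pcs()].
#' @param pc_threshold Selection p-value threshold for PCs.
#' @param age_window Optional length-2 age interval applied to `data$age`.
#' @param model,stratum Labels copied into the result row.
#' @return One-row `AssocResult` data frame.
#' @export
fit_case_control <- function(data, exposure, outcome = "ad",
                             covariates = c("age", "apoe"), pcs = NULL,
                             pc_threshold = 0.05, age_window = NULL,
                             model = "logistic", stratum = "all") {
  if (!is.null(age_window)) {
    data <- data[data$age >= age_window[1] & data$age <= age_window[2], ,
                 drop = FALSE]
  }
  use <- c(outcome, exposure, covariates, pcs)
  data <- data[stats::complete.cases(data[use]), use, drop = FALSE]
  if (nrow(data) == 0L || length(unique(data[[outcome]])) < 2) {
    return(empty_assoc_result(model, exposure, stratum,
                              "empty or degenerate stratum"))
  }
  if (!is.null(pcs) && length(pcs)) {
    pcs <- select_pcs(data[pcs], data[[outcome]], threshold = pc_threshold)
  }
  fml <- stats::reformulate(c(exposure, covariates, pcs),
                            response = outcome)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  # quasi-separated fits also show fitted probabilities pinned at 0/1
  eps <- 1e-10
  if (any(fit$fitted.values < eps) || any(fit$fitted.values > 1 - eps)) {
    separation <- TRUE
  }
  new_assoc_result(model, exposure, stratum, fit, exposure, nrow(data),
                   c(covariates, pcs), separation)
}

#' Cox model of MCI phenoconversion
#'
#' Cox proportional-hazards partial likelihood (Breslow tie handling) for
#' conversion from mild cognitive impairment to all-cause dementia or to
#' AD. In the AD-specific model, converters to non-AD dementia are
#' censored at their conversion time. Effects are on the log-hazard
#' scale; exponentiate for hazard ratios.
#'
#' @param data Data frame with `time`, event columns, exposure and
#'   covariates.
#' @param exposure Exposure column name (sign-harmonised when mLRR-Y).
#' @param outcome `"dementia"` (all-cause) or `"ad"`.
#' @param covariates Covariate column names.
#' @param event_dementia,event_ad Names of the logical event columns.
#' @param time Name of the follow-up time column (years).
#' @param model,stratum Labels for the result row.
#' @return One-row `AssocResult` data frame.
#' @export
fit_conversion <- function(data, exposure, outcome = c("dementia", "ad"),
                           covariates = c("age", "apoe", "cohort"),
                           event_dementia = "event_dementia",
                           event_ad = "event_ad", time = "time",
                           pcs = NULL, pc_threshold = 0.05,
                           model = "cox", stratum = "all") {
  outcome <- match.arg(outcome)
  event <- if (outcome == "dementia") data[[event_dementia]]
    else data[[event_ad]]
  use <- c(time, exposure, covariates, pcs)
  keep <- stats::complete.cases(data[use]) & !is.na(event)
  data <- data[keep, , drop = FALSE]
  event <- event[keep]
  if (nrow(data) == 0L) {
    return(empty_assoc_result(paste0("cox_", outcome), exposure, stratum,
                              "empty stratum"))
  }
  if (any(data[[time]] <= 0)) stop("follow-up times must be positive",
                                   call. = FALSE)
  if (sum(event) == 0) stop("no events in stratum; cannot fit Cox model",
                            call. = FALSE)
  # drop constant covariates (e.g. single-cohort strata)
  covariates <- covariates[vapply(covariates, function(v)
    length(unique(data[[v]])) > 1, TRUE)]
  if (!is.null(pcs) && length(pcs)) {
    pcs <- select_pcs(data[pcs],
                      survival::Surv(data[[time]], event),
                      threshold = pc_threshold)
    covariates <- c(covariates, pcs)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", event) ~ ",
    paste(c(exposure, covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "breslow")
  new_assoc_result(paste0("cox_", outcome), exposure, stratum, fit,
                   exposure, nrow(data), covariates)
}

#' Distribution tests for mLRR-Y between groups
#'
#' An unadjusted two-sample Kolmogorov-Smirnov test of the exposure
#' between two groups plus an analysis of covariance: the F test of the
#' group factor in `x ~ group + age + apoe`.
#'
#' @param x Numeric exposure (e.g. mLRR-Y).
#' @param group Two-level grouping (e.g. case/control).
#' @param age,apoe Covariates for the ANCOVA.
#' @return List with `ks_D`, `ks_p`, `ancova_F`, `ancova_p`.
#' @export
distribution_tests <- function(x, group, age, apoe) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) {
    stop("exactly two groups are required", call. = FALSE)
  }
  if (any(table(group) < 3)) {
    stop("each group needs at least 3 samples", call. = FALSE)
  }
  g <- levels(droplevels(group))
  ks <- suppressWarnings(stats::ks.test(x[group == g[1]],
                                        x[group == g[2]]))
  full <- stats::lm(x ~ group + age + apoe)
  red <- stats::lm(x ~ age + apoe)
  an <- stats::anova(red, full)
  list(ks_D = unname(ks$statistic), ks_p = ks$p.value,
       ancova_F = an$F[2], ancova_p = an$`Pr(>F)`[2])
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools stratum estimates with weights `w_i = 1/SE_i^2`:
#' `pooled = sum(w_i b_i) / sum(w_i)`, `SE = 1/sqrt(sum(w_i))`. A
#' Cochran's Q heterogeneity statistic is reported as a note.
#'
#' @param estimates Numeric vector of stratum effects (common scale).
#' @param ses Standard errors (all > 0).
#' @param labels Optional stratum labels.
#' @return List of class `meta_result`: `estimate`, `se`, `z`, `p`,
#'   `ci_lo`, `ci_hi`, `weights`, `q`, `q_p`, `n_strata`.
#' @export
#' @examples
#' ivw_meta(c(1, 3), c(1, 1))$estimate  # 2
ivw_meta <- function(estimates, ses, labels = NULL) {
  stopifnot(length(estimates) == length(ses))
  keep <- !is.na(estimates) & !is.na(ses)
  estimates <- estimates[keep]; ses <- ses[keep]
  if (length(estimates) < 2) {
    stop("at least two strata are required for meta-analysis",
         call. = FALSE)
  }
  if (any(ses <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (estimates - est)^2)
  out <- list(estimate = est, se = se, z = est / se,
              p = 2 * stats::pnorm(-abs(est / se)),
              ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
              weights = stats::setNames(w, labels),
              q = q, q_p = stats::pchisq(q, length(estimates) - 1,
                                         lower.tail = FALSE),
              n_strata = length(estimates))
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW fixed-effect meta: estimate %.4f (SE %.4f), p = %.3g\n",
              x$estimate, x$se, x$p))
  cat(sprintf("  %d strata, Q = %.2f (p = %.3g)\n", x$n_strata, x$q, x$q_p))
  invisible(x)
}

#' Select population-structure PCs relevant to an outcome
#'
#' Keeps the principal components whose marginal association with the
#' outcome reaches `p < threshold` (logistic for a binary outcome, Cox
#' for a `Surv` object, linear otherwise), mirroring the convention of
#' only adjusting by the PCs associated with the dependent variable.
#'
#' @param pcs Data frame or matrix of candidate PCs.
#' @param outcome Outcome vector or `survival::Surv` object.
#' @param threshold Marginal p-value threshold.
#' @return Character vector of selected PC names, with the marginal
#'   p-values in the `"p_values"` attribute.
#' @export
select_pcs <- function(pcs, outcome, threshold = 0.05) {
  pcs <- as.data.frame(pcs)
  binary <- !survival::is.Surv(outcome) &&
    length(unique(outcome[!is.na(outcome)])) == 2
  pv <- vapply(pcs, function(pc) {
    if (survival::is.Surv(outcome)) {
      fit <- survival::coxph(outcome ~ pc, ties = "breslow")
      summary(fit)$coefficients[1, "Pr(>|z|)"]
    } else if (binary) {
      fit <- stats::glm(outcome ~ pc, family = stats::binomial())
      summary(fit)$coefficients["pc", 4]
    } else {
      fit <- stats::lm(outcome ~ pc)
      summary(fit)$coefficients["pc", 4]
    }
  }, 0)
  sel <- names(pcs)[pv < threshold]
  attr(sel, "p_values") <- pv
  sel
}
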