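#' Run the full Mendelian-randomisation association grid
#'
#' Produces one tidy table covering the whole analysis design:
#' \itemize{
#'   \item mLOY phenotype exposures (sign-harmonised mLRR-Y and mLOY
#'     calls) against AD case-control status in men — all men, the 65-85
#'     window, the four 5-year age bands, and an IVW META row over the
#'     bands — and against MCI-to-dementia / MCI-to-AD conversion in men;
#'   \item the polygenic-score exposure against the same outcomes in the
#'     three sex strata (all, men, women).
#' }
#' Logistic models adjust for age, APOE and the screened PCs; Cox models
#' adjust for age, APOE, cohort ascertainment and screened PCs
#' (per-stratum screening via [select_pcs()]). Strata that are empty or
#' that fail to fit are emitted as rows with missing estimates and the
#' reason in the `covariates` field, so the grid shape is stable.
#'
#' @param pheno Phenotype table (needs `sample`, `male`, `age`, `apoe`,
#'   `ad`, `mci`, `time`, `event_dementia`, `event_ad`, `cohort`, PCs).
#' @param prs Optional `prs_vector` (or data frame `sample`, `std`).
#' @param calls Optional `mloy_calls`; anomaly-flagged samples are
#'   excluded from the phenotype-exposure models.
#' @param age_window Age window for the windowed/banded strata.
#' @param age_bands List of length-2 band intervals.
#' @param pcs PC column names to screen.
#' @return Data frame of `AssocResult` rows (one per model).
#' @export
run_mr_suite <- function(pheno, prs = NULL, calls = NULL,
                         age_window = c(65, 85),
                         age_bands = list(c(65, 70), c(70, 75),
                                          c(75, 80), c(80, 85)),
                         pcs = c("pc1", "pc2")) {
  rows <- list()
  add <- function(row) rows[[length(rows) + 1L]] <<- row
  try_fit <- function(expr, model, exposure, stratum) {
    tryCatch(expr, error = function(e) {
      empty_assoc_result(model, exposure, stratum, conditionMessage(e))
    })
  }

  dat <- pheno
  if (!is.null(calls)) {
    cal <- calls[is.na(calls$anomaly),
                 c("sample", "mlrry", "mloy_call")]
    dat <- merge(dat, cal, by = "sample", all.x = TRUE)
    dat$loy_exposure <- harmonise_mlrry(dat$mlrry)
    dat$mloy_call <- as.numeric(dat$mloy_call)
  }
  if (!is.null(prs)) {
    dat <- merge(dat, data.frame(sample = prs$sample, prs = prs$std,
                                 stringsAsFactors = FALSE), by = "sample")
  }

  band_label <- function(b) sprintf("men_%d_%d", b[1], b[2])

  if (!is.null(calls)) {
    men <- dat[dat$male, , drop = FALSE]
    for (expo in c("loy_exposure", "mloy_call")) {
      expo_name <- if (expo == "loy_exposure") "mLRR-Y" else "mloy_call"
      # case-control: all men, windowed men, age bands + META
      add(try_fit(fit_case_control(men, expo, pcs = pcs,
                                   model = "logistic_ad",
                                   stratum = "men"),
                  "logistic_ad", expo_name, "men"))
      add(try_fit(fit_case_control(men, expo, pcs = pcs,
                                   age_window = age_window,
                                   model = "logistic_ad",
                                   stratum = "men_65_85"),
                  "logistic_ad", expo_name, "men_65_85"))
      band_rows <- lapply(age_bands, function(b) {
        try_fit(fit_case_control(men, expo, pcs = pcs, age_window = b,
                                 model = "logistic_ad",
                                 stratum = band_label(b)),
                "logistic_ad", expo_name, band_label(b))
      })
      for (r in band_rows) add(r)
      add(meta_row(band_rows, "logistic_ad", expo_name, "men_META"))
      # conversion models in prospective MCI men
      mci_men <- men[men$mci, , drop = FALSE]
      for (oc in c("dementia", "ad")) {
        add(try_fit(fit_conversion(mci_men, expo, outcome = oc,
                                   covariates = c("age", "apoe"),
                                   pcs = pcs, stratum = "men"),
                    paste0("cox_", oc), expo_name, "men"))
      }
    }
    # replace exposure label mLRR-Y rows' exposure column
    for (i in seq_along(rows)) {
      if (rows[[i]]$exposure == "loy_exposure") rows[[i]]$exposure <- "mLRR-Y"
    }
  }

  if (!is.null(prs)) {
    strata <- list(all = rep(TRUE, nrow(dat)), men = dat$male,
                   women = !dat$male)
    for (s in names(strata)) {
      sub <- dat[strata[[s]], , drop = FALSE]
      add(try_fit(fit_case_control(sub, "prs", pcs = pcs,
                                   age_window = age_window,
                                   model = "logistic_ad", stratum = s),
                  "logistic_ad", "prs", s))
      mci <- sub[sub$mci, , drop = FALSE]
      for (oc in c("dementia", "ad")) {
        add(try_fit(fit_conversion(mci, "prs", outcome = oc,
                                   covariates = c("age", "apoe", "cohort"),
                                   pcs = pcs, stratum = s),
                    paste0("cox_", oc), "prs", s))
      }
    }
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# IVW pool a list of AssocResult rows into a META row; falls back to a
# missing row when fewer than two strata estimated
meta_row <- function(band_rows, model, exposure, stratum) {
  est <- vapply(band_rows, function(r) r$estimate, 0)
  se <- vapply(band_rows, function(r) r$se, 0)
  ok <- !is.na(est) & !is.na(se)
  if (sum(ok) < 2) {
    return(empty_assoc_result(model, exposure, stratum,
                              "fewer than two estimable strata"))
  }
  m <- ivw_meta(est[ok], se[ok])
  data.frame(model = model, exposure = exposure, stratum = stratum,
             n = sum(vapply(band_rows[ok], function(r) r$n, 0L)),
             estimate = m$estimate, se = m$se, ci_lo = m$ci_lo,
             ci_hi = m$ci_hi, z = m$z, p = m$p,
             covariates = sprintf("IVW meta of %d strata", m$n_strata),
             separation = FALSE, stringsAsFactors = FALSE)
}
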