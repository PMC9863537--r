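#' Simulate phenotypes: AD status, MCI phenoconversion, CSF biomarkers
#'
#' AD case-control status follows a logistic model in age and APOE score
#' with a male-only term on mLOY burden (`-log2(1 - cell fraction)`), so
#' cases are older than controls by construction (the age-confounded
#' structure of an ageing case-control cohort). MCI-to-dementia
#' conversion times follow a Weibull proportional-hazards law (exponential
#' by default) with a male-only polygenic-score effect of
#' `conversion_hr_per_sd_male` per SD, independent uniform censoring, and
#' a fixed fraction of converters diagnosed with AD. CSF total tau rises
#' with mLOY burden and APOE; p-tau is proportional to tau; Abeta-42 is
#' independent of mLOY. Optional pleiotropic score effects
#' (`pleiotropy_or`, `pleiotropy_hr`) act in both sexes.
#'
#' @param truth Data frame with `sample`, `male`, `age`, `prs`,
#'   `loy_burden`, and optionally `ancestry_outlier`.
#' @param config A [loy_sim_config()].
#' @param seed Optional seed.
#' @return A phenotype data frame (one row per sample) with demographic,
#'   outcome, survival, principal-component and CSF biomarker columns.
#' @export
sim_phenotypes <- function(truth, config, seed = NULL) {
  validate_loy_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("sample", "male", "age", "prs", "loy_burden")
                %in% names(truth)))
  n <- nrow(truth)
  male <- truth$male

  af <- config$apoe_freqs
  a1 <- sample(names(af), n, replace = TRUE, prob = af)
  a2 <- sample(names(af), n, replace = TRUE, prob = af)
  apoe_geno <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  apoe <- apoe_score(apoe_geno)

  # case-control AD status, logistic in age and APOE + male-only LOY term
  lin_ad <- stats::qlogis(config$ad_base_rate) +
    log(config$ad_or_age) * (truth$age - 75) +
    log(config$ad_or_apoe) * apoe +
    log(config$ad_or_loy_male) * truth$loy_burden * male +
    log(config$pleiotropy_or) * truth$prs
  ad <- stats::runif(n) < stats::plogis(lin_ad)

  # MCI phenoconversion: Weibull PH, male-only score effect
  loghr <- log(config$conversion_hr_per_sd_male) * truth$prs * male +
    log(config$conversion_hr_per_sd_female) * truth$prs * (!male) +
    log(config$pleiotropy_hr) * truth$prs +
    log(config$conv_hr_age) * (truth$age - 75) +
    log(config$conv_hr_apoe) * apoe
  h <- config$conv_base_hazard * exp(loghr)
  k <- config$conv_weibull_shape
  t_conv <- (-log(stats::runif(n)) / h)^(1 / k)
  cens <- stats::runif(n, config$censor_range[1], config$censor_range[2])
  time <- pmin(t_conv, cens)
  event_dementia <- t_conv <= cens
  ad_dx <- stats::runif(n) < config$ad_fraction_of_dementia
  event_ad <- event_dementia & ad_dx

  # principal components of population structure
  pc1 <- stats::rnorm(n); pc2 <- stats::rnorm(n)
  if (!is.null(truth$ancestry_outlier) && any(truth$ancestry_outlier)) {
    out <- truth$ancestry_outlier
    pc1[out] <- 8 * sign(stats::runif(sum(out)) - 0.5)
  }

  # CSF biomarkers
  lp_gap <- stats::runif(n, 0, 5)
  tau <- config$tau_mean + config$tau_per_loy * truth$loy_burden +
    config$tau_apoe * apoe + stats::rnorm(n, 0, config$tau_sd)
  tau <- pmax(tau, 10)
  ptau <- pmax(config$ptau_ratio * tau + stats::rnorm(n, 0, config$ptau_sd),
               1)
  abeta <- pmax(stats::rnorm(n, config$abeta_mean, config$abeta_sd), 10)

  data.frame(
    sample = truth$sample,
    sex = ifelse(male, "male", "female"),
    male = male,
    age = truth$age,
    apoe_geno = apoe_geno,
    apoe = apoe,
    ad = as.integer(ad),
    mci = !ad,
    time = time,
    event_dementia = event_dementia,
    event_ad = event_ad,
    cohort = sample(c("caseControl", "mciProspective"), n, replace = TRUE),
    pc1 = pc1, pc2 = pc2,
    age_lp = truth$age + lp_gap,
    lp_gap = lp_gap,
    syndrome = ifelse(ad, "dementia", "MCI"),
    csf_tau = tau, csf_ptau = ptau, csf_abeta42 = abeta,
    stringsAsFactors = FALSE
  )
}

#' Simulate an Olink-style two-fluid protein panel
#'
#' Generates `config$n_proteins` analytes per fluid (CSF and plasma) whose
#' entire association with mLOY flows through CSF total tau: each analyte
#' is its fluid-specific loading times standardized tau plus unit noise.
#' Loadings are drawn once per analyte from a zero-mean normal law with SD
#' `protein_tau_loading_csf` / `protein_tau_loading_plasma`.
#'
#' @param pheno Phenotype table from [sim_phenotypes()] (needs `sample`
#'   and `csf_tau`).
#' @param config A [loy_sim_config()].
#' @param samples Optional sample ids to restrict the panel to.
#' @param seed Optional seed.
#' @return Long data frame: `sample`, `fluid`, `analyte`, `level`, with
#'   the loading table in attribute `"loadings"`.
#' @export
sim_proteome <- function(pheno, config, samples = pheno$sample,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- pheno[pheno$sample %in% samples, , drop = FALSE]
  n <- nrow(keep)
  m <- config$n_proteins
  tau_z <- as.vector(scale(keep$csf_tau))
  if (n == 1L) tau_z <- 0
  analytes <- sprintf("PROT%03d", seq_len(m))
  panels <- list(CSF = config$protein_tau_loading_csf,
                 plasma = config$protein_tau_loading_plasma)
  out <- vector("list", 2L)
  loadings <- vector("list", 2L)
  for (j in seq_along(panels)) {
    lam <- stats::rnorm(m, 0, panels[[j]])
    lev <- outer(tau_z, lam) + stats::rnorm(n * m)
    out[[j]] <- data.frame(
      sample = rep(keep$sample, times = m),
      fluid = names(panels)[j],
      analyte = rep(analytes, each = n),
      level = as.vector(lev),
      stringsAsFactors = FALSE
    )
    loadings[[j]] <- data.frame(fluid = names(panels)[j], analyte = analytes,
                                loading = lam, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "loadings") <- do.call(rbind, loadings)
  res
}
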