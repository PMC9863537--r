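#' Configuration for the synthetic cohort generator
#'
#' Builds the full parameter set driving [simulate_cohort()] and the
#' individual `sim_*()` stages. Defaults encode the statistical structure of
#' an ageing memory-clinic case-control study: mLOY prevalence of 18.9% in
#' 65-85-year-old men, a polygenic instrument acting on mLOY liability at
#' OR 1.80 per SD, an age effect of OR 1.08 per year, and a male-only
#' instrument effect on MCI-to-AD phenoconversion of HR 1.23 per SD.
#'
#' @param n_samples Number of samples to simulate.
#' @param sex_ratio Fraction of male samples.
#' @param age_range Sampling-age range in years (uniform draw).
#' @param n_instrument_snps Number of autosomal instrument variants.
#' @param prs_or_per_sd Odds ratio on mLOY liability per SD of the
#'   standardized polygenic score.
#' @param age_or_per_year Odds ratio on mLOY liability per year of age.
#' @param target_mloy_prevalence Target empirical mLOY prevalence among
#'   males aged 65-85; the liability intercept is calibrated by bisection
#'   to meet it.
#' @param cell_fraction_shape Beta shape parameters for the carrier
#'   cell-fraction law.
#' @param cell_fraction_range Carrier cell fractions are the Beta draw
#'   rescaled into this interval.
#' @param conversion_hr_per_sd_male,conversion_hr_per_sd_female Hazard
#'   ratio per SD of the polygenic score on MCI-to-dementia conversion,
#'   by sex. The male default is the causal (Y-loss-mediated) signal; the
#'   female default of 1 encodes absence of pleiotropy.
#' @param pleiotropy_or,pleiotropy_hr Optional both-sex (pleiotropic)
#'   effects of the score on AD status (odds ratio per SD) and on
#'   conversion hazard (HR per SD). Defaults of 1 mean all score effects
#'   are mediated through mLOY in men.
#' @param apoe_freqs Named allele frequencies for APOE e2/e3/e4.
#' @param ad_or_age,ad_or_apoe,ad_or_loy_male Odds ratios for AD status
#'   per year of age (centred at 75), per APOE score unit, and per unit of
#'   male mLOY burden (-log2(1 - cell fraction)).
#' @param ad_base_rate Approximate AD probability at the covariate
#'   reference point (male, age 75, APOE 0, no mLOY).
#' @param conv_base_hazard Baseline yearly hazard of MCI-to-dementia
#'   conversion.
#' @param conv_hr_age,conv_hr_apoe Conversion hazard ratios per year of
#'   age and per APOE score unit.
#' @param conv_weibull_shape Weibull shape of the baseline conversion
#'   hazard; 1 gives the exponential default.
#' @param censor_range Uniform range (years) of the independent censoring
#'   time.
#' @param ad_fraction_of_dementia Fraction of dementia converters whose
#'   diagnosis is AD.
#' @param tau_mean,tau_sd CSF total-tau baseline mean and residual SD
#'   (pg/mL).
#' @param tau_per_loy Total-tau increase per unit of mLOY burden.
#' @param tau_apoe Total-tau increase per APOE score unit.
#' @param ptau_ratio,ptau_sd p-tau181 is `ptau_ratio * tau` plus noise
#'   with this SD.
#' @param abeta_mean,abeta_sd Abeta-42 mean and SD; independent of mLOY.
#' @param n_proteins Analytes per Olink-style panel (each fluid).
#' @param protein_tau_loading_csf,protein_tau_loading_plasma SD of the
#'   per-analyte loading on standardized total tau, by fluid. All
#'   analyte-mLOY association flows through tau.
#' @param n_biomarker,n_proteome Sub-cohort sizes for the CSF biomarker
#'   panel and the proteomics panel.
#' @param noise_sd_lrr Per-probe LRR noise SD.
#' @param sample_shift_sd SD of the per-sample baseline LRR shift that the
#'   trimmed autosomal mean normalisation is meant to remove.
#' @param baf_sd Per-probe BAF noise SD for heterozygous genotypes.
#' @param lrr_floor Floor (log2 units) for zero-copy signal, mimicking
#'   array background; applies to LRR-Y of XX samples.
#' @param gain_lrr Observed LRR of a single-copy gain (array-compressed,
#'   conventionally ~0.55 rather than log2(3/2)).
#' @param compression Multiplicative compression of the log2 copy-ratio
#'   signal for mosaic loss.
#' @param n_probes Named counts of probes per region (msy, par1, x, auto).
#' @param karyotype_rates Named rates of planted XXY, XYY and
#'   trisomy-21-carrier samples.
#' @param qc_violation_rates Named rates of planted QC violations
#'   (low_call_rate, excess_het, related, ancestry).
#' @param par1_loh_rate,bdev_loh Rate of planted PAR1
#'   loss-of-heterozygosity samples and the planted BAF split.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows
#'   from it.
#'
#' @return A list of class `loy_sim_config`.
#' @export
#' @examples
#' cfg <- loy_sim_config(n_samples = 500, seed = 7)
#' cfg$target_mloy_prevalence
loy_sim_config <- function(n_samples = 10000,
                           sex_ratio = 0.5,
                           age_range = c(60, 95),
                           n_instrument_snps = 114,
                           prs_or_per_sd = 1.80,
                           age_or_per_year = 1.08,
                           target_mloy_prevalence = 0.189,
                           cell_fraction_shape = c(2, 4),
                           cell_fraction_range = c(0.05, 0.9),
                           conversion_hr_per_sd_male = 1.23,
                           conversion_hr_per_sd_female = 1.00,
                           pleiotropy_or = 1.0,
                           pleiotropy_hr = 1.0,
                           apoe_freqs = c(e2 = 0.07, e3 = 0.78, e4 = 0.15),
                           ad_or_age = 1.16,
                           ad_or_apoe = 2.5,
                           ad_or_loy_male = 2.2,
                           ad_base_rate = 0.35,
                           conv_base_hazard = 0.08,
                           conv_hr_age = 1.10,
                           conv_hr_apoe = 1.3,
                           conv_weibull_shape = 1.0,
                           censor_range = c(0.5, 10),
                           ad_fraction_of_dementia = 0.7,
                           tau_mean = 350,
                           tau_sd = 100,
                           tau_per_loy = 400,
                           tau_apoe = 30,
                           ptau_ratio = 0.1,
                           ptau_sd = 6,
                           abeta_mean = 700,
                           abeta_sd = 180,
                           n_proteins = 184,
                           protein_tau_loading_csf = 0.5,
                           protein_tau_loading_plasma = 0.1,
                           n_biomarker = 214,
                           n_proteome = 135,
                           noise_sd_lrr = 0.25,
                           sample_shift_sd = 0.05,
                           baf_sd = 0.03,
                           lrr_floor = -3,
                           gain_lrr = 0.55,
                           compression = 1.0,
                           n_probes = c(msy = 100, par1 = 30, x = 50,
                                        auto = 1000),
                           karyotype_rates = c(xxy = 5e-4, xyy = 2e-4,
                                               t21 = 5e-4),
                           qc_violation_rates = c(low_call_rate = 0.002,
                                                  excess_het = 0.002,
                                                  related = 0.002,
                                                  ancestry = 0.002),
                           par1_loh_rate = 0.001,
                           bdev_loh = 0.15,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "loy_sim_config"
  validate_loy_sim_config(cfg)
  cfg
}

validate_loy_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$n_samples) || cfg$n_samples < 1) {
    stop("`n_samples` must be a positive count", call. = FALSE)
  }
  rates <- c(sex_ratio = cfg$sex_ratio,
             target_mloy_prevalence = cfg$target_mloy_prevalence,
             ad_fraction_of_dementia = cfg$ad_fraction_of_dementia)
  bad <- rates[!(rates > 0 & rates < 1) & names(rates) != "sex_ratio"]
  if (cfg$sex_ratio < 0 || cfg$sex_ratio > 1) {
    stop("`sex_ratio` must lie in [0, 1]", call. = FALSE)
  }
  if (length(bad)) {
    stop("rates must lie in (0, 1): ", paste(names(bad), collapse = ", "),
         call. = FALSE)
  }
  ratios <- c(cfg$prs_or_per_sd, cfg$age_or_per_year,
              cfg$conversion_hr_per_sd_male, cfg$conversion_hr_per_sd_female,
              cfg$pleiotropy_or, cfg$pleiotropy_hr,
              cfg$ad_or_age, cfg$ad_or_apoe, cfg$ad_or_loy_male,
              cfg$conv_hr_age, cfg$conv_hr_apoe)
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("odds/hazard ratios must be finite and > 0", call. = FALSE)
  }
  if (cfg$conv_base_hazard <= 0 || cfg$conv_weibull_shape <= 0) {
    stop("hazard parameters must be positive", call. = FALSE)
  }
  if (cfg$n_instrument_snps < 1) {
    stop("`n_instrument_snps` must be >= 1", call. = FALSE)
  }
  if (abs(sum(cfg$apoe_freqs) - 1) > 1e-8) {
    stop("`apoe_freqs` must sum to 1", call. = FALSE)
  }
  if (diff(cfg$age_range) <= 0) stop("`age_range` must be increasing",
                                     call. = FALSE)
  invisible(cfg)
}

#' Read or write a generator/pipeline configuration as YAML
#'
#' Only fields that differ from the defaults need to be present in the
#' file; everything else is filled in by [loy_sim_config()].
#'
#' @param path Path to a YAML file.
#' @param config A `loy_sim_config` object.
#' @return `read_sim_config()` returns a `loy_sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(loy_sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # yaml reads named vectors as lists; restore numeric vectors
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(loy_sim_config, vals)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "loy_sim_config"))
  # named vectors become YAML maps so their names survive the round-trip
  out <- lapply(unclass(config), function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' QC thresholds used by the sample-filtering cascade
#'
#' Defaults are the standard settings for Affymetrix-style array QC:
#' sample call rate > 0.97 (plate > 0.985), heterozygosity within 3 SD of
#' the cohort mean, ancestry within 6 SD of the reference-population mean
#' on the first two principal components, kinship <= 0.046875
#' (second-degree relatives), and LRR SD <= 0.46.
#'
#' `het_mean`/`het_sd` and `pc_center`/`pc_scale` may be supplied to fix
#' the adaptive cut-offs to external reference values (e.g. a reference
#' panel, or the values recorded in a previous [qc_filter_samples()]
#' report, which makes the cascade idempotent on its survivors).
#'
#' @param call_rate Minimum sample call rate (exclusive).
#' @param plate_call_rate Minimum plate call rate (exclusive), applied to
#'   a precomputed `plate_call_rate` column when present.
#' @param het_sd_mult Heterozygosity cut-off in cohort SD units above the
#'   mean.
#' @param ancestry_sd_mult Ancestry cut-off in SD units on each PC.
#' @param kinship Kinship coefficient above which a pair is related.
#' @param lrr_sd Maximum per-sample LRR SD.
#' @param het_mean,het_sd Optional fixed reference moments for the
#'   heterozygosity rule.
#' @param pc_center,pc_scale Optional fixed reference center/scale (length
#'   2: PC1, PC2) for the ancestry rule.
#' @param min_karyotype_margin Minimum nearest-centroid margin for a
#'   confident karyotype call (see [classify_sex_karyotype()]).
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(call_rate = 0.97,
                          plate_call_rate = 0.985,
                          het_sd_mult = 3,
                          ancestry_sd_mult = 6,
                          kinship = 0.046875,
                          lrr_sd = 0.46,
                          het_mean = NULL,
                          het_sd = NULL,
                          pc_center = NULL,
                          pc_scale = NULL,
                          min_karyotype_margin = 0.1) {
  th <- as.list(environment())
  class(th) <- "qc_thresholds"
  th
}
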