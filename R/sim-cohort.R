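#' Simulate a complete synthetic cohort
#'
#' Orchestrates the generator stages into one reproducible cohort:
#' instrument genotypes and weights, the true polygenic score, karyotypes
#' (mostly XY/XX with rare planted XXY, XYY and trisomy-21 carriers),
#' mLOY carrier status calibrated to the target 65-85 male prevalence,
#' per-probe LRR/BAF intensities, phenotypes (AD status, phenoconversion,
#' CSF biomarkers, protein panels), genotype QC summaries with planted
#' violations, and a kinship pair list. All randomness flows from
#' `config$seed`; identical configs give identical cohorts.
#'
#' @param config A [loy_sim_config()].
#' @return An object of class `loy_cohort`: a list with elements `config`,
#'   `truth`, `dosages`, `weights`, `intensities`, `probes`, `manifest`,
#'   `phenotypes`, `proteome`, `qc_stats` and `kinship`.
#' @export
#' @examples
#' coh <- simulate_cohort(loy_sim_config(n_samples = 300, seed = 1,
#'   n_probes = c(msy = 30, par1 = 10, x = 10, auto = 100)))
#' coh
simulate_cohort <- function(config) {
  validate_loy_sim_config(config)
  set.seed(as.integer(config$seed))
  n <- as.integer(config$n_samples)

  geno <- sim_genotypes(config)
  prs <- compute_prs(geno$dosages, geno$weights)

  male <- stats::runif(n) < config$sex_ratio
  age <- stats::runif(n, config$age_range[1], config$age_range[2])

  kr <- config$karyotype_rates
  karyotype <- ifelse(male, "XY", "XX")
  u_kar <- stats::runif(n)
  karyotype[male & u_kar < kr[["xxy"]]] <- "XXY"
  karyotype[male & u_kar >= kr[["xxy"]] &
              u_kar < kr[["xxy"]] + kr[["xyy"]]] <- "XYY"
  t21 <- stats::runif(n) < kr[["t21"]]

  truth <- data.frame(sample = rownames(geno$dosages),
                      male = male, age = age, karyotype = karyotype,
                      t21 = t21, prs = prs$std,
                      stringsAsFactors = FALSE)

  loy <- sim_mloy_status(config, truth$prs, truth$age, truth$male)
  # non-XY karyotypes are excluded upstream of calling; keep their truth
  # mosaic state consistent with their Y-copy number instead
  loy$loy[karyotype != "XY"] <- FALSE
  loy$loy_cell_fraction[karyotype != "XY"] <- 0
  loy$loy_burden[karyotype != "XY"] <- 0
  truth <- cbind(truth, loy)
  attr(truth, "alpha0") <- attr(loy, "alpha0")

  vr <- config$qc_violation_rates
  truth$low_call_rate <- stats::runif(n) < vr[["low_call_rate"]]
  truth$excess_het <- stats::runif(n) < vr[["excess_het"]]
  truth$ancestry_outlier <- stats::runif(n) < vr[["ancestry"]]
  truth$par1_loh <- stats::runif(n) < config$par1_loh_rate
  truth$lrr_noise_mult <- 1

  manifest <- default_probe_manifest()
  probes <- sim_probes(config, manifest)
  intens <- sim_intensities(truth, probes, config)

  pheno <- sim_phenotypes(truth, config)
  prot_samples <- utils::head(pheno$sample[pheno$male & pheno$mci],
                              config$n_proteome)
  proteome <- sim_proteome(pheno, config, samples = prot_samples)

  # genotype-level QC summaries (array-wide call and heterozygosity rates
  # are emitted directly; the instrument SNPs are too few to recompute them)
  call_rate <- pmin(stats::rnorm(n, 0.995, 0.002), 1)
  call_rate[truth$low_call_rate] <- stats::runif(sum(truth$low_call_rate),
                                                 0.90, 0.965)
  het_rate <- stats::rnorm(n, 0.33, 0.01)
  het_rate[truth$excess_het] <- het_rate[truth$excess_het] + 0.08

  istats <- intensity_sample_stats(intens)
  plate <- sprintf("PL%03d", (seq_len(n) - 1L) %/% 96L + 1L)
  qc_stats <- data.frame(
    sample = truth$sample,
    call_rate = call_rate,
    plate = plate,
    plate_call_rate = 0.995,
    het_rate = het_rate,
    mean_lrr_x = istats$mean_lrr_x,
    mean_lrr_y = istats$mean_lrr_y,
    lrr_sd = istats$lrr_sd,
    pc1 = pheno$pc1, pc2 = pheno$pc2,
    chromosomopathy = truth$t21,
    stringsAsFactors = FALSE
  )

  # planted related pairs: adjacent samples with second-degree kinship
  n_rel <- round(vr[["related"]] * n)
  kinship <- data.frame(sample1 = character(0), sample2 = character(0),
                        kinship = numeric(0), stringsAsFactors = FALSE)
  if (n_rel > 0 && n >= 2) {
    i1 <- sample.int(n - 1L, n_rel)
    kinship <- data.frame(sample1 = truth$sample[i1],
                          sample2 = truth$sample[i1 + 1L],
                          kinship = stats::runif(n_rel, 0.06, 0.25),
                          stringsAsFactors = FALSE)
    truth$related <- truth$sample %in% c(kinship$sample1, kinship$sample2)
  } else {
    truth$related <- FALSE
  }

  structure(list(config = config, truth = truth,
                 dosages = geno$dosages, weights = geno$weights,
                 intensities = intens, probes = probes, manifest = manifest,
                 phenotypes = pheno, proteome = proteome,
                 qc_stats = qc_stats, kinship = kinship),
            class = "loy_cohort")
}

#' @export
print.loy_cohort <- function(x, ...) {
  tr <- x$truth
  win <- tr$male & tr$age >= 65 & tr$age <= 85
  cat("<loy_cohort> n =", nrow(tr),
      sprintf("(%.0f%% male), seed %s\n", 100 * mean(tr$male),
              x$config$seed))
  cat(sprintf("  mLOY carriers: %d (%.1f%% of males 65-85)\n",
              sum(tr$loy), 100 * mean(tr$loy[win])))
  cat(sprintf("  probes: %d; instrument SNPs: %d; AD cases: %d\n",
              nrow(x$probes), ncol(x$dosages), sum(x$phenotypes$ad)))
  invisible(x)
}

#' Write a synthetic cohort to a directory of TSV files
#'
#' Writes the same tabular formats the pipeline reads (`intensities.tsv`,
#' `weights.tsv`, `phenotypes.tsv`, `dosages.tsv`, `qc_stats.tsv`,
#' `kinship.tsv`, `manifest.tsv`, `proteome.tsv`) plus the ground-truth
#' table (`truth.tsv`) used by recovery tests.
#'
#' @param cohort A `loy_cohort`.
#' @param dir Output directory (created if needed).
#' @param intensities Write the (large) long-format intensity table?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, intensities = TRUE) {
  stopifnot(inherits(cohort, "loy_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) write_tsv(df, file.path(dir, name))
  wr(cohort$truth, "truth.tsv")
  wr(cohort$weights, "weights.tsv")
  wr(cohort$phenotypes, "phenotypes.tsv")
  wr(cohort$qc_stats, "qc_stats.tsv")
  wr(cohort$kinship, "kinship.tsv")
  wr(cohort$manifest, "manifest.tsv")
  wr(cohort$proteome, "proteome.tsv")
  dos <- data.frame(sample = rownames(cohort$dosages), cohort$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wr(dos, "dosages.tsv")
  if (intensities) wr(as_intensity_table(cohort$intensities),
                      "intensities.tsv")
  invisible(dir)
}
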