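subset_intensities <- function(intensities, samples) {
  keep <- intensities$samples %in% samples
  structure(list(lrr = intensities$lrr[keep, , drop = FALSE],
                 baf = intensities$baf[keep, , drop = FALSE],
                 probes = intensities$probes,
                 samples = intensities$samples[keep]),
            class = "intensity_set")
}

#' Run the full pipeline on a synthetic cohort
#'
#' Executes every stage end-to-end with one seed: cohort simulation,
#' the sample-QC cascade, mLRR-Y / PAR1-Bdev computation, batched
#' threshold calling with batch-effect checks, anomaly flagging,
#' instrument filtering and polygenic scoring, the sex- and
#' age-stratified association grid, the CSF biomarker meta-analyses, and
#' the two-fluid proteome scan in base and tau-adjusted variants. When
#' `out_dir` is given, all result tables are written as TSV together with
#' a JSON run manifest (config snapshot, seed, QC funnel, md5 digests of
#' every output file); identical configs reproduce byte-identical
#' bundles.
#'
#' @param config A [loy_sim_config()].
#' @param out_dir Optional output directory.
#' @param n_batches Batches for threshold calling.
#' @param thresholds A [qc_thresholds()] object.
#' @return List of class `loy_pipeline`: `cohort`, `qc`, `calls`, `prs`,
#'   `instrument`, `assoc`, `biomarkers`, `scan`, `funnel`, `manifest`.
#' @export
run_pipeline <- function(config = loy_sim_config(), out_dir = NULL,
                         n_batches = 2, thresholds = qc_thresholds()) {
  cohort <- simulate_cohort(config)

  # full cascade (XY males only) for mLOY calling; genotype-level cascade
  # (keeps women, skips the intensity-based stages) for the score analyses
  qc <- qc_filter_samples(cohort$qc_stats, cohort$kinship, thresholds)
  survivors <- qc$sample[!qc$excluded]
  qc_geno <- qc_filter_samples(cohort$qc_stats, cohort$kinship, thresholds,
                               skip = c("karyotype", "lrr_sd"))
  geno_survivors <- qc_geno$sample[!qc_geno$excluded]

  intens <- subset_intensities(cohort$intensities, survivors)
  mlrry <- compute_mlrry(intens,
                         min_auto = min(1000, config$n_probes[["auto"]]))
  bdev <- compute_par1_bdev(intens)
  calls <- call_mloy(mlrry, bdev, n_batches = n_batches,
                     seed = config$seed)
  calls <- flag_anomalies(calls)

  stats <- cohort$weights[c("variant", "maf", "r2")]
  stats$available <- TRUE
  instrument <- filter_instrument_variants(cohort$weights, stats)
  prs <- compute_prs(cohort$dosages[geno_survivors, , drop = FALSE],
                     instrument)

  pheno <- cohort$phenotypes[cohort$phenotypes$sample %in% geno_survivors, ,
                             drop = FALSE]
  assoc <- run_mr_suite(pheno, prs = prs, calls = calls)

  # CSF biomarkers: male survivors with calls, harmonised exposure
  bio <- merge(pheno[pheno$male, , drop = FALSE],
               calls[is.na(calls$anomaly), c("sample", "mlrry")],
               by = "sample")
  bio$loy_exposure <- harmonise_mlrry(bio$mlrry)
  bio <- utils::head(bio[order(bio$sample), , drop = FALSE],
                     config$n_biomarker)
  biomarkers <- lapply(
    stats::setNames(nm = c("csf_tau", "csf_ptau", "csf_abeta42")),
    function(a) fit_biomarker(bio, a, "loy_exposure"))

  scan_cov <- merge(pheno, calls[is.na(calls$anomaly),
                                 c("sample", "mlrry")], by = "sample")
  scan_cov$loy_exposure <- harmonise_mlrry(scan_cov$mlrry)
  scan <- proteome_scan(cohort$proteome,
                        scan_cov[c("sample", "loy_exposure", "age_lp",
                                   "lp_gap", "apoe", "csf_tau")])

  funnel <- c(input = nrow(qc), attr(qc, "funnel"),
              anomaly_clean = sum(is.na(calls$anomaly)))
  bio_rows <- do.call(rbind, lapply(names(biomarkers), function(a) {
    m <- biomarkers[[a]]$meta
    rbind(biomarkers[[a]]$per_group,
          data.frame(model = "linear", exposure = a, stratum = "META",
                     n = sum(biomarkers[[a]]$per_group$n),
                     estimate = m$estimate, se = m$se, ci_lo = m$ci_lo,
                     ci_hi = m$ci_hi, z = m$z, p = m$p,
                     covariates = "IVW meta", separation = FALSE,
                     stringsAsFactors = FALSE))
  }))

  result <- list(cohort = cohort, qc = qc, qc_geno = qc_geno,
                 calls = calls, prs = prs,
                 instrument = instrument, assoc = assoc,
                 biomarkers = biomarkers, biomarker_table = bio_rows,
                 scan = scan, funnel = funnel, manifest = NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(qc_report = "qc_report.tsv", mloy_calls = "mloy_calls.tsv",
               prs = "prs.tsv", assoc = "assoc_results.tsv",
               biomarkers = "biomarker_results.tsv",
               proteome = "proteome_scan.tsv", funnel = "funnel.tsv")
    write_tsv(as.data.frame(qc), file.path(out_dir, files["qc_report"]))
    write_tsv(as.data.frame(calls), file.path(out_dir, files["mloy_calls"]))
    write_tsv(as.data.frame(prs), file.path(out_dir, files["prs"]))
    write_tsv(assoc, file.path(out_dir, files["assoc"]))
    write_tsv(bio_rows, file.path(out_dir, files["biomarkers"]))
    scan_out <- as.data.frame(scan)
    write_tsv(scan_out, file.path(out_dir, files["proteome"]))
    write_tsv(data.frame(stage = names(funnel), n = unname(funnel)),
              file.path(out_dir, files["funnel"]))

    digests <- as.list(tools::md5sum(file.path(out_dir, unname(files))))
    names(digests) <- unname(files)
    manifest <- list(
      package_version = as.character(utils::packageVersion("mloymr")),
      seed = config$seed,
      config = unclass(config),
      n_batches = n_batches,
      funnel = as.list(funnel),
      n_geno_survivors = length(geno_survivors),
      lambda = as.list(attr(scan, "lambda")),
      batch_tests = attr(calls, "batch_tests")[c("ks_p", "prop_p")],
      digests = digests)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    result$manifest <- manifest
  }
  class(result) <- "loy_pipeline"
  result
}

#' @export
print.loy_pipeline <- function(x, ...) {
  cat("<loy_pipeline>\n  funnel:",
      paste(names(x$funnel), x$funnel, sep = "=", collapse = " > "), "\n")
  cat("  mLOY calls:", sum(x$calls$mloy_call), "of", nrow(x$calls), "\n")
  cat("  association rows:", nrow(x$assoc), "\n")
  lam <- attr(x$scan, "lambda")
  cat("  scan lambda:",
      paste(names(lam), sprintf("%.2f", lam), collapse = ", "), "\n")
  invisible(x)
}
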