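#' Per-sample intensity summaries
#'
#' Mean LRR over chromosome X and chromosome Y probes (used for sex
#' karyotype classification) and the per-sample LRR standard deviation
#' over autosomal probes (a noise metric for array QC).
#'
#' @param intensities An `intensity_set`.
#' @return Data frame: `sample`, `mean_lrr_x`, `mean_lrr_y`, `lrr_sd`.
#' @export
intensity_sample_stats <- function(intensities) {
  stopifnot(inherits(intensities, "intensity_set"))
  region <- intensities$probes$region
  ycols <- intensities$probes$chrom == "Y" & region %in% c("MSY", "XTR")
  xcols <- region == "X"
  acols <- region == "AUTO"
  lrr <- intensities$lrr
  data.frame(
    sample = intensities$samples,
    mean_lrr_x = rowMeans(lrr[, xcols, drop = FALSE], na.rm = TRUE),
    mean_lrr_y = rowMeans(lrr[, ycols, drop = FALSE], na.rm = TRUE),
    lrr_sd = apply(lrr[, acols, drop = FALSE], 1, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Default sex-karyotype centroids
#'
#' Centroids in (mean LRR-X, mean LRR-Y) space under the log2 copy-ratio
#' convention with an XY reference: a single-copy gain sits at `gain_lrr`
#' and a zero-copy state at the `floor` background level.
#'
#' @param gain_lrr Observed LRR of a single-copy gain.
#' @param floor Background LRR of a zero-copy state.
#' @return Matrix with rows XY, XX, XXY, XYY and columns
#'   `mean_lrr_x`, `mean_lrr_y`.
#' @export
default_karyotype_centroids <- function(gain_lrr = 0.55, floor = -3) {
  m <- rbind(XY = c(0, 0),
             XX = c(gain_lrr, floor),
             XXY = c(gain_lrr, 0),
             XYY = c(0, gain_lrr))
  colnames(m) <- c("mean_lrr_x", "mean_lrr_y")
  m
}

#' Classify sex-chromosome karyotype from mean LRR-X / LRR-Y
#'
#' Nearest-centroid assignment in (mean LRR-X, mean LRR-Y) space over the
#' classes XY, XX, XXY and XYY. The margin is the distance to the
#' second-nearest centroid minus the distance to the nearest; samples
#' whose margin falls below `min_margin` are labelled `"unclassified"`.
#'
#' @param mean_lrr_x,mean_lrr_y Numeric vectors of per-sample means.
#' @param centroids Centroid matrix (see [default_karyotype_centroids()]).
#' @param min_margin Minimum margin for a confident call.
#' @return Data frame: `karyotype`, `distance`, `margin`.
#' @export
#' @examples
#' classify_sex_karyotype(c(0, 0.55, 0), c(0, -3, 0.55))
classify_sex_karyotype <- function(mean_lrr_x, mean_lrr_y,
                                   centroids = default_karyotype_centroids(),
                                   min_margin = 0.1) {
  stopifnot(length(mean_lrr_x) == length(mean_lrr_y))
  if (any(!is.finite(mean_lrr_x)) || any(!is.finite(mean_lrr_y))) {
    stop("mean LRR-X / LRR-Y must be finite", call. = FALSE)
  }
  d <- outer(mean_lrr_x, centroids[, 1], "-")^2 +
    outer(mean_lrr_y, centroids[, 2], "-")^2
  d <- sqrt(d)
  best <- max.col(-d, ties.method = "first")
  dist <- d[cbind(seq_along(best), best)]
  d2 <- d
  d2[cbind(seq_along(best), best)] <- Inf
  margin <- apply(d2, 1, min) - dist
  kar <- rownames(centroids)[best]
  kar[margin < min_margin] <- "unclassified"
  data.frame(karyotype = kar, distance = dist, margin = margin,
             stringsAsFactors = FALSE)
}

# greedy deterministic resolution of related pairs: repeatedly drop the
# member with the lower call rate (ties: lexicographically larger id)
# until no retained pair remains related
resolve_kinship <- function(kinship, call_rate, threshold) {
  drop <- character(0)
  if (nrow(kinship) == 0) return(drop)
  rel <- kinship[kinship$kinship > threshold, , drop = FALSE]
  rel <- rel[order(rel$sample1, rel$sample2), , drop = FALSE]
  repeat {
    live <- !(rel$sample1 %in% drop) & !(rel$sample2 %in% drop)
    if (!any(live)) break
    pair <- rel[which(live)[1], ]
    cr1 <- call_rate[[pair$sample1]]
    cr2 <- call_rate[[pair$sample2]]
    victim <- if (cr1 < cr2) pair$sample1
      else if (cr2 < cr1) pair$sample2
      else max(pair$sample1, pair$sample2)
    drop <- c(drop, victim)
  }
  drop
}

#' Apply the sample-QC cascade
#'
#' Applies the exclusion cascade in a fixed order, recording for every
#' excluded sample the *first* rule it failed:
#' \enumerate{
#'   \item non-XY karyotype (from nearest-centroid classification of mean
#'     LRR-X / LRR-Y),
#'   \item relatedness (kinship > 0.046875; the member of a pair with the
#'     lower call rate is dropped, ties resolved lexicographically),
#'   \item sample call rate <= 0.97 (and plate call rate <= 0.985 when a
#'     `plate_call_rate` column is present),
#'   \item heterozygosity more than 3 SD above the cohort mean,
#'   \item ancestry outlier: |PC1| or |PC2| more than 6 SD from the
#'     reference mean,
#'   \item autosomal chromosomopathy flag,
#'   \item LRR SD > 0.46.
#' }
#'
#' The adaptive heterozygosity and ancestry cut-offs are resolved to
#' absolute values (from the input cohort unless reference moments are
#' supplied in `thresholds`) and recorded in the report's
#' `"resolved_thresholds"` attribute; re-running the cascade on the
#' survivors with those recorded thresholds excludes nobody.
#'
#' @param stats Per-sample QC table with columns `sample`, `call_rate`,
#'   `het_rate`, `mean_lrr_x`, `mean_lrr_y`, `lrr_sd`, `pc1`, `pc2` and
#'   optionally `plate_call_rate`, `chromosomopathy`, `karyotype`.
#'   When `karyotype` is absent it is computed from the LRR means.
#' @param kinship Data frame of pairs: `sample1`, `sample2`, `kinship`.
#' @param thresholds A [qc_thresholds()] object.
#' @param skip Stage names to skip (e.g. `c("karyotype", "lrr_sd")` for
#'   the genotype-level cascade applied to the polygenic-score cohort,
#'   which keeps women).
#' @return A `qc_report` data frame: `stats` plus `karyotype`, `excluded`
#'   and `reason` columns, with attributes `"resolved_thresholds"` and
#'   `"funnel"` (samples surviving after each stage).
#' @export
qc_filter_samples <- function(stats, kinship = NULL,
                              thresholds = qc_thresholds(),
                              skip = character(0)) {
  need <- c("sample", "call_rate", "het_rate", "mean_lrr_x", "mean_lrr_y",
            "lrr_sd", "pc1", "pc2")
  miss <- setdiff(need, names(stats))
  if (length(miss)) stop("`stats` missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stats <- stats[order(stats$sample), , drop = FALSE]
  rownames(stats) <- NULL
  n <- nrow(stats)
  if (is.null(kinship)) {
    kinship <- data.frame(sample1 = character(0), sample2 = character(0),
                          kinship = numeric(0))
  } else {
    unknown <- setdiff(c(kinship$sample1, kinship$sample2), stats$sample)
    if (length(unknown)) {
      stop("kinship table names sample(s) absent from `stats`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }

  if (!"karyotype" %in% names(stats)) {
    stats$karyotype <- classify_sex_karyotype(
      stats$mean_lrr_x, stats$mean_lrr_y,
      min_margin = thresholds$min_karyotype_margin)$karyotype
  }

  # resolve adaptive thresholds once, against the input cohort
  het_mean <- thresholds$het_mean %||% mean(stats$het_rate)
  het_sd <- thresholds$het_sd %||% stats::sd(stats$het_rate)
  pc_center <- thresholds$pc_center %||% c(mean(stats$pc1), mean(stats$pc2))
  pc_scale <- thresholds$pc_scale %||% c(stats::sd(stats$pc1),
                                         stats::sd(stats$pc2))
  het_cut <- het_mean + thresholds$het_sd_mult * het_sd
  resolved <- list(call_rate = thresholds$call_rate,
                   plate_call_rate = thresholds$plate_call_rate,
                   het_cut = het_cut, het_mean = het_mean, het_sd = het_sd,
                   pc_center = pc_center, pc_scale = pc_scale,
                   ancestry_sd_mult = thresholds$ancestry_sd_mult,
                   kinship = thresholds$kinship,
                   lrr_sd = thresholds$lrr_sd)

  reason <- rep(NA_character_, n)
  alive <- function() is.na(reason)
  mark <- function(hit, why) {
    if (why %in% skip) return(invisible(NULL))
    hit <- !is.na(hit) & hit & alive()
    reason[hit] <<- why
    invisible(NULL)
  }
  funnel <- integer(0)
  stage <- function(name) {
    funnel[name] <<- sum(alive())
  }

  mark(stats$karyotype != "XY", "karyotype")
  stage("karyotype")

  kin_drop <- resolve_kinship(
    kinship[kinship$sample1 %in% stats$sample[alive()] &
              kinship$sample2 %in% stats$sample[alive()], , drop = FALSE],
    stats::setNames(stats$call_rate, stats$sample), thresholds$kinship)
  mark(stats$sample %in% kin_drop, "relatedness")
  stage("relatedness")

  low_cr <- stats$call_rate <= thresholds$call_rate
  if ("plate_call_rate" %in% names(stats)) {
    low_cr <- low_cr | stats$plate_call_rate <= thresholds$plate_call_rate
  }
  mark(low_cr, "call_rate")
  stage("call_rate")

  mark(stats$het_rate > het_cut, "heterozygosity")
  stage("heterozygosity")

  anc <- abs(stats$pc1 - pc_center[1]) >
    thresholds$ancestry_sd_mult * pc_scale[1] |
    abs(stats$pc2 - pc_center[2]) > thresholds$ancestry_sd_mult * pc_scale[2]
  mark(anc, "ancestry")
  stage("ancestry")

  chromo <- if ("chromosomopathy" %in% names(stats)) {
    as.logical(stats$chromosomopathy)
  } else rep(FALSE, n)
  mark(chromo %in% TRUE, "chromosomopathy")
  stage("chromosomopathy")

  mark(stats$lrr_sd > thresholds$lrr_sd, "lrr_sd")
  stage("lrr_sd")

  out <- stats
  out$excluded <- !is.na(reason)
  out$reason <- reason
  attr(out, "resolved_thresholds") <- resolved
  attr(out, "funnel") <- funnel
  class(out) <- c("qc_report", class(out))
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", nrow(x), " samples, ", sum(x$excluded),
      " excluded\n", sep = "")
  if (any(x$excluded)) print(table(reason = x$reason[x$excluded]))
  invisible(as.data.frame(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
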