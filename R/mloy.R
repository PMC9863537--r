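#' Compute mLRR-Y: normalised mean LRR over the male-specific Y region
#'
#' mLRR-Y is the mean LRR of probes in the male-specific region of
#' chromosome Y (MSY, chrY:6611498-24510581 on hg19, excluding the
#' X-transposed region) minus the per-sample 5% trimmed mean of autosomal
#' LRR. The subtraction removes the sample-level intensity baseline;
#' trimming (5% of values from *each* tail) makes the autosomal reference
#' robust to CNVs and outlier probes. More negative mLRR-Y means a higher
#' mosaic fraction of LOY cells: a noise-free sample with fraction `f`
#' sits at `log2(1 - f)`.
#'
#' @param intensities An `intensity_set` (or a long intensity table, which
#'   is converted using `manifest`).
#' @param manifest Region manifest; only needed for long tables or to
#'   re-annotate probes.
#' @param min_msy,min_auto Minimum numbers of MSY and autosomal probes.
#' @param trim Trim fraction per tail for the autosomal mean.
#' @return Named numeric vector of per-sample mLRR-Y.
#' @export
compute_mlrry <- function(intensities, manifest = NULL, min_msy = 20,
                          min_auto = 1000, trim = 0.05) {
  if (!inherits(intensities, "intensity_set")) {
    intensities <- as_intensity_set(intensities,
                                    manifest %||% default_probe_manifest())
  } else if (!is.null(manifest)) {
    intensities$probes <- annotate_probes(
      intensities$probes[c("probe", "chrom", "pos")], manifest)
  }
  region <- intensities$probes$region
  msy <- which(region == "MSY")
  auto <- which(region == "AUTO")
  if (length(msy) < min_msy || length(auto) < min_auto) {
    stop(sprintf(paste0("too few probes for mLRR-Y: %d MSY (need >= %d), ",
                        "%d autosomal (need >= %d)"),
                 length(msy), min_msy, length(auto), min_auto),
         call. = FALSE)
  }
  lrr <- intensities$lrr
  msy_mean <- rowMeans(lrr[, msy, drop = FALSE], na.rm = TRUE)
  auto_ref <- apply(lrr[, auto, drop = FALSE], 1, trimmed_mean, trim = trim)
  stats::setNames(msy_mean - auto_ref, intensities$samples)
}

#' Trimmed mean removing a fraction of values from each tail
#'
#' `floor(n * trim)` of the smallest and largest values are removed before
#' averaging, the conventional trimmed-mean definition (and the one used
#' by `mean(x, trim = )`).
#'
#' @param x Numeric vector.
#' @param trim Fraction per tail in \[0, 0.5).
#' @return The trimmed mean.
#' @export
trimmed_mean <- function(x, trim = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NaN)
  if (trim <= 0) return(mean(x))
  stopifnot(trim < 0.5)
  k <- floor(n * trim)
  s <- sort(x)
  mean(s[(k + 1L):(n - k)])
}

#' Compute PAR1 B-deviation
#'
#' Bdev is the mean absolute deviation from the expected BAF of 0.5 over
#' heterozygous SNPs in the pseudoautosomal region 1, a complementary
#' indicator of mosaicism / loss of heterozygosity. Heterozygotes are
#' taken as probes with BAF in the open window `het_range`.
#'
#' @param intensities An `intensity_set`, or a numeric vector of PAR1 BAF
#'   values for a single sample.
#' @param min_het Minimum heterozygous PAR1 SNPs; below it the result is
#'   `NA` with the reason recorded in the `"reason"` attribute rather than
#'   an error.
#' @param het_range Open BAF interval defining heterozygotes.
#' @return Per-sample named numeric vector of Bdev (single value for a
#'   BAF vector input).
#' @export
#' @examples
#' compute_par1_bdev(c(0.40, 0.60, 0.35, 0.65, 0.5))
compute_par1_bdev <- function(intensities, min_het = 5,
                              het_range = c(0.1, 0.9)) {
  one <- function(baf) {
    het <- baf[!is.na(baf) & baf > het_range[1] & baf < het_range[2]]
    if (length(het) < min_het) return(NA_real_)
    mean(abs(het - 0.5))
  }
  if (is.numeric(intensities)) {
    res <- one(intensities)
    if (is.na(res)) attr(res, "reason") <- "too few heterozygous PAR1 SNPs"
    return(res)
  }
  stopifnot(inherits(intensities, "intensity_set"))
  p1 <- which(intensities$probes$region == "PAR1")
  res <- apply(intensities$baf[, p1, drop = FALSE], 1, one)
  res <- stats::setNames(res, intensities$samples)
  if (anyNA(res)) {
    attr(res, "reason") <- stats::setNames(
      ifelse(is.na(res), "too few heterozygous PAR1 SNPs", NA),
      intensities$samples)[is.na(res)]
  }
  res
}

#' Call mLOY from the cohort mLRR-Y distribution (positive-side threshold)
#'
#' The calling threshold extrapolates the 99% confidence bound of the
#' positive side of the cohort mLRR-Y distribution: with the cohort median
#' as centre, the positive deviations `d = x - median` (for `x` above the
#' median, which are assumed free of LOY signal) estimate the null spread,
#' and the threshold is `median - q`, where `q` is the empirical 0.99
#' quantile of `d` (`method = "empirical"`, the default) or the half-normal
#' parametric bound `sd_hat * qnorm(0.995)` with
#' `sd_hat = sqrt(mean(d^2))` (`method = "halfnormal"`). Samples with
#' mLRR-Y strictly below the threshold are called mLOY.
#'
#' @param mlrry Numeric vector of cohort mLRR-Y values.
#' @param method Threshold construction; see Details.
#' @param conf Positive-side confidence level (0.99 reproduces the
#'   conventional setting).
#' @param min_n Minimum cohort size for a stable threshold.
#' @return List with `threshold`, `calls` (logical, named like `mlrry`),
#'   `center`, `method`, `n`.
#' @export
call_mloy_threshold <- function(mlrry, method = c("empirical", "halfnormal"),
                                conf = 0.99, min_n = 100) {
  method <- match.arg(method)
  mlrry <- mlrry[!is.na(mlrry)]
  n <- length(mlrry)
  if (n < min_n) {
    stop(sprintf("cohort too small for threshold calling: %d < %d",
                 n, min_n), call. = FALSE)
  }
  center <- stats::median(mlrry)
  d <- mlrry[mlrry > center] - center
  if (length(d) == 0) {
    stop("degenerate mLRR-Y distribution: no values above the median",
         call. = FALSE)
  }
  q <- switch(method,
              empirical = stats::quantile(d, conf, names = FALSE),
              halfnormal = sqrt(mean(d^2)) *
                stats::qnorm((1 + conf) / 2))
  threshold <- center - q
  list(threshold = threshold,
       calls = mlrry < threshold,
       center = center, method = method, n = n)
}

#' Call mLOY in randomised batches and check for batch effects
#'
#' Randomly partitions the cohort into `n_batches` batches under `seed`,
#' computes the calling threshold within each batch, and assesses batch
#' effects with a two-sample Kolmogorov-Smirnov test on mLRR-Y and a
#' proportion test on batch call rates. With `n_batches = 1` the result is
#' identical to pooled calling.
#'
#' @param mlrry Named numeric vector of cohort mLRR-Y.
#' @param bdev Optional named numeric vector of PAR1-Bdev.
#' @param n_batches Number of random batches.
#' @param seed Seed for the batch partition.
#' @param ... Passed to [call_mloy_threshold()].
#' @return An object of class `mloy_calls`: a data frame with columns
#'   `sample`, `mlrry`, `bdev`, `mloy_call`, `batch`, `threshold`,
#'   `anomaly`, plus attributes `batch_tests` (KS and proportion-test
#'   p-values) and `thresholds`.
#' @export
call_mloy <- function(mlrry, bdev = NULL, n_batches = 2, seed = 1, ...) {
  if (n_batches < 1) stop("`n_batches` must be >= 1", call. = FALSE)
  n <- length(mlrry)
  ids <- names(mlrry) %||% sprintf("S%05d", seq_len(n))
  set.seed(seed)
  batch <- sample(rep_len(seq_len(n_batches), n))

  thresholds <- numeric(n_batches)
  calls <- logical(n)
  for (b in seq_len(n_batches)) {
    in_b <- batch == b
    res <- call_mloy_threshold(mlrry[in_b], ...)
    thresholds[b] <- res$threshold
    calls[in_b] <- mlrry[in_b] < res$threshold
  }

  batch_tests <- list(ks_p = NA_real_, prop_p = NA_real_,
                      ks_D = NA_real_)
  if (n_batches >= 2) {
    ks_p <- ks_D <- numeric(0)
    for (b1 in seq_len(n_batches - 1)) {
      for (b2 in (b1 + 1):n_batches) {
        kt <- suppressWarnings(stats::ks.test(mlrry[batch == b1],
                                              mlrry[batch == b2]))
        ks_p <- c(ks_p, kt$p.value)
        ks_D <- c(ks_D, unname(kt$statistic))
      }
    }
    pt <- suppressWarnings(stats::prop.test(
      tapply(calls, batch, sum), tapply(calls, batch, length)))
    batch_tests <- list(ks_p = min(ks_p) * length(ks_p),  # Bonferroni
                        ks_p_raw = ks_p, ks_D = ks_D,
                        prop_p = pt$p.value)
    batch_tests$ks_p <- min(batch_tests$ks_p, 1)
  }

  out <- data.frame(sample = ids, mlrry = unname(mlrry),
                    bdev = if (is.null(bdev)) NA_real_ else unname(bdev),
                    mloy_call = calls, batch = batch,
                    threshold = thresholds[batch],
                    anomaly = NA_character_,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- thresholds
  attr(out, "batch_tests") <- batch_tests
  class(out) <- c("mloy_calls", class(out))
  out
}

#' Flag PAR1-LOH and partial-loss anomalies
#'
#' Samples whose PAR1-Bdev exceeds `median + k * MAD` of the cohort Bdev
#' are flagged `"par1_loh"` (allelic imbalance not explained by whole-Y
#' loss); samples whose mLRR-Y falls inside an optional intermediate
#' `partial_band` are flagged `"partial_y"`. Flagged samples should be
#' excluded from association inputs. `k = Inf` (or constant Bdev)
#' disables the Bdev rule.
#'
#' @param calls An `mloy_calls` object (or data frame with `mlrry`,
#'   `bdev`).
#' @param k MAD multiplier for the Bdev rule.
#' @param partial_band Optional length-2 mLRR-Y interval flagged as
#'   partial Y loss; `NULL` disables it.
#' @return `calls` with the `anomaly` column filled (`NA` = no anomaly).
#' @export
flag_anomalies <- function(calls, k = 5, partial_band = NULL) {
  anomaly <- rep(NA_character_, nrow(calls))
  bdev <- calls$bdev
  if (!all(is.na(bdev))) {
    cut <- stats::median(bdev, na.rm = TRUE) +
      k * stats::mad(bdev, na.rm = TRUE)
    if (is.finite(cut)) {
      anomaly[!is.na(bdev) & bdev > cut] <- "par1_loh"
    }
  }
  if (!is.null(partial_band)) {
    hit <- calls$mlrry >= partial_band[1] & calls$mlrry <= partial_band[2]
    anomaly[hit & is.na(anomaly)] <- "partial_y"
  }
  calls$anomaly <- anomaly
  calls
}

#' Sign-harmonise mLRR-Y for association models
#'
#' Association models use `-mLRR-Y` as the exposure so that positive
#' effects mean "more mosaic loss, more risk".
#'
#' @param mlrry Numeric vector.
#' @return `-mlrry`.
#' @export
harmonise_mlrry <- function(mlrry) -mlrry

#' @export
print.mloy_calls <- function(x, ...) {
  cat("<mloy_calls> ", nrow(x), " samples, ", sum(x$mloy_call),
      " mLOY calls (", sprintf("%.1f%%", 100 * mean(x$mloy_call)), ")\n",
      sep = "")
  th <- attr(x, "thresholds")
  cat("  thresholds: ", paste(sprintf("%.4f", th), collapse = ", "),
      " (", length(th), " batch", if (length(th) > 1) "es", ")\n", sep = "")
  bt <- attr(x, "batch_tests")
  if (!is.na(bt$ks_p)) {
    cat(sprintf("  batch effect: KS p = %.3g, call-rate p = %.3g\n",
                bt$ks_p, bt$prop_p))
  }
  invisible(x)
}

#' @export
summary.mloy_calls <- function(object, ...) {
  out <- list(n = nrow(object),
              n_calls = sum(object$mloy_call),
              call_rate = mean(object$mloy_call),
              thresholds = attr(object, "thresholds"),
              batch_tests = attr(object, "batch_tests"),
              anomalies = table(object$anomaly, useNA = "no"),
              mlrry = summary(object$mlrry))
  class(out) <- "summary.mloy_calls"
  out
}

#' @export
print.summary.mloy_calls <- function(x, ...) {
  cat("mLOY calling summary\n")
  cat(sprintf("  samples: %d, calls: %d (%.2f%%)\n", x$n, x$n_calls,
              100 * x$call_rate))
  cat("  thresholds:", sprintf("%.4f", x$thresholds), "\n")
  if (!is.na(x$batch_tests$ks_p)) {
    cat(sprintf("  batch KS p = %.3g; call-rate p = %.3g\n",
                x$batch_tests$ks_p, x$batch_tests$prop_p))
  }
  if (length(x$anomalies)) print(x$anomalies)
  invisible(x)
}

#' Plot mLRR-Y against PAR1-Bdev with calls and thresholds
#'
#' The standard diagnostic scatter for spotting partial-Y and PAR1-LOH
#' anomalies.
#'
#' @param x An `mloy_calls` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mloy_calls <- function(x, ...) {
  col <- ifelse(!is.na(x$anomaly), "orange",
                ifelse(x$mloy_call, "red", "grey40"))
  graphics::plot(x$mlrry, x$bdev, col = col, pch = 20,
                 xlab = "mLRR-Y", ylab = "PAR1-Bdev", ...)
  graphics::abline(v = attr(x, "thresholds"), lty = 2)
  invisible(x)
}

#' Invert the noise-free mLRR-Y relation to a mosaic cell fraction
#'
#' Utility for tests: `f = 1 - 2^mlrry`, the inverse of
#' `mLRR-Y = log2(1 - f)`.
#'
#' @param mlrry Numeric vector.
#' @return Estimated cell fractions, clipped to \[0, 1\].
#' @export
mlrry_to_fraction <- function(mlrry) pmin(pmax(1 - 2^mlrry, 0), 1)
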