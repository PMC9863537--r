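#' Filter instrument variants against cohort statistics
#'
#' Keeps autosomal variants that are present in the cohort with
#' MAF >= `maf_min` and imputation quality R^2 >= `r2_min`, mirroring the
#' published instrument-construction filter (cohort MAF, not published
#' MAF, is evaluated). One exclusion reason is logged per dropped variant,
#' in the fixed precedence unavailable > sex chromosome > low MAF >
#' low imputation quality.
#'
#' @param weights Instrument-weights data frame (`variant`, `chrom`,
#'   `beta`, ...).
#' @param cohort_stats Data frame with `variant`, `available` (logical),
#'   `maf`, `r2`. Variants missing from the table count as unavailable.
#' @param maf_min Minimum cohort minor-allele frequency.
#' @param r2_min Minimum imputation R^2.
#' @return The surviving rows of `weights`, with the exclusion log (data
#'   frame `variant`, `reason`) in attribute `"exclusions"`.
#' @export
filter_instrument_variants <- function(weights, cohort_stats,
                                       maf_min = 0.01, r2_min = 0.3) {
  if (anyDuplicated(weights$variant)) {
    stop("duplicate variant id in weights: ",
         weights$variant[duplicated(weights$variant)][1], call. = FALSE)
  }
  idx <- match(weights$variant, cohort_stats$variant)
  available <- !is.na(idx)
  if ("available" %in% names(cohort_stats)) {
    available[available] <- cohort_stats$available[idx[available]]
  }
  maf <- rep(NA_real_, nrow(weights))
  r2 <- rep(NA_real_, nrow(weights))
  maf[!is.na(idx)] <- cohort_stats$maf[idx[!is.na(idx)]]
  r2[!is.na(idx)] <- cohort_stats$r2[idx[!is.na(idx)]]

  chrom <- toupper(sub("^chr", "", as.character(weights$chrom)))
  sex_chrom <- chrom %in% c("X", "Y", "23", "24", "XY", "MT", "M")

  reason <- rep(NA_character_, nrow(weights))
  assign_reason <- function(hit, why) {
    hit <- !is.na(hit) & hit & is.na(reason)
    reason[hit] <<- why
  }
  assign_reason(!available, "unavailable")
  assign_reason(sex_chrom, "sex_chromosome")
  assign_reason(maf < maf_min, "low_maf")
  assign_reason(r2 < r2_min, "low_imputation_r2")

  keep <- is.na(reason)
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- data.frame(
    variant = weights$variant[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Compute the polygenic score from dosages and instrument weights
#'
#' The raw score of a sample is the sum over instrument variants of its
#' effect-allele dosage times the published beta. When the cohort counted
#' allele of a variant is the weights' *other* allele, the dosage is
#' flipped to `2 - d` (logged in the `"flipped"` attribute) before
#' weighting. Missing dosages are mean-imputed per variant (logged in
#' `"imputed"`). The standardized score is centred and scaled to SD 1 over
#' the scoring cohort (both sexes).
#'
#' @param dosages Samples x variants numeric matrix of effect-allele
#'   dosages in \[0, 2\]; column names must cover the weights' variants.
#' @param weights Instrument-weights data frame (`variant`, `beta`, and
#'   for orientation checks `effect_allele`/`other_allele`).
#' @param counted_alleles Optional data frame `variant`, `counted_allele`
#'   giving the allele whose dosage the matrix actually counts; used to
#'   resolve orientation.
#' @param standardize Scale the score to mean 0, SD 1?
#' @return Data frame with columns `sample`, `raw`, `std` (class
#'   `prs_vector`), plus attributes `flipped` and `imputed`.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2), 1, dimnames = list("s1", c("v1", "v2", "v3")))
#' w <- data.frame(variant = c("v1", "v2", "v3"), beta = c(0.1, -0.2, 0.3))
#' compute_prs(d, w, standardize = FALSE)$raw
compute_prs <- function(dosages, weights, counted_alleles = NULL,
                        standardize = TRUE) {
  miss <- setdiff(weights$variant, colnames(dosages))
  if (length(miss)) {
    stop("variant(s) in weights absent from dosage matrix: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  if (nrow(weights) == 0L) {
    stop("empty instrument: no variants left to score", call. = FALSE)
  }
  d <- dosages[, weights$variant, drop = FALSE]
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }

  flipped <- character(0)
  if (!is.null(counted_alleles)) {
    idx <- match(weights$variant, counted_alleles$variant)
    ca <- counted_alleles$counted_allele[idx]
    flip <- !is.na(ca) & ca == weights$other_allele
    mismatch <- !is.na(ca) & ca != weights$effect_allele &
      ca != weights$other_allele
    if (any(mismatch)) {
      stop("counted allele matches neither instrument allele for: ",
           paste(weights$variant[mismatch], collapse = ", "), call. = FALSE)
    }
    if (any(flip)) {
      d[, flip] <- 2 - d[, flip]
      flipped <- weights$variant[flip]
    }
  }

  imputed <- character(0)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) {
      d[is.na(d[, j]), j] <- mu[j]
      imputed <- c(imputed, colnames(d)[j])
    }
  }

  raw <- as.vector(d %*% weights$beta)
  std <- rep(NA_real_, length(raw))
  if (standardize) {
    s <- stats::sd(raw)
    if (!is.finite(s) || s == 0) {
      stop("polygenic score has zero variance; cannot standardize",
           call. = FALSE)
    }
    std <- (raw - mean(raw)) / s
  }
  out <- data.frame(sample = rownames(dosages) %||%
                      sprintf("S%05d", seq_along(raw)),
                    raw = raw, std = std, stringsAsFactors = FALSE)
  attr(out, "flipped") <- flipped
  attr(out, "imputed") <- imputed
  class(out) <- c("prs_vector", class(out))
  out
}
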