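#' Simulate instrument genotypes and a weights table
#'
#' Draws Hardy-Weinberg dosages (0/1/2) for independent autosomal
#' instrument variants at allele frequencies uniform in \[0.05, 0.95\],
#' together with an instrument-weights table (effect/other allele, beta,
#' cohort MAF, imputation quality). Betas are drawn from a zero-mean
#' normal law unless a weights table is supplied, in which case its betas
#' and alleles are reused and only the dosages are drawn.
#'
#' Independence between variants mirrors an instrument built from
#' LD-clumped genome-wide significant signals.
#'
#' @param config A [loy_sim_config()].
#' @param weights Optional existing instrument-weights data frame
#'   (columns `variant`, `effect_allele`, `other_allele`, `beta`).
#' @param freqs Optional vector of effect-allele frequencies overriding
#'   the uniform draw (recycled to the number of variants).
#' @param seed Optional seed; by default the caller's RNG state is used.
#' @return A list with `dosages` (samples x variants integer matrix with
#'   sample ids as rownames) and `weights` (data frame: `variant`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `maf`,
#'   `r2`).
#' @export
#' @examples
#' g <- sim_genotypes(loy_sim_config(n_samples = 20, n_instrument_snps = 5,
#'                                   seed = 1))
#' dim(g$dosages)
sim_genotypes <- function(config, weights = NULL, freqs = NULL,
                          seed = NULL) {
  validate_loy_sim_config(config)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(config$n_samples)
  if (n <= 0) stop("sample count must be positive", call. = FALSE)
  m <- as.integer(config$n_instrument_snps)

  if (is.null(freqs)) {
    freqs <- stats::runif(m, 0.05, 0.95)
  } else {
    freqs <- rep_len(freqs, m)
    if (any(freqs < 0 | freqs > 1)) {
      stop("allele frequencies must lie in [0, 1]", call. = FALSE)
    }
  }

  dos <- matrix(stats::rbinom(n * m, size = 2L, prob = rep(freqs, each = n)),
                nrow = n, ncol = m)
  ids <- sprintf("S%05d", seq_len(n))
  rownames(dos) <- ids

  if (is.null(weights)) {
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), "")
    weights <- data.frame(
      variant = sprintf("rs%06d", seq_len(m)),
      chrom = as.character(sample(1:22, m, replace = TRUE)),
      pos = sample.int(2.4e8, m),
      effect_allele = ea,
      other_allele = unname(oa),
      beta = stats::rnorm(m, 0, 0.08),
      stringsAsFactors = FALSE
    )
  } else {
    weights <- as.data.frame(weights)[seq_len(m), , drop = FALSE]
  }
  colnames(dos) <- weights$variant
  # cohort-observed stats for the instrument filter
  weights$maf <- pmin(freqs, 1 - freqs)
  weights$r2 <- stats::runif(m, 0.8, 1)
  list(dosages = dos, weights = weights)
}
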