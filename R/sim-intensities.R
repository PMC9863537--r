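#' Default probe-region manifest (hg19 coordinates)
#'
#' BED-like table of the regions the pipeline distinguishes, with 1-based
#' inclusive coordinates: PAR1 and the X-transposed region (XTR) on
#' chromosome Y, the male-specific region of Y (MSY,
#' chrY:6611498-24510581, i.e. between PAR1 and PAR2 with the XTR
#' excluded), chromosome X, and the autosomes.
#'
#' @return Data frame with columns `chrom`, `start`, `end`, `region`.
#' @export
default_probe_manifest <- function() {
  auto <- data.frame(chrom = as.character(1:22), start = 1L,
                     end = 250000000L, region = "AUTO",
                     stringsAsFactors = FALSE)
  sex <- data.frame(
    chrom = c("Y", "Y", "Y", "X"),
    start = c(60001L, 2699521L, 6611498L, 1L),
    end = c(2699520L, 6611497L, 24510581L, 155270560L),
    region = c("PAR1", "XTR", "MSY", "X"),
    stringsAsFactors = FALSE
  )
  rbind(sex, auto)
}

#' Annotate probes with their manifest region
#'
#' @param probes Data frame with columns `probe`, `chrom`, `pos`.
#' @param manifest Region manifest as from [default_probe_manifest()].
#' @return `probes` with a `region` column (`NA` outside all regions).
#' @export
annotate_probes <- function(probes, manifest) {
  stopifnot(all(c("probe", "chrom", "pos") %in% names(probes)),
            all(c("chrom", "start", "end", "region") %in% names(manifest)))
  region <- rep(NA_character_, nrow(probes))
  for (i in seq_len(nrow(manifest))) {
    hit <- probes$chrom == manifest$chrom[i] &
      probes$pos >= manifest$start[i] & probes$pos <= manifest$end[i] &
      is.na(region)
    region[hit] <- manifest$region[i]
  }
  probes$region <- region
  probes
}

#' Simulate an array probe set over the manifest regions
#'
#' @param config A [loy_sim_config()]; `config$n_probes` gives the counts
#'   per region. Ten probes are additionally placed in the XTR to
#'   exercise its exclusion from mLRR-Y.
#' @param manifest Region manifest.
#' @param seed Optional seed.
#' @return Annotated probe data frame (`probe`, `chrom`, `pos`, `region`).
#' @export
sim_probes <- function(config, manifest = default_probe_manifest(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  np <- config$n_probes
  draw <- function(region, n) {
    rows <- manifest[manifest$region == region, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("empty manifest region: ", region, call. = FALSE)
    }
    idx <- sample.int(nrow(rows), n, replace = TRUE)
    data.frame(chrom = rows$chrom[idx],
               pos = rows$start[idx] +
                 floor(stats::runif(n) * (rows$end[idx] - rows$start[idx])),
               stringsAsFactors = FALSE)
  }
  parts <- rbind(
    cbind(draw("MSY", np[["msy"]]), tag = "msy"),
    cbind(draw("XTR", 10L), tag = "xtr"),
    cbind(draw("PAR1", np[["par1"]]), tag = "par1"),
    cbind(draw("X", np[["x"]]), tag = "x"),
    cbind(draw("AUTO", np[["auto"]]), tag = "auto")
  )
  probes <- data.frame(probe = sprintf("P%05d", seq_len(nrow(parts))),
                       chrom = parts$chrom, pos = as.integer(parts$pos),
                       stringsAsFactors = FALSE)
  annotate_probes(probes, manifest)
}

# per-sample expected Y-probe LRR given integer copies / mosaic fraction
y_centroid_lrr <- function(y_copies, frac, config) {
  out <- numeric(length(y_copies))
  out[y_copies == 0] <- config$lrr_floor
  out[y_copies == 2] <- config$gain_lrr
  one <- y_copies == 1
  val <- config$compression * log2(1 - frac[one])
  # only a complete loss (f = 1) hits the array background floor
  val[!is.finite(val)] <- config$lrr_floor
  out[one] <- val
  out
}

#' Simulate per-probe LRR/BAF intensities
#'
#' Generates the intensity signal the mLOY caller consumes. LRR follows
#' the log2 copy-ratio convention with a male (XY) reference: MSY probes
#' of a male with mosaic LOY fraction `f` are centred at
#' `log2(max(1 - f, eps))`, a single-copy gain sits at `config$gain_lrr`
#' and a zero-copy state at the `config$lrr_floor` background. Every probe
#' receives a per-sample baseline shift (`sample_shift_sd`) plus
#' independent noise (`noise_sd_lrr` times the sample's `lrr_noise_mult`).
#' BAF is ~0.5 (SD `baf_sd`) for heterozygous genotypes and near 0/1
#' otherwise; samples flagged `par1_loh` have their heterozygous PAR1 BAF
#' split to `0.5 +/- config$bdev_loh`.
#'
#' @param truth Data frame with one row per sample: `sample`, `male`,
#'   `karyotype` (XY/XX/XXY/XYY/T21), `loy_cell_fraction`, and optionally
#'   `par1_loh` (logical) and `lrr_noise_mult`.
#' @param probes Annotated probe table from [sim_probes()].
#' @param config A [loy_sim_config()].
#' @param seed Optional seed.
#' @return An object of class `intensity_set`: list with `lrr` and `baf`
#'   (samples x probes matrices), `probes`, and `samples`.
#' @export
sim_intensities <- function(truth, probes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(c("sample", "male", "karyotype", "loy_cell_fraction")
                %in% names(truth)))
  if (nrow(probes) == 0L) stop("empty probe set", call. = FALSE)
  n <- nrow(truth)
  p <- nrow(probes)
  if (is.null(truth$par1_loh)) truth$par1_loh <- FALSE
  if (is.null(truth$lrr_noise_mult)) truth$lrr_noise_mult <- 1

  kar <- truth$karyotype
  y_copies <- ifelse(kar == "XX", 0L, ifelse(kar == "XYY", 2L, 1L))
  x_copies <- ifelse(kar %in% c("XX", "XXY"), 2L, 1L)

  y_lrr <- y_centroid_lrr(y_copies, truth$loy_cell_fraction, config)
  x_lrr <- ifelse(x_copies == 2L, config$gain_lrr, 0)

  shift <- stats::rnorm(n, 0, config$sample_shift_sd)
  # expected value per sample x probe, built region-block-wise
  mu <- matrix(shift, nrow = n, ncol = p)
  region <- probes$region
  ycols <- which(probes$chrom == "Y" & region %in% c("MSY", "XTR"))
  mu[, ycols] <- mu[, ycols] + y_lrr
  xcols <- which(region == "X")
  mu[, xcols] <- mu[, xcols] + x_lrr
  t21 <- if (is.null(truth$t21)) rep(FALSE, n) else truth$t21
  t21cols <- which(region == "AUTO" & probes$chrom == "21")
  if (length(t21cols) && any(t21)) {
    mu[t21, t21cols] <- mu[t21, t21cols] + config$gain_lrr
  }
  noise_sd <- rep(config$noise_sd_lrr * truth$lrr_noise_mult, p)
  lrr <- mu + stats::rnorm(n * p, 0, noise_sd)

  # BAF: population allele frequency per probe, HW heterozygosity
  pb <- stats::runif(p, 0.1, 0.9)
  het <- matrix(stats::runif(n * p) < rep(2 * pb * (1 - pb), each = n),
                nrow = n)
  # hemizygous and zero-copy regions cannot be heterozygous
  het[, ycols] <- FALSE
  het[x_copies == 1L, xcols] <- FALSE
  homb <- matrix(stats::runif(n * p) < rep(pb, each = n), nrow = n)
  baf <- ifelse(homb, 1, 0) +
    stats::rnorm(n * p, 0, config$baf_sd / 3)
  split_sign <- matrix(sign(stats::runif(n * p) - 0.5), nrow = n)
  dev <- matrix(0, n, p)
  p1cols <- which(region == "PAR1")
  if (any(truth$par1_loh)) {
    dev[truth$par1_loh, p1cols] <-
      split_sign[truth$par1_loh, p1cols] * config$bdev_loh
  }
  baf[het] <- 0.5 + dev[het] + stats::rnorm(sum(het), 0, config$baf_sd)
  baf <- pmin(pmax(baf, 0), 1)

  structure(list(lrr = `dimnames<-`(lrr, list(truth$sample, probes$probe)),
                 baf = `dimnames<-`(baf, list(truth$sample, probes$probe)),
                 probes = probes,
                 samples = truth$sample),
            class = "intensity_set")
}

#' @export
print.intensity_set <- function(x, ...) {
  cat("<intensity_set> ", length(x$samples), " samples x ",
      nrow(x$probes), " probes (",
      paste(names(table(x$probes$region)), table(x$probes$region),
            sep = ":", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Convert between the matrix and long tabular intensity representations
#'
#' The long format is one row per (sample, probe) with columns `sample`,
#' `probe`, `chrom`, `pos`, `lrr`, `baf` — the TSV format read by
#' [read_intensities()].
#'
#' @param x An `intensity_set`.
#' @return A long-format data frame.
#' @export
as_intensity_table <- function(x) {
  stopifnot(inherits(x, "intensity_set"))
  n <- length(x$samples); p <- nrow(x$probes)
  data.frame(
    sample = rep(x$samples, times = p),
    probe = rep(x$probes$probe, each = n),
    chrom = rep(x$probes$chrom, each = n),
    pos = rep(x$probes$pos, each = n),
    lrr = as.vector(x$lrr),
    baf = as.vector(x$baf),
    stringsAsFactors = FALSE
  )
}

#' Assemble an `intensity_set` from a long intensity table
#'
#' @param tab Long-format intensity table (`sample`, `probe`, `chrom`,
#'   `pos`, `lrr`, `baf`).
#' @param manifest Region manifest used to annotate probes.
#' @return An `intensity_set`.
#' @export
as_intensity_set <- function(tab, manifest = default_probe_manifest()) {
  need <- c("sample", "probe", "chrom", "pos", "lrr", "baf")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  samples <- unique(tab$sample)
  probes <- unique(tab[c("probe", "chrom", "pos")])
  probes <- annotate_probes(probes, manifest)
  si <- match(tab$sample, samples)
  pi <- match(tab$probe, probes$probe)
  lrr <- matrix(NA_real_, length(samples), nrow(probes),
                dimnames = list(samples, probes$probe))
  baf <- lrr
  lrr[cbind(si, pi)] <- tab$lrr
  baf[cbind(si, pi)] <- tab$baf
  structure(list(lrr = lrr, baf = baf, probes = probes, samples = samples),
            class = "intensity_set")
}
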