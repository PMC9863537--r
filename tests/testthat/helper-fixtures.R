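# Shared fixtures, all generated in code.

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 400, seed = 1,
         n_probes = c(msy = 30, par1 = 15, x = 15, auto = 1000)),
    list(...))
  do.call(loy_sim_config, args)
}

# truth table for intensity simulation with planted cell fractions
make_truth <- function(fractions, male = TRUE, karyotype = "XY",
                       par1_loh = FALSE) {
  n <- length(fractions)
  data.frame(sample = sprintf("T%04d", seq_len(n)),
             male = rep_len(male, n),
             karyotype = rep_len(karyotype, n),
             loy_cell_fraction = fractions,
             par1_loh = rep_len(par1_loh, n),
             stringsAsFactors = FALSE)
}

# 20-sample QC fixture with six planted violations, one per cascade rule
# (reference PC moments supplied, as from an external reference panel)
make_qc_fixture <- function() {
  n <- 20
  ids <- sprintf("Q%02d", seq_len(n))
  set.seed(42)
  stats <- data.frame(
    sample = ids,
    call_rate = 0.99,
    het_rate = 0.33,
    mean_lrr_x = rnorm(n, 0, 0.02),
    mean_lrr_y = rnorm(n, 0, 0.02),
    lrr_sd = 0.2,
    pc1 = seq(-1, 1, length.out = n),
    pc2 = seq(1, -1, length.out = n),
    chromosomopathy = FALSE,
    stringsAsFactors = FALSE
  )
  planted <- c(Q02 = "karyotype", Q04 = "relatedness", Q06 = "call_rate",
               Q08 = "heterozygosity", Q10 = "ancestry", Q12 = "lrr_sd")
  stats[stats$sample == "Q02", c("mean_lrr_x", "mean_lrr_y")] <-
    c(0.55, -3)                              # XX
  stats$call_rate[stats$sample == "Q04"] <- 0.975  # lower of the pair
  stats$call_rate[stats$sample == "Q06"] <- 0.95
  stats$het_rate[stats$sample == "Q08"] <- 0.41
  stats$pc1[stats$sample == "Q10"] <- 8
  stats$lrr_sd[stats$sample == "Q12"] <- 0.6
  kinship <- data.frame(sample1 = "Q04", sample2 = "Q05", kinship = 0.05,
                        stringsAsFactors = FALSE)
  thresholds <- qc_thresholds(pc_center = c(0, 0), pc_scale = c(0.6, 0.6))
  list(stats = stats, kinship = kinship, thresholds = thresholds,
       planted = planted)
}

# independent brute-force oracles
bf_trimmed_mean <- function(x, trim = 0.05) {
  k <- floor(length(x) * trim)
  s <- sort(x)
  mean(s[(k + 1):(length(s) - k)])
}

bf_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(ecdf(x)(pts) - ecdf(y)(pts)))
}

bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

bf_prs <- function(dosages, betas) {
  out <- numeric(nrow(dosages))
  for (s in seq_len(nrow(dosages))) {
    acc <- 0
    for (v in seq_along(betas)) acc <- acc + dosages[s, v] * betas[v]
    out[s] <- acc
  }
  out
}
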