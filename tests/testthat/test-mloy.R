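make_intensity_set <- function(lrr, baf, probes) {
  structure(list(lrr = lrr, baf = baf, probes = probes,
                 samples = rownames(lrr)),
            class = "intensity_set")
}

test_that("mLRR-Y subtracts the trimmed autosomal mean from the MSY mean", {
  probes <- data.frame(
    probe = sprintf("p%02d", 1:25),
    chrom = c(rep("Y", 5), rep("1", 20)),
    pos = c(seq(7e6, 8e6, length.out = 5), seq_len(20) * 1e6),
    region = c(rep("MSY", 5), rep("AUTO", 20)),
    stringsAsFactors = FALSE)
  lrr <- matrix(c(rep(-0.80, 5), rep(-0.05, 20)), nrow = 1,
                dimnames = list("s1", probes$probe))
  it <- make_intensity_set(lrr, lrr * 0 + 0.5, probes)
  expect_equal(unname(compute_mlrry(it, min_msy = 5, min_auto = 20)),
               -0.75)
  # integers 1..20 as autosomal probes: 5% per-tail trim removes 1 and 20
  lrr2 <- matrix(c(rep(0, 5), 1:20), nrow = 1,
                 dimnames = list("s1", probes$probe))
  it2 <- make_intensity_set(lrr2, lrr2 * 0 + 0.5, probes)
  expect_equal(unname(compute_mlrry(it2, min_msy = 5, min_auto = 20)),
               0 - 10.5)
  expect_error(compute_mlrry(it, min_msy = 50), "too few probes")
})

test_that("XTR probes are excluded from the MSY mean", {
  probes <- data.frame(
    probe = sprintf("p%02d", 1:30),
    chrom = c(rep("Y", 10), rep("1", 20)),
    pos = c(seq(7e6, 8e6, length.out = 5), seq(3e6, 5e6, length.out = 5),
            seq_len(20) * 1e6),
    stringsAsFactors = FALSE)
  probes <- annotate_probes(probes, default_probe_manifest())
  expect_equal(probes$region[6:10], rep("XTR", 5))
  lrr <- matrix(c(rep(-1, 5), rep(99, 5), rep(0, 20)), nrow = 1,
                dimnames = list("s1", probes$probe))
  it <- make_intensity_set(lrr, lrr * 0 + 0.5, probes)
  expect_equal(unname(compute_mlrry(it, min_msy = 5, min_auto = 20)), -1)
})

test_that("trimmed mean matches a brute-force oracle", {
  expect_equal(trimmed_mean(1:20, 0.05), 10.5)
  set.seed(11)
  for (i in 1:100) {
    x <- rnorm(sample(20:200, 1))
    expect_identical(trimmed_mean(x, 0.05), bf_trimmed_mean(x, 0.05))
  }
})

test_that("PAR1-Bdev is the mean absolute deviation of het BAF from 0.5", {
  expect_equal(compute_par1_bdev(c(0.40, 0.60, 0.35, 0.65, 0.5),
                                 min_het = 5), 0.10,
               ignore_attr = TRUE)
  expect_equal(compute_par1_bdev(rep(0.5, 10)), 0, ignore_attr = TRUE)
  # homozygous BAF (outside the het window) never contributes
  expect_equal(compute_par1_bdev(c(0.45, 0.55, 0.5, 0.52, 0.48,
                                   0, 0, 1, 1, 0.05)),
               mean(abs(c(0.45, 0.55, 0.5, 0.52, 0.48) - 0.5)),
               ignore_attr = TRUE)
  few <- compute_par1_bdev(c(0.5, 0.5, 0.5))
  expect_true(is.na(few))
  expect_match(attr(few, "reason"), "too few")
})

test_that("threshold matches the half-normal closed form on null cohorts", {
  set.seed(21)
  sigma <- 0.1
  x <- rnorm(10000, 0, sigma)
  res <- call_mloy_threshold(x)
  expect_equal(res$threshold, -sigma * qnorm(0.995), tolerance = 0.05)
  expect_lte(mean(res$calls), 0.007)
  expect_lt(res$threshold, median(x))
  res_hn <- call_mloy_threshold(x, method = "halfnormal")
  expect_equal(res_hn$threshold, -sigma * qnorm(0.995), tolerance = 0.05)
  expect_error(call_mloy_threshold(rep(1, 500)), "degenerate")
  expect_error(call_mloy_threshold(rnorm(50)), "too small")
})

test_that("threshold is shift-equivariant and calls are unchanged", {
  set.seed(22)
  x <- rnorm(2000, 0, 0.1)
  x[1:100] <- x[1:100] - 0.8
  a <- call_mloy_threshold(x)
  b <- call_mloy_threshold(x + 0.3)
  expect_equal(b$threshold, a$threshold + 0.3, tolerance = 1e-12)
  expect_identical(a$calls, b$calls)
})

test_that("calls are monotone in the mosaic fraction", {
  cfg <- small_config(noise_sd_lrr = 1e-6, sample_shift_sd = 0)
  set.seed(23)
  f <- c(rep(0, 300), runif(100, 0.05, 0.9))
  truth <- make_truth(f)
  probes <- sim_probes(cfg, seed = 23)
  it <- sim_intensities(truth, probes, cfg, seed = 23)
  ml <- compute_mlrry(it, min_auto = 500)
  res <- call_mloy_threshold(ml, min_n = 100)
  called_f <- f[res$calls]
  if (length(called_f) && any(!res$calls)) {
    expect_gt(min(called_f), max(f[!res$calls & f > 0], 0))
  }
  expect_false(any(res$calls[f == 0]))
})

test_that("batch splitting is seeded and reduces to pooled calling", {
  set.seed(24)
  x <- setNames(rnorm(1000, 0, 0.1), sprintf("s%04d", 1:1000))
  one <- call_mloy(x, n_batches = 1, seed = 5)
  pooled <- call_mloy_threshold(x)
  expect_equal(unique(one$threshold), pooled$threshold)
  expect_identical(one$mloy_call, unname(pooled$calls))
  a <- call_mloy(x, n_batches = 2, seed = 6)
  b <- call_mloy(x, n_batches = 2, seed = 6)
  expect_identical(a$batch, b$batch)
  expect_error(call_mloy(x[1:150], n_batches = 2, seed = 1), "too small")
})

test_that("batch-effect p-values are null-calibrated on homogeneous cohorts", {
  set.seed(25)
  ps <- replicate(200, {
    x <- setNames(rnorm(1000, 0, 0.1), sprintf("s%04d", 1:1000))
    attr(call_mloy(x, n_batches = 2, seed = sample.int(1e6, 1)),
         "batch_tests")$ks_p_raw[1]
  })
  expect_gt(suppressWarnings(ks.test(ps, punif)$p.value), 0.01)
})

test_that("anomaly flags pick out planted PAR1-LOH samples", {
  set.seed(26)
  calls <- data.frame(sample = sprintf("s%03d", 1:200),
                      mlrry = rnorm(200, 0, 0.05),
                      bdev = abs(rnorm(200, 0.01, 0.003)),
                      mloy_call = FALSE, batch = 1L, threshold = -0.13,
                      anomaly = NA_character_, stringsAsFactors = FALSE)
  calls$bdev[7] <- 0.15
  fl <- flag_anomalies(calls)
  expect_equal(which(!is.na(fl$anomaly)), 7L)
  expect_equal(fl$anomaly[7], "par1_loh")
  # constant Bdev or k = Inf disable the rule
  same <- calls; same$bdev <- 0.01
  expect_true(all(is.na(flag_anomalies(same)$anomaly)))
  expect_true(all(is.na(flag_anomalies(calls, k = Inf)$anomaly)))
  # partial-loss band flags intermediate mLRR-Y
  fl2 <- flag_anomalies(calls, partial_band = c(-0.4, -0.12))
  expect_true(all(calls$mlrry[!is.na(fl2$anomaly) &
                                fl2$anomaly == "partial_y"] >= -0.4))
})

test_that("sign harmonisation flips every reported effect exactly", {
  set.seed(27)
  n <- 600
  d <- data.frame(mlrry = rnorm(n, 0, 0.1), age = runif(n, 60, 90),
                  apoe = sample(-2:2, n, TRUE))
  d$ad <- rbinom(n, 1, plogis(-2 * d$mlrry + 0.05 * (d$age - 75)))
  d$x_pos <- harmonise_mlrry(d$mlrry)
  d$x_neg <- d$mlrry
  a <- fit_case_control(d, "x_pos")
  b <- fit_case_control(d, "x_neg")
  expect_equal(a$estimate, -b$estimate, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("mlrry_to_fraction inverts the noise-free relation", {
  f <- c(0, 0.25, 0.5, 0.9)
  expect_equal(mlrry_to_fraction(log2(1 - f)), f, tolerance = 1e-12)
})
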