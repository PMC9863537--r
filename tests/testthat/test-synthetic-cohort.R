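test_that("generator is deterministic under a fixed seed", {
  cfg <- small_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$truth, b$truth)
  expect_identical(a$intensities$lrr, b$intensities$lrr)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$proteome, b$proteome)
})

test_that("genotype dosages follow Hardy-Weinberg expectations", {
  cfg <- loy_sim_config(n_samples = 50000, n_instrument_snps = 2, seed = 4)
  g <- sim_genotypes(cfg, freqs = c(1.0, 0.3), seed = 4)
  expect_true(all(g$dosages[, 1] == 2))
  expect_equal(mean(g$dosages[, 2]), 0.6, tolerance = 0.02)
  expect_error(sim_genotypes(loy_sim_config(n_samples = 0)),
               "positive")
})

test_that("mLOY prevalence is calibrated to target in 65-85 males", {
  cfg <- loy_sim_config(n_samples = 60000, sex_ratio = 1, seed = 2)
  set.seed(2)
  prs <- rnorm(60000)
  ages <- runif(60000, 60, 95)
  loy <- sim_mloy_status(cfg, prs, ages, rep(TRUE, 60000))
  win <- ages >= 65 & ages <= 85
  expect_lt(abs(mean(loy$loy[win]) - 0.189), 0.005)
})

test_that("null liability model gives uniform prevalence in age", {
  cfg <- loy_sim_config(n_samples = 40000, sex_ratio = 1,
                        prs_or_per_sd = 1, age_or_per_year = 1, seed = 3)
  set.seed(3)
  prs <- rnorm(40000)
  ages <- runif(40000, 60, 95)
  loy <- sim_mloy_status(cfg, prs, ages, rep(TRUE, 40000))
  bands <- cut(ages, c(60, 70, 80, 95))
  rates <- tapply(loy$loy, bands, mean)
  expect_true(all(abs(rates - 0.189) < 0.02))
})

test_that("females carry no LOY and carrier fractions are positive", {
  cfg <- loy_sim_config(n_samples = 2000, seed = 5)
  set.seed(5)
  loy_f <- sim_mloy_status(cfg, rnorm(2000), runif(2000, 60, 95),
                           rep(FALSE, 2000))
  expect_true(all(!loy_f$loy))
  expect_true(all(loy_f$loy_cell_fraction == 0))
  set.seed(5)
  loy_m <- sim_mloy_status(cfg, rnorm(2000), runif(2000, 60, 95),
                           rep(TRUE, 2000))
  expect_true(all(loy_m$loy_cell_fraction[loy_m$loy] > 0))
  rng <- cfg$cell_fraction_range
  expect_true(all(loy_m$loy_cell_fraction[loy_m$loy] >= rng[1] &
                    loy_m$loy_cell_fraction[loy_m$loy] <= rng[2]))
})

test_that("calibration failure reports the bracketing interval", {
  cfg <- loy_sim_config(n_samples = 100, seed = 1)
  expect_error(sim_mloy_status(cfg, rnorm(100), rep(50, 100),
                               rep(TRUE, 100)),
               "no males aged 65-85")
})

test_that("expected MSY LRR is strictly decreasing in cell fraction", {
  f <- seq(0, 0.95, by = 0.05)
  cfg <- small_config(noise_sd_lrr = 0, sample_shift_sd = 0)
  truth <- make_truth(f)
  probes <- sim_probes(cfg, seed = 1)
  it <- sim_intensities(truth, probes, cfg, seed = 1)
  ml <- compute_mlrry(it, min_auto = 500)
  expect_true(all(diff(ml) < 0))
})

test_that("noise-free intensities hit the log2 copy-ratio centroids", {
  cfg <- small_config(noise_sd_lrr = 0, sample_shift_sd = 0, baf_sd = 0)
  truth <- make_truth(c(0, 0.5), karyotype = "XY")
  probes <- sim_probes(cfg, seed = 2)
  it <- sim_intensities(truth, probes, cfg, seed = 2)
  ml <- compute_mlrry(it, min_auto = 500)
  expect_equal(unname(ml[1]), 0, tolerance = 1e-12)
  expect_equal(unname(ml[2]), -1, tolerance = 1e-12)
  # XX: Y probes at the background floor, X probes at the gain level
  tr2 <- make_truth(0, male = FALSE, karyotype = "XX")
  it2 <- sim_intensities(tr2, probes, cfg, seed = 3)
  st <- intensity_sample_stats(it2)
  expect_equal(st$mean_lrr_y, -3, tolerance = 1e-12)
  expect_equal(st$mean_lrr_x, 0.55, tolerance = 1e-12)
})

test_that("planted PAR1-LOH round-trips through compute_par1_bdev", {
  cfg <- small_config(n_probes = c(msy = 30, par1 = 60, x = 15,
                                   auto = 1000))
  truth <- make_truth(rep(0, 40), par1_loh = c(TRUE, rep(FALSE, 39)))
  probes <- sim_probes(cfg, seed = 4)
  it <- sim_intensities(truth, probes, cfg, seed = 4)
  bdev <- compute_par1_bdev(it)
  expect_equal(unname(bdev[1]), 0.15, tolerance = 0.07)
  expect_lt(max(bdev[-1]), 0.07)
})

test_that("null conversion model covers HR 1 and generator effects recover", {
  cfg <- loy_sim_config(n_samples = 6000, seed = 7,
                        conversion_hr_per_sd_male = 1.0,
                        conversion_hr_per_sd_female = 1.0)
  set.seed(7)
  truth <- data.frame(sample = sprintf("S%05d", 1:6000),
                      male = runif(6000) < 0.5,
                      age = runif(6000, 60, 95),
                      prs = rnorm(6000), loy_burden = 0,
                      stringsAsFactors = FALSE)
  ph <- sim_phenotypes(truth, cfg, seed = 7)
  ph$prs <- truth$prs
  men <- ph[ph$male & ph$mci, ]
  r <- fit_conversion(men, "prs", outcome = "dementia",
                      covariates = c("age", "apoe"))
  expect_true(r$ci_lo < 0 && r$ci_hi > 0)
})

test_that("tau is independent of mLOY when its burden coefficient is zero", {
  cfg <- loy_sim_config(n_samples = 3000, seed = 8, tau_per_loy = 0)
  set.seed(8)
  truth <- data.frame(sample = sprintf("S%05d", 1:3000), male = TRUE,
                      age = runif(3000, 60, 95), prs = rnorm(3000),
                      loy_burden = rexp(3000, 5),
                      stringsAsFactors = FALSE)
  ph <- sim_phenotypes(truth, cfg, seed = 8)
  ph$loy_exposure <- truth$loy_burden
  ph$syndrome <- rep(c("MCI", "dementia"), length.out = 3000)
  fb <- fit_biomarker(ph, "csf_tau", "loy_exposure")
  expect_true(fb$meta$ci_lo < 0 && fb$meta$ci_hi > 0)
})

test_that("config validation rejects impossible settings", {
  expect_error(loy_sim_config(target_mloy_prevalence = 1.2), "rates")
  expect_error(loy_sim_config(prs_or_per_sd = -1), "ratios")
  expect_error(loy_sim_config(conv_base_hazard = -0.1), "hazard")
  expect_error(loy_sim_config(n_samples = 0), "n_samples")
})

test_that("config round-trips through YAML", {
  cfg <- small_config(prs_or_per_sd = 2.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$prs_or_per_sd, 2.2)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
})
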