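test_that("APOE scoring counts e4 minus e2 alleles", {
  expect_equal(apoe_score(c("e3/e3", "e2/e4", "e4/e4", "e2/e2", "e2/e3",
                            "e3/e4")),
               c(0L, 0L, 2L, -2L, -1L, 1L))
  expect_equal(apoe_score("E3|E4"), 1L)
  expect_error(apoe_score("e3/e5"), "unknown APOE")
  expect_error(apoe_score("e3"), "unknown APOE")
})

test_that("logistic MLE on a 2x2 table equals the closed-form odds ratio", {
  d <- data.frame(x = rep(c(1, 1, 0, 0), c(20, 10, 10, 20)),
                  ad = rep(c(1, 0, 1, 0), c(20, 10, 10, 20)))
  r <- fit_case_control(d, "x", covariates = character(0))
  expect_equal(exp(r$estimate), 4.0, tolerance = 1e-6)
  # agreement with the closed-form Wald SE of a 2x2 table
  expect_equal(r$se, sqrt(1 / 20 + 1 / 10 + 1 / 10 + 1 / 20),
               tolerance = 1e-6)
})

test_that("case-control test is calibrated under a permuted exposure", {
  set.seed(41)
  n <- 400
  base <- data.frame(age = runif(n, 60, 90), apoe = sample(-2:2, n, TRUE))
  base$ad <- rbinom(n, 1, plogis(-3 + 0.05 * base$age))
  rej <- mean(replicate(200, {
    base$x <- rnorm(n)
    fit_case_control(base, "x")$p < 0.05
  }))
  expect_gt(rej, 0.015)
  expect_lt(rej, 0.105)
})

test_that("separation is flagged, not silently returned", {
  d <- data.frame(x = c(rep(0, 20), rep(10, 20)),
                  ad = c(rep(0, 20), rep(1, 20)))
  r <- fit_case_control(d, "x", covariates = character(0))
  expect_true(r$separation)
})

test_that("Cox models are null-calibrated and scale-invariant", {
  set.seed(42)
  n <- 3000
  d <- data.frame(x = rnorm(n), age = runif(n, 60, 90),
                  apoe = sample(-2:2, n, TRUE), cohort = "A",
                  time = rexp(n, 0.1), event_dementia = runif(n) < 0.5)
  d$event_ad <- d$event_dementia
  r <- fit_conversion(d, "x", outcome = "dementia",
                      covariates = c("age", "apoe"))
  expect_true(r$ci_lo < 0 && r$ci_hi > 0)
  d2 <- d; d2$time <- d$time * 2
  r2 <- fit_conversion(d2, "x", outcome = "dementia",
                       covariates = c("age", "apoe"))
  expect_equal(r2$estimate, r$estimate, tolerance = 1e-9)
  expect_equal(r2$se, r$se, tolerance = 1e-9)

  d3 <- d; d3$event_dementia <- FALSE
  expect_error(fit_conversion(d3, "x", outcome = "dementia",
                              covariates = c("age", "apoe")), "no events")
  d4 <- d; d4$time[1] <- 0
  expect_error(fit_conversion(d4, "x", outcome = "dementia",
                              covariates = c("age", "apoe")), "positive")
})

test_that("AD-specific conversion censors non-AD dementia converters", {
  set.seed(43)
  n <- 500
  d <- data.frame(x = rnorm(n), age = 75, apoe = 0, cohort = "A",
                  time = rexp(n, 0.2),
                  event_dementia = runif(n) < 0.8)
  d$event_ad <- d$event_dementia & runif(n) < 0.5
  r_ad <- fit_conversion(d, "x", outcome = "ad", covariates = "age")
  r_dem <- fit_conversion(d, "x", outcome = "dementia", covariates = "age")
  expect_equal(r_ad$n, r_dem$n)  # same risk sets, fewer events
  expect_gt(r_ad$se, r_dem$se)
})

test_that("KS and ANCOVA match reference implementations", {
  set.seed(44)
  x <- c(rnorm(150, 0, 0.1), rnorm(120, -0.08, 0.12))
  grp <- rep(c("control", "case"), c(150, 120))
  age <- runif(270, 60, 90)
  apoe <- sample(-2:2, 270, TRUE)
  res <- distribution_tests(x, grp, age, apoe)
  expect_equal(res$ks_D, bf_ks_D(x[grp == "case"], x[grp == "control"]),
               tolerance = 1e-8)
  ref_ks <- suppressWarnings(ks.test(x[grp == "case"],
                                     x[grp == "control"]))
  expect_equal(res$ks_p, ref_ks$p.value, tolerance = 1e-8)
  ref_an <- anova(lm(x ~ age + apoe), lm(x ~ factor(grp) + age + apoe))
  expect_equal(res$ancova_F, ref_an$F[2], tolerance = 1e-8)
  expect_equal(res$ancova_p, ref_an$`Pr(>F)`[2], tolerance = 1e-8)

  expect_equal(distribution_tests(rep(c(1, 2), 50), rep(c("a", "b"), 50),
                                  runif(100), runif(100))$ks_D, 1)
  expect_error(distribution_tests(x, rep("one", 270), age, apoe),
               "two groups")
  expect_error(distribution_tests(c(1, 2, 3, 4), c("a", "a", "a", "b"),
                                  runif(4), runif(4)), "at least 3")
})

test_that("identical samples give KS D of zero", {
  x <- rnorm(50)
  res <- distribution_tests(c(x, x), rep(c("a", "b"), each = 50),
                            runif(100), runif(100))
  expect_equal(res$ks_D, 0)
})

test_that("IVW meta-analysis matches closed forms and metafor", {
  m <- ivw_meta(c(1, 3), c(1, 1))
  expect_equal(m$estimate, 2)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-12)

  m2 <- ivw_meta(c(0.7, 0.7), c(0.2, 0.2))
  expect_equal(m2$estimate, 0.7)
  expect_equal(m2$se, 0.2 / sqrt(2), tolerance = 1e-12)

  m3 <- ivw_meta(c(0.5, 99), c(0.1, 1e6))
  expect_equal(m3$estimate, 0.5, tolerance = 1e-6)
  expect_lte(m3$se, 0.1)

  skip_if_not_installed("metafor")
  set.seed(45)
  b <- rnorm(5); s <- runif(5, 0.1, 0.5)
  ref <- metafor::rma.uni(yi = b, sei = s, method = "FE")
  mine <- ivw_meta(b, s)
  expect_equal(mine$estimate, as.numeric(ref$beta), tolerance = 1e-10)
  expect_equal(mine$se, ref$se, tolerance = 1e-10)
  expect_equal(mine$p, ref$pval, tolerance = 1e-10)

  expect_error(ivw_meta(c(1, 2), c(0, 1)), "positive")
  expect_error(ivw_meta(1, 0.1), "at least two")
})

test_that("PC selection keeps outcome-associated components", {
  set.seed(46)
  n <- 500
  pcs <- data.frame(pc1 = rnorm(n), pc2 = rnorm(n))
  y <- pcs$pc1 + rnorm(n, 0, 0.1)
  expect_true("pc1" %in% select_pcs(pcs, y))
  expect_equal(sort(select_pcs(pcs, y, threshold = 1)),
               c("pc1", "pc2"))
  # null calibration: selection rate approximates the threshold
  hits <- replicate(100, {
    y0 <- rbinom(200, 1, 0.4)
    length(select_pcs(data.frame(pc1 = rnorm(200), pc2 = rnorm(200),
                                 pc3 = rnorm(200)), y0))
  })
  rate <- sum(hits) / 300
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.10)
})

test_that("the MR grid has the expected shape and emits reasons", {
  cfg <- small_config(n_samples = 1200, seed = 47)
  coh <- simulate_cohort(cfg)
  qc <- qc_filter_samples(coh$qc_stats, coh$kinship)
  men <- qc$sample[!qc$excluded]
  it <- mloymr:::subset_intensities(coh$intensities, men)
  calls <- flag_anomalies(call_mloy(compute_mlrry(it),
                                    compute_par1_bdev(it),
                                    n_batches = 1, seed = 1))
  w <- coh$weights
  stats <- data.frame(variant = w$variant, available = TRUE, maf = w$maf,
                      r2 = w$r2)
  prs <- compute_prs(coh$dosages, filter_instrument_variants(w, stats))
  grid <- run_mr_suite(coh$phenotypes, prs = prs, calls = calls)
  expect_true(all(c("model", "exposure", "stratum", "estimate", "se",
                    "p") %in% names(grid)))
  # phenotype exposures: 6 logistic + META + 2 cox, each of 2 exposures
  expect_equal(sum(grid$exposure == "mLRR-Y"), 9)
  expect_equal(sum(grid$exposure == "mloy_call"), 9)
  # score exposure: 3 strata x (1 logistic + 2 cox)
  expect_equal(sum(grid$exposure == "prs"), 9)
  expect_true(any(grid$stratum == "men_META"))
  # an empty stratum yields a missing row with a reason, not an error
  women_only <- coh$phenotypes[!coh$phenotypes$male, ]
  g2 <- run_mr_suite(women_only, prs = prs, calls = calls)
  men_rows <- g2[g2$stratum == "men" & g2$exposure == "prs", ]
  expect_true(all(is.na(men_rows$estimate)))
  expect_true(all(nzchar(men_rows$covariates)))
})

test_that("the polygenic score is orthogonal to age by construction", {
  cfg <- loy_sim_config(n_samples = 5000, seed = 48)
  coh <- simulate_cohort(cfg)
  ct <- cor.test(coh$truth$prs, coh$truth$age)
  expect_gt(ct$p.value, 0.001)
  expect_lt(abs(ct$estimate), 0.05)
})
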