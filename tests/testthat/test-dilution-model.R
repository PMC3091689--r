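test_that("noiseless dilution data are recovered exactly", {
  cc <- rep(c(0, .25, .5, .75, 1), each = 2)
  y <- log2(cc * 900 + 100)
  f <- fit_dilution(y, cc)
  expect_equal(f$delta_hat, 900, tolerance = 1e-6)
  expect_equal(f$b_hat, 100, tolerance = 1e-6)
  expect_true(f$converged)

  # null case: flat data identify Delta = 0 at the common level
  f0 <- fit_dilution(rep(log2(100), 6), rep(c(0, .5, 1), 2))
  expect_equal(f0$delta_hat, 0, tolerance = 1e-9)
  expect_equal(f0$b_hat, 100, tolerance = 1e-6)

  # negative Delta (Brain brighter than UHRR)
  yn <- log2(cc * (-150) + 200)
  fn <- fit_dilution(yn, cc)
  expect_equal(fn$delta_hat, -150, tolerance = 1e-6)
  expect_equal(fn$b_hat, 200, tolerance = 1e-6)

  expect_error(fit_dilution(c(1, 2, 3), rep(0.5, 3)), "unidentifiable")
  expect_error(fit_dilution(c(1, 2), c(0, 1)), "at least 3")
})

test_that("equal weights reproduce the unweighted fit", {
  set.seed(77)
  cc <- canonical_cc()
  for (i in 1:10) {
    y <- log2(cc * runif(1, -100, 900) + runif(1, 100, 500)) +
      rnorm(18, 0, 0.2)
    f1 <- fit_dilution(y, cc)
    f2 <- fit_dilution(y, cc, w = rep(7, 18))
    expect_equal(f1$delta_hat, f2$delta_hat, tolerance = 1e-6)
    expect_equal(f1$b_hat, f2$b_hat, tolerance = 1e-6)
    expect_equal(f1$se_delta, f2$se_delta, tolerance = 1e-6)
  }
})

test_that("estimates and standard errors agree with nls on weighted fits", {
  set.seed(123)
  cc <- canonical_cc()
  n_ok <- 0
  for (i in 1:12) {
    B <- runif(1, 100, 1000)
    D <- if (runif(1) < 0.3) -runif(1, 0.1, 0.8) * B else runif(1, 0.2, 5) * B
    y <- log2(cc * D + B) + rnorm(18, 0, 0.05)
    w <- pmax(rpois(18, 20), 1)
    ref <- tryCatch(
      nls(y ~ log2(cc * d + b), start = list(d = D, b = B), weights = w),
      error = function(e) NULL)
    if (is.null(ref)) next
    co <- summary(ref)$coefficients
    f <- fit_dilution(y, cc, w)
    expect_equal(f$delta_hat, unname(co["d", "Estimate"]), tolerance = 1e-4)
    expect_equal(f$b_hat, unname(co["b", "Estimate"]), tolerance = 1e-4)
    expect_equal(f$se_delta, unname(co["d", "Std. Error"]), tolerance = 1e-3)
    expect_equal(f$p_value, unname(co["d", "Pr(>|t|)"]), tolerance = 1e-3)
    n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 8)
})

test_that("the dilution estimator is unbiased with calibrated intervals", {
  set.seed(2024)
  cc <- canonical_cc()
  n_rep <- 400
  dhat <- se <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    y <- log2(cc * 300 + 200) + rnorm(18, 0, 0.1)
    w <- pmax(rpois(18, 20), 1)
    f <- fit_dilution(y, cc, w)
    dhat[i] <- f$delta_hat; se[i] <- f$se_delta
  }
  mc_se <- sd(dhat) / sqrt(n_rep)
  expect_lt(abs(mean(dhat) - 300), 2 * mc_se)
  coverage <- mean(abs(dhat - 300) <= 1.96 * se)
  expect_gte(coverage, 0.92)
  expect_lte(coverage, 0.98)
})

test_that("the Wald test is symmetric and handles degenerate fits", {
  cc <- canonical_cc()
  set.seed(55)
  y <- log2(cc * 300 + 200) + rnorm(18, 0, 0.1)
  f <- fit_dilution(y, cc)
  expect_equal(test_delta(f), f$p_value)
  f_neg <- f
  f_neg$delta_hat <- -f$delta_hat
  f_neg$t_stat <- -f$t_stat
  expect_equal(test_delta(f_neg), test_delta(f))

  f_null <- f; f_null$delta_hat <- 0
  expect_equal(test_delta(f_null), 1)
  f_deg <- f; f_deg$se_delta <- 0
  p <- test_delta(f_deg)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
})

test_that("fit_all keeps per-bead-type bookkeeping straight", {
  cfg <- small_config(n_bead_types = 150, seed = 12)
  sim <- simulate_experiment(cfg)
  em <- preprocess_experiment(sim$sections, sim$annotation)
  emn <- quantile_normalize(em, setNames(sim$design$quantity_ng,
                                         sim$design$section_id))
  group <- analysis_group_filter(sim$annotation, em$n_beads)
  fits <- fit_all(emn, sim$design, 250, group)
  expect_equal(nrow(fits), length(group))
  expect_gte(mean(fits$converged), 0.99)
  expect_true(all(fits$df == fits$n_obs - 2L))

  # a bead-type missing from one section is fitted on the rest
  p1 <- group[1]
  emn$log2_mean[p1, sim$design$section_id[sim$design$quantity_ng == 250][1]] <- NA
  f1 <- fit_all(emn, sim$design, 250, p1)
  expect_equal(f1$n_obs, 17L)
  expect_equal(f1$df, 15L)

  expect_equal(nrow(fit_all(emn, sim$design, 250, character(0))), 0L)
})

test_that("signal-to-noise summaries and inflation factors are exact", {
  fits <- data.frame(bead_type_id = c("a", "b", "c"),
                     delta_hat = c(100, 100, 100), b_hat = 100,
                     se_delta = c(20, 30, 40),
                     t_stat = 1, p_value = 0.5, df = 16L, converged = TRUE,
                     n_obs = 18L, objective = 1)
  s <- snr_summary(fits)
  expect_equal(s$median_ratio, 0.3)
  expect_equal(s$n_used, 3L)
  expect_equal(snr_summary(fits[1, , drop = FALSE])$median_ratio, 0.2)

  # Delta = 0 records are excluded, not averaged in
  fits0 <- fits; fits0$delta_hat[2] <- 0
  s0 <- snr_summary(fits0)
  expect_equal(s0$n_excluded, 1L)
  expect_equal(s0$median_ratio, 0.3)

  expect_equal(sample_size_inflation(1, 1), 1)
  expect_equal(sample_size_inflation(1.76, 1), 3.0976)
  expect_equal(sample_size_inflation(1.12, 1), 1.2544)
  expect_error(sample_size_inflation(-1, 1), "positive")
})
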