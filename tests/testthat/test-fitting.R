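test_that("noise-free self-consistency: each model recovers its own parameters", {
  acq <- acq_params(); v <- vif_params()
  p <- physio_params()
  f1 <- fit_model(simulate_dynamic_signal(p, acq, v, model = "I"), "I", acq, v)
  expect_true(f1$converged)
  expect_lt(rel_err(f1$estimates[["k_ve"]], 0.02), 1e-4)
  expect_lt(rel_err(f1$estimates[["v_b"]], 0.09), 1e-4)
  expect_lt(rel_err(f1$estimates[["v_e"]], 0.30), 1e-4)

  f2 <- fit_model(simulate_dynamic_signal(p, acq, v, model = "II"), "II", acq, v)
  expect_lt(rel_err(f2$estimates[["k_ve"]], 0.02), 1e-4)
  expect_lt(rel_err(f2$estimates[["v_e"]], 0.30), 1e-4)

  f3 <- fit_model(simulate_dynamic_signal(p, acq, v, model = "III"), "III", acq, v)
  expect_lt(rel_err(f3$estimates[["k_ve"]], 0.02), 1e-4)
  expect_lt(rel_err(f3$estimates[["v_b"]], 0.09), 1e-4)
  expect_lt(rel_err(f3$v_e, 1 - 0.09), 1e-4)
})

test_that("simplified models are biased in opposite directions on Model I data", {
  acq <- acq_params(); v <- vif_params()
  curve <- simulate_dynamic_signal(physio_params(), acq, v, model = "I")
  f2 <- fit_model(curve, "II", acq, v)
  f3 <- fit_model(curve, "III", acq, v)
  expect_gt(f2$estimates[["k_ve"]], 0.02)
  expect_lt(f3$estimates[["k_ve"]], 0.02)
})

test_that("k_ve/v_e is invariant to VIF amplitude rescaling under joint scale fitting", {
  acq <- acq_params()
  curve <- simulate_dynamic_signal(physio_params(), acq, vif_params(), model = "I")
  opts <- fit_options(fit_vif_scale = TRUE)
  base_ratio <- fit_model(curve, "I", acq, vif_params(), options = opts)$ratios[["kve_ve"]]
  scaled <- fit_model(curve, "I", acq, vif_params(amplitude = 2), options = opts)
  expect_lt(rel_err(scaled$ratios[["kve_ve"]], base_ratio), 1e-3)
  expect_lt(rel_err(base_ratio, 0.02 / 0.30), 1e-3)
})

test_that("estimates respect their box constraints and ratios derive from estimates", {
  acq <- acq_params(); v <- vif_params()
  curve <- add_noise(simulate_dynamic_signal(physio_params(), acq, v), 0.01, seed = 5)
  for (mod in c("I", "II", "III")) {
    fit <- fit_model(curve, mod, acq, v, options = fit_options(fit_vif_scale = TRUE))
    est <- fit$estimates
    expect_true(all(est[names(est) != "vif_scale"] >= 0))
    expect_true(all(est[names(est) != "vif_scale"] <= 1))
    if ("vif_scale" %in% names(est)) {
      expect_gte(est[["vif_scale"]], 0.01)
      expect_lte(est[["vif_scale"]], 100)
    }
    expect_equal(fit$ratios[["kve_ve"]], est[["k_ve"]] / fit$v_e)
  }
})

test_that("Model I estimates honor v_b + v_ee <= 1", {
  acq <- acq_params(); v <- vif_params()
  p <- physio_params(k_ve = 0.05, v_b = 0.3, v_ee = 0.65)
  for (seed in 1:5) {
    noisy <- add_noise(simulate_dynamic_signal(p, acq, v), 0.005, seed = seed)
    fit <- fit_model(noisy, "I", acq, v)
    expect_lte(fit$estimates[["v_b"]] + fit$estimates[["v_e"]], 1 + 1e-6)
  }
})

test_that("degenerate fits report non-convergence instead of raising", {
  acq <- acq_params(); v <- vif_params()
  flat <- signal_curve(0:59, rep(0, 60))
  fit <- fit_model(flat, "I", acq, v)
  expect_s3_class(fit, "hpk_fit")
  expect_true(is.logical(fit$converged))
  short <- signal_curve(0:2, c(0, 1, 2))
  expect_error(fit_model(short, "I", acq, v, options = fit_options(fit_vif_scale = TRUE)),
               "sample")
})

test_that("fit objects expose broom-style tidy/glance and fitted values", {
  acq <- acq_params(); v <- vif_params()
  curve <- simulate_dynamic_signal(physio_params(), acq, v)
  fit <- fit_model(curve, "III", acq, v)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "kind") %in% names(td)))
  expect_true("kve_vb" %in% td$term)
  expect_true("v_e" %in% td$term)  # derived for Model III
  gl <- glance(fit)
  expect_equal(gl$n, 60)
  expect_true(gl$residual_norm >= 0)
  expect_length(fitted(fit), 60)
  p <- ggplot2::ggplot_build(autoplot(fit))
  expect_s3_class(p, "ggplot_built")
})

test_that("mean error and CoV metrics match hand arithmetic", {
  expect_equal(mean_error_pct(c(0.02, 0.02), 0.02), 0)
  expect_equal(mean_error_pct(0.03, 0.02), 50)
  expect_error(mean_error_pct(0.03, 0), "truth")
  expect_error(mean_error_pct(numeric(0), 1), "non-empty")
  expect_equal(coefficient_of_variation_pct(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation_pct(c(1, 3)), 70.71068, tolerance = 1e-6)
  expect_error(coefficient_of_variation_pct(1), "at least 2")
  expect_error(coefficient_of_variation_pct(c(-1, 1)), "mean")
  # known CoV of N(10, 1) draws
  draws <- withr::with_seed(99, rnorm(1e5, 10, 1))
  expect_equal(coefficient_of_variation_pct(draws), 10, tolerance = 0.01)
  # mean error of draws around a slightly biased center
  draws2 <- withr::with_seed(42, rnorm(100, 0.0196, 1e-3))
  expect_equal(mean_error_pct(draws2, 0.02), -2, tolerance = 0.5)
})

test_that("estimator bias shrinks as reference SNR grows", {
  acq <- acq_params(); v <- vif_params()
  clean <- simulate_dynamic_signal(physio_params(), acq, v)
  peak <- max(clean$signal)
  bias <- vapply(c(10, 50), function(snr) {
    est <- vapply(1:40, function(r) {
      noisy <- add_noise(clean, peak / snr, seed = 1000 * snr + r)
      fit_model(noisy, "I", acq, v)$estimates[["k_ve"]]
    }, numeric(1))
    abs(mean_error_pct(est, 0.02))
  }, numeric(1))
  expect_lt(bias[2], bias[1] + 1)  # monotone within MC error
})
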