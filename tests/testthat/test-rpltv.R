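test_that("zero log-ratio and noiseless constant truth give exact recovery", {
  # Y == 0 -> identity maps, for any TV weights (constants have zero TV)
  Y0 <- array(0, dim = c(10, 5, 5))
  fit <- fit_rpl_tv(Y0, solver_config(), freq_mhz = seq(4, 18, length.out = 10),
                    axial_step_cm = 0.056)
  expect_equal(max(abs(fit$delta_b - 1)), 0, tolerance = 1e-8)
  expect_equal(max(abs(fit$delta_n)), 0, tolerance = 1e-8)
  expect_equal(max(abs(fit$delta_a)), 0, tolerance = 1e-8)
  expect_true(fit$converged)

  # constant maps (zero attenuation slope, so the cumulative attenuation
  # is constant too) have zero total variation: exact at any weights
  gt <- make_ground_truth(c(6, 6), "constant",
                          levels = list(delta_b = 3, delta_n = 1))
  v <- simulate_spectra(gt)
  fitc <- fit_rpl_tv(v, solver_config())
  expect_equal(fitc$delta_b[, , 1], gt$delta_b_true, tolerance = 1e-6)
  expect_equal(fitc$delta_n[, , 1], gt$delta_n_true, tolerance = 1e-6)

  # a nonzero constant attenuation slope makes the cumulative map a ramp
  # whose total variation is positive: the unregularized fit stays exact
  gt2 <- make_ground_truth(c(6, 6), "constant",
                           levels = list(delta_b = 3, delta_n = 1,
                                         delta_alpha = 0.2))
  fit2 <- per_block_ols(simulate_spectra(gt2))
  expect_equal(fit2$delta_alpha[, , 1], gt2$delta_alpha_true,
               tolerance = 1e-6)
})

test_that("the unregularized limit equals per-block OLS", {
  gt <- two_level_truth(c(12, 12))
  v <- simulate_spectra(gt, noise_sd = 0.3, seed = 9)
  tv0 <- fit_rpl_tv(v, solver_config(0, 0, 0))
  ols <- per_block_ols(v)
  expect_equal(tv0$delta_b, ols$delta_b, tolerance = 1e-10)
  expect_equal(tv0$delta_n, ols$delta_n, tolerance = 1e-10)
  expect_equal(tv0$delta_a, ols$delta_a, tolerance = 1e-10)
})

test_that("OLS estimator variance matches the analytic covariance", {
  f <- seq(4, 18, length.out = 20)
  G <- cbind(1, log(f), -4 * f)
  sigma <- 0.4
  cov_beta <- sigma^2 * solve(crossprod(G))
  set.seed(21)
  n_mc <- 400
  est <- replicate(n_mc, {
    y <- array(rnorm(length(f), sd = sigma), dim = c(length(f), 1, 1))
    fit <- per_block_ols(y, freq_mhz = f)
    c(log(fit$delta_b[1, 1, 1]), fit$delta_n[1, 1, 1], fit$delta_a[1, 1, 1])
  })
  emp_sd <- apply(est, 1, sd)
  expect_equal(emp_sd, sqrt(diag(cov_beta)), tolerance = 0.15)

  expect_error(per_block_ols(array(0, c(2, 1, 1)), freq_mhz = c(4, 5)),
               "rank-deficient")
})

test_that("TV regularization beats OLS on noisy piecewise truth", {
  gt <- two_level_truth(c(14, 14))
  a_true <- qusliver:::cumulative_attenuation(gt$delta_alpha_true, 0.056)
  wins <- 0
  for (s in 1:3) {
    v <- simulate_spectra(gt, noise_sd = 0.5, seed = 100 + s)
    ols <- per_block_ols(v)
    tv <- fit_rpl_tv(v, solver_config())
    err_ols <- rmse(log(ols$delta_b[, , 1]), log(gt$delta_b_true)) +
      rmse(ols$delta_n[, , 1], gt$delta_n_true) +
      rmse(ols$delta_a[, , 1], a_true)
    err_tv <- rmse(log(tv$delta_b[, , 1]), log(gt$delta_b_true)) +
      rmse(tv$delta_n[, , 1], gt$delta_n_true) +
      rmse(tv$delta_a[, , 1], a_true)
    if (err_tv < err_ols) wins <- wins + 1
  }
  expect_equal(wins, 3)
})

test_that("solver objective is non-increasing and weights act monotonically", {
  gt <- two_level_truth(c(10, 10))
  v <- simulate_spectra(gt, noise_sd = 0.5, seed = 33)
  fit <- fit_rpl_tv(v, solver_config())
  expect_true(all(diff(fit$objective_trace[[1]]) <= 1e-8))
  expect_true(all(fit$delta_b > 0))

  # larger mu_a weakly decreases the total variation of the delta_a map
  tv_of <- function(m) {
    sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  }
  tvs <- sapply(c(1, 1e3, 1e5), function(mu_a) {
    f <- fit_rpl_tv(v, solver_config(mu_a = mu_a))
    tv_of(f$delta_a[, , 1])
  })
  expect_true(all(diff(tvs) <= 1e-6))
})

test_that("cumulative attenuation differentiates to the slope map", {
  # linear ramp of slope 0.3 differentiates to a constant
  z <- matrix(seq(0, 0.27, by = 0.03), 10, 4)
  da <- attenuation_from_cumulative(z * 1, axial_step_cm = 0.1)
  expect_equal(unname(da), matrix(0.3, 10, 4))
  # constant map differentiates to zero
  expect_true(all(attenuation_from_cumulative(matrix(1, 5, 3), 0.1) == 0))
  # cumsum then differentiate returns the interior rows of the original
  set.seed(8)
  alpha <- matrix(runif(24, 0, 1), 6, 4)
  a <- apply(alpha, 2, cumsum) * 0.056
  back <- attenuation_from_cumulative(a, 0.056)
  expect_equal(back[1:5, ], alpha[2:6, ], tolerance = 1e-10)
  expect_error(attenuation_from_cumulative(matrix(1, 1, 3), 0.1),
               "single-row")
})

test_that("relative BSC evaluation follows the power law", {
  maps <- list(delta_b = array(1, c(2, 2, 1)), delta_n = array(0, c(2, 2, 1)))
  expect_equal(unique(as.vector(compute_relative_bsc(maps, 7))), 1)
  maps2 <- list(delta_b = array(2, c(1, 1, 1)), delta_n = array(1, c(1, 1, 1)))
  expect_equal(as.vector(compute_relative_bsc(maps2, 11)), 22)
  # Rayleigh scatterers (delta_n = 4): doubling f multiplies BSC by 16
  maps4 <- list(delta_b = array(3, c(1, 1, 1)), delta_n = array(4, c(1, 1, 1)))
  expect_equal(as.vector(compute_relative_bsc(maps4, 10) /
                           compute_relative_bsc(maps4, 5)), 16)
  expect_error(compute_relative_bsc(maps2, -1), "positive")
})

test_that("feature extraction averages per-frame ROI medians", {
  gt <- make_ground_truth(c(6, 6), "constant",
                          levels = list(delta_b = 10, delta_alpha = 0.3))
  v <- simulate_spectra(gt, noise_sd = 0, n_frames = 3)
  maps <- per_block_ols(v)
  snr <- array(1.9, dim = dim(maps$delta_b))
  ft <- extract_features(maps, snr)
  expect_equal(ft$delta_b_db, 10, tolerance = 1e-5)
  expect_equal(ft$delta_alpha, 0.3, tolerance = 1e-5)
  expect_equal(ft$snr, 1.9)
  expect_equal(ft$n_frames, 3)

  # identical frames: features equal single-frame medians; and a
  # two-frame mean of medians {1, 3} gives 2
  m <- structure(list(delta_b = array(10^(c(0.1, 0.3) / 1), c(1, 1, 2)),
                      delta_n = array(0, c(1, 1, 2)),
                      delta_alpha = array(c(1, 3), c(1, 1, 2)),
                      axial_step_cm = 0.056),
                 class = "coefficient_maps")
  ft2 <- extract_features(m, array(c(1, 3), c(1, 1, 2)))
  expect_equal(ft2$delta_alpha, 2)
  expect_equal(ft2$snr, 2)
  expect_error(extract_features(maps, snr,
                                roi = list(axial = c(2, 1),
                                           lateral = c(1, 0))))
})
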