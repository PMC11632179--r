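test_that("prediction metrics match hand-computed values", {
  d <- c(1, 0, 1, 0)
  score <- c(0.9, 0.8, 0.7, 0.1)
  m <- prediction_metrics(d, score, family = "logistic")
  expect_equal(unname(m["auroc"]), 0.75)          # 3 of 4 pairs concordant
  expect_equal(unname(m["auprc"]), 5 / 6)         # average precision by hand

  # perfect prediction, continuous
  y <- c(0.2, 1.4, -0.7, 3.1)
  mc <- prediction_metrics(y, y, family = "linear")
  expect_equal(unname(mc["r2"]), 1)
  expect_equal(unname(mc["mae"]), 0)

  # constant score: every positive-negative pair ties at one half
  m0 <- prediction_metrics(c(1, 0, 1, 0), rep(0.3, 4), family = "logistic")
  expect_equal(unname(m0["auroc"]), 0.5)

  # zero-variance prediction against a continuous label: r2 = 0 by convention
  mz <- prediction_metrics(y, rep(1, 4), family = "linear")
  expect_equal(unname(mz["r2"]), 0)
})

test_that("model fitting matches closed-form least squares and handles separation", {
  # intercept-only linear model predicts the mean
  y <- c(1, 2, 3, 6)
  f <- gemeval:::fit_and_predict(y, cbind(rep(1, 4)), "linear")
  expect_equal(f$pred, rep(3, 4))

  # two-parameter fit against the hand-solved normal equations
  x <- c(0, 1, 2, 3)
  X <- cbind(1, x)
  beta_hat <- solve(t(X) %*% X, t(X) %*% y)
  f2 <- gemeval:::fit_and_predict(y, X, "linear")
  expect_equal(f2$pred, drop(X %*% beta_hat), tolerance = 1e-12)

  # perfectly separating covariate triggers the ridge fallback but the
  # predictions still order with the labels
  d <- c(0, 0, 0, 1, 1, 1)
  Xs <- cbind(1, c(-1, -2, -3, 1, 2, 3))
  fs <- gemeval:::fit_and_predict(d, Xs, "logistic")
  expect_true(fs$separation)
  expect_true(min(fs$pred[d == 1]) > max(fs$pred[d == 0]))
})

test_that("permutation-bootstrap p-value obeys its exact formula and bounds", {
  set.seed(14)
  n <- 120
  covs <- cbind(age = rnorm(n))
  d <- rnorm(n) + 0.3 * covs[, 1]
  prs <- matrix(rnorm(2 * n), n, 2)
  rt <- relevance_test(d, prs, covs, family = "linear", B = 19, seed = 5)

  # p = (1 + #exceedances)/(1 + B), recomputed from the returned nulls
  star_obs <- log(rt$metrics$delta_obs)
  for (j in 1:2) {
    exceed <- sum(abs(rt$null_deltas[, j]) >= abs(star_obs[j]))
    expect_equal(rt$metrics$p_value[j], (1 + exceed) / 20)
  }
  expect_true(all(rt$metrics$p_value >= 1 / 20 & rt$metrics$p_value <= 1))

  # identical seed gives a bit-identical report
  rt2 <- relevance_test(d, prs, covs, family = "linear", B = 19, seed = 5)
  expect_identical(rt, rt2)

  # positive affine rescaling of a score column changes nothing
  prs_scaled <- prs
  prs_scaled[, 1] <- 100 * prs_scaled[, 1] + 7
  rt3 <- relevance_test(d, prs_scaled, covs, family = "linear", B = 19,
                        seed = 5)
  expect_equal(rt3$metrics, rt$metrics, tolerance = 1e-10)

  # reduced-model metrics do not depend on how many scores the full model has
  rt1 <- relevance_test(d, prs[, 1, drop = FALSE], covs, family = "linear",
                        B = 19, seed = 5)
  expect_equal(rt1$metrics$reduced, rt$metrics$reduced, tolerance = 1e-12)
})

test_that("uninformative score sets are reported as not evaluable", {
  d <- rnorm(30)
  rt <- relevance_test(d, matrix(0, 30, 2), family = "linear", B = 19)
  expect_false(rt$evaluable)
  expect_null(rt$metrics)
  expect_output(print(rt), "not evaluable")
})

test_that("binary-outcome path reports AUROC/AUPRC contrasts", {
  set.seed(33)
  n <- 300
  x <- rnorm(n)
  prs <- matrix(rnorm(n), n, 1)
  d <- rbinom(n, 1, plogis(0.8 * x + 1.2 * prs[, 1]))
  rt <- relevance_test(d, prs, cbind(x = x), family = "logistic", B = 99,
                       seed = 3)
  expect_identical(rt$metrics$metric, c("auroc", "auprc"))
  expect_gt(rt$metrics$delta_obs[1], 1)   # scores genuinely help here
  expect_lt(rt$metrics$p_value[1], 0.05)
})
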