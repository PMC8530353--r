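test_that("the bounded-response transform is exact and invertible", {
  expect_equal(logistic_transform(50), 0)
  expect_equal(logistic_transform(0.1), log(0.1 / 99.9))
  set.seed(1)
  y <- runif(200, 0.2, 99.8)
  expect_equal(inverse_logistic_transform(logistic_transform(y)), y,
               tolerance = 1e-10)
  # boundary values are clamped, out-of-range values rejected
  expect_equal(logistic_transform(0), log(0.1 / 99.9))
  expect_error(logistic_transform(101), "outside")
})

test_that("intercept-only median fit is the back-transformed sample median", {
  set.seed(2)
  y <- runif(201, 1, 99)
  f <- fit_lqr(matrix(numeric(0), 201, 0), y, 0.5)
  expect_equal(unname(f$coefficients), median(logistic_transform(y)),
               tolerance = 1e-6)
  expect_true(all(f$fitted_q > 0 & f$fitted_q < 100))
})

test_that("the solver check loss beats a brute-force lattice", {
  set.seed(3)
  x <- cbind(a = rnorm(30), b = rnorm(30))
  y <- inverse_logistic_transform(-0.5 + 0.8 * x[, 1] - 0.4 * x[, 2] +
                                    rlogis(30))
  z <- logistic_transform(y)
  Xd <- cbind(1, x)
  grd <- as.matrix(expand.grid(b0 = seq(-3, 3, 0.1), b1 = seq(-2, 3, 0.1),
                               b2 = seq(-3, 2, 0.1)))
  R <- matrix(z, 30, nrow(grd)) - Xd %*% t(grd)
  for (tau in c(0.25, 0.5, 0.9)) {
    fit <- fit_lqr(x, y, tau)
    lattice_min <- min(colSums(R * (tau - (R < 0))))
    expect_lte(fit$loss, lattice_min + 1e-8)
  }
})

test_that("rank-deficient designs are rejected", {
  set.seed(4)
  x <- cbind(a = rnorm(50))
  x <- cbind(x, b = x[, 1])
  y <- runif(50, 1, 99)
  expect_error(fit_lqr(x, y, 0.5), "rank deficient")
})

test_that("quantile AIC matches its closed form and is monotone in loss", {
  set.seed(5)
  x <- cbind(a = rnorm(40))
  y <- inverse_logistic_transform(0.5 * x[, 1] + rlogis(40))
  fit <- fit_lqr(x, y, 0.25)
  sigma <- fit$loss / fit$n
  ll <- fit$n * (log(0.25 * 0.75) - log(sigma) - 1)
  expect_equal(lqr_aic(fit), 2 * 2 - 2 * ll)

  # same k, halved loss -> smaller AIC
  fit2 <- fit
  fit2$loss <- fit$loss / 2
  expect_lt(lqr_aic(fit2), lqr_aic(fit))

  fit3 <- fit
  fit3$loss <- 0
  expect_error(lqr_aic(fit3), "degenerate")
})

test_that("a pure-noise covariate usually increases the quantile AIC", {
  set.seed(6)
  worse <- replicate(40, {
    x <- cbind(a = rnorm(1500))
    y <- inverse_logistic_transform(-1 + x[, 1] + rlogis(1500))
    xn <- cbind(x, noise = rnorm(1500))
    lqr_aic(fit_lqr(xn, y, 0.5)) > lqr_aic(fit_lqr(x, y, 0.5))
  })
  # simulation puts the long-run rate near 0.79 (the chi-square-1 < 2 rule,
  # as for OLS-AIC); assert the qualitative property with seed-proof margin
  expect_gte(mean(worse), 0.7)
})

test_that("bootstrap standard errors are reproducible and positive", {
  set.seed(7)
  x <- cbind(a = rnorm(150), b = rnorm(150))
  y <- inverse_logistic_transform(-1 + x[, 1] + rlogis(150))
  f1 <- bootstrap_se(x, y, 0.5, B = 50, seed = 11)
  f2 <- bootstrap_se(x, y, 0.5, B = 50, seed = 11)
  expect_identical(f1$se, f2$se)
  expect_true(all(f1$se > 0))
  expect_true(all(f1$p_value >= 0 & f1$p_value <= 1))
  f3 <- bootstrap_se(x, y, 0.5, B = 50, seed = 12)
  expect_false(identical(f1$se, f3$se))
})

test_that("VIF matches its closed form and flags collinearity", {
  set.seed(8)
  x <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  v <- vif(x)
  expect_true(all(abs(v - 1) < 0.2))

  dup <- cbind(x, d = x[, 1])
  vd <- vif(dup)
  expect_true(is.infinite(vd["d"]))
  expect_true(attr(vd, "flagged")["d"])

  # population R^2 = 0.9 -> VIF about 10
  set.seed(9)
  x1 <- rnorm(30000)
  x2 <- x1 + rnorm(30000, 0, sqrt(1 / 9))
  v2 <- vif(cbind(x1 = x1, x2 = x2))
  expect_equal(unname(v2["x2"]), 10, tolerance = 0.5)
})

test_that("VIF agrees with the car package on random data", {
  skip_if_not_installed("car")
  set.seed(10)
  X <- matrix(rnorm(500), 100, 5)
  X[, 2] <- X[, 1] + rnorm(100, 0, 0.5)
  colnames(X) <- paste0("v", 1:5)
  df <- data.frame(y = rnorm(100), X)
  ours <- vif(X)
  theirs <- car::vif(lm(y ~ ., data = df))
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 1e-8)
})

test_that("AIC ranks average correctly with ties", {
  aic <- rbind(m1 = c(10, 20), m2 = c(12, 20), m3 = c(11, 25))
  rk <- aic_rank_table(aic)
  expect_equal(rk$ranks[, 1], c(m1 = 1, m2 = 3, m3 = 2))
  expect_equal(rk$ranks[, 2], c(m1 = 1.5, m2 = 1.5, m3 = 3))
  expect_equal(rk$avg_rank, c(m1 = 1.25, m2 = 2.25, m3 = 2.5))
  # columns are permutations up to tie-averaging
  expect_equal(sort(colSums(rk$ranks)), rep(6, 2))
})

test_that("hierarchical selection enumerates the nine SNS x PNS candidates", {
  rec <- simulate_analysis_records(900, seed = 13)
  sel <- hierarchical_select(rec, B = 15, seed = 13)
  expect_equal(nrow(sel$candidates), 9)
  expect_equal(sel$candidates$sns[c(1, 5, 9)],
               c("lf_score", "lfhf_ratio", "sdnn"))
  expect_equal(sel$candidates$pns[c(1, 5, 9)],
               c("hf_score", "nn50", "rmssd"))
  expect_equal(dim(sel$aic), c(10, 5))
  expect_true(all(is.finite(sel$aic)))
  # baseline (fewer parameters, no ANF signal) never beats every candidate
  expect_true(all(apply(sel$aic[-1, , drop = FALSE], 2, min) <=
                    sel$aic[1, ]))
  expect_true(all(sel$vif_max < 10))
  expect_true(all(colSums(sel$ranks) == sum(1:9)))
})

test_that("records missing candidate columns are rejected", {
  rec <- simulate_analysis_records(200, seed = 14)
  rec$nn50 <- NULL
  expect_error(hierarchical_select(rec, B = 5), "nn50")
})

test_that("the mean-effect model is exact OLS on the logit scale", {
  set.seed(15)
  x <- cbind(a = rnorm(60), b = rnorm(60))
  z <- 1 + 2 * x[, 1] - 0.5 * x[, 2]
  y <- inverse_logistic_transform(z)
  f <- fit_mean_model(x, y)
  expect_equal(unname(f$coefficients), c(1, 2, -0.5), tolerance = 1e-6)

  y2 <- runif(60, 1, 99)
  f2 <- fit_mean_model(matrix(numeric(0), 60, 0), y2)
  expect_equal(unname(f2$coefficients), mean(logistic_transform(y2)))

  rec <- simulate_analysis_records(4000, seed = 16)
  f3 <- fit_mean_model(as.matrix(rec[, c("lfhf_ratio", "nn50", "avghr",
                                         "age", "mean_speed")]),
                       rec$risk_pct)
  expect_gt(f3$coefficients["lfhf_ratio"], 0)
  expect_lt(f3$coefficients["nn50"], 0)
})

test_that("the fractional-logit mean model recovers the same signs as OLS", {
  rec <- simulate_analysis_records(4000, seed = 17)
  X <- as.matrix(rec[, c("lfhf_ratio", "nn50", "avghr", "age",
                         "mean_speed")])
  frac <- fit_mean_model(X, rec$risk_pct, method = "fractional")
  expect_gt(frac$coefficients["lfhf_ratio"], 0)
  expect_lt(frac$coefficients["nn50"], 0)
  expect_true(all(frac$se > 0))
})
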