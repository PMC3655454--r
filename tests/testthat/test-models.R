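test_that("Yule-Walker and least-squares fits recover AR parameters", {
  x1 <- gen_ar(0.5, noise_sd = 1, length = 5000, seed = 21)
  yw <- fit_ar_yw(x1, 1)
  expect_lt(abs(yw$coeffs - 0.5), 0.05)

  x2 <- gen_ar(c(0.5, -0.3), noise_sd = 1, length = 5000, seed = 22)
  ls <- fit_ar_ls(x2, 2)
  expect_lt(max(abs(ls$coeffs - c(0.5, -0.3))), 0.05)

  # the two estimators agree closely on large stationary samples
  yw2 <- fit_ar_yw(x2, 2)
  expect_lt(max(abs(yw2$coeffs - ls$coeffs)), 0.02)

  # null recovery on white noise
  z <- gen_ar(numeric(0), noise_sd = 1, length = 10000, seed = 23)
  expect_lt(abs(fit_ar_yw(z, 1)$coeffs), 0.05)

  expect_error(fit_ar_yw(rep(4, 100), 1), "zero variance")
  expect_error(fit_ar_ls(c(1, 2), 1), "at least")
})

test_that("least-squares fit matches the ar.ols reference", {
  x <- gen_ar(c(0.6, -0.2), noise_sd = 1, length = 800, seed = 24)
  mine <- fit_ar_ls(x, 2)
  ref <- stats::ar.ols(as.numeric(x), aic = FALSE, order.max = 2,
                       demean = TRUE, intercept = TRUE)
  expect_equal(mine$coeffs, as.numeric(ref$ar), tolerance = 1e-6)
})

test_that("ar_one_step computes the linear prediction", {
  m <- caar:::new_ar_model(1, 1, intercept = 0, noise_var = 1, method = "ls")
  expect_equal(ar_one_step(m, c(2, 5, 7)), 7)
  m2 <- caar:::new_ar_model(1, 0, intercept = 2, noise_var = 1, method = "ls")
  expect_equal(ar_one_step(m2, 99), 2)
  m3 <- caar:::new_ar_model(2, c(0.5, 0.5), intercept = 0, noise_var = 1,
                            method = "ls")
  expect_equal(ar_one_step(m3, c(1, 6, 4)), 5)  # x_{t-1}=4, x_{t-2}=6
  expect_error(ar_one_step(m3, 4), "at least 2")
})

test_that("sign search equals exhaustive enumeration", {
  set.seed(33)
  for (p in 2:6) {
    for (W in c(p, 2 * p)) {
      x <- stats::rnorm(40)
      t <- 35
      got <- select_signs(x, t, p, W)
      ref <- brute_select_signs(x, t, p, W)
      expect_identical(got$signs, as.numeric(ref$signs),
                       label = sprintf("p=%d W=%d", p, W))
      expect_equal(got$intercept, ref$intercept, tolerance = 1e-12)
      expect_equal(got$rss, ref$rss, tolerance = 1e-12)
    }
  }
})

test_that("sign search honours its contracts and guards", {
  # exact zero-noise random walk: positive sign, zero intercept, zero residual
  x <- rep(5, 21)
  s <- select_signs(x, 15, 1, 3)
  expect_identical(s$signs, 1)
  expect_equal(s$rss, 0)

  # noiseless identifiability: known signs and intercept are recovered
  x2 <- gen_caar(c(1, -1, 1), intercept = 0.3, length = 60, seed = 3)
  s2 <- select_signs(x2, 50, 3)
  expect_identical(s2$signs, c(1, -1, 1))
  expect_lt(abs(s2$intercept - 0.3), 1e-9)

  expect_error(select_signs(1:10, 9, 4, 5), "insufficient history")
  expect_error(select_signs(stats::rnorm(100), 90, 21, 5), "force = TRUE")
})

test_that("one-step CA-AR forecasts degenerate cases exactly", {
  # constant series: the intercept absorbs the sign sum
  for (p in 1:3) {
    expect_equal(caar_one_step(rep(5, 30), 25, p), 5, tolerance = 1e-12)
  }
  # ramp: drifted unit root, exact one-step continuation
  r <- as.numeric(1:50)
  expect_equal(caar_one_step(r, 40, 1), 40, tolerance = 1e-12)
  # determinism
  x <- gen_random_walk(length = 100, seed = 5)
  expect_identical(caar_one_step(x, 80, 3), caar_one_step(x, 80, 3))
})

test_that("multi-step CA-AR forecasting follows the rolling protocol", {
  # a ramp is exactly representable whenever the signs can sum to 1 (odd p)
  r <- caar_series(as.numeric(1:60))
  for (p in c(1, 5)) {
    fr <- caar_forecast(r, 41, 10, p = p)
    expect_equal(fr$rmse, 0, tolerance = 1e-12)
    expect_equal(fr$predicted, as.numeric(41:50), tolerance = 1e-12)
  }

  x <- gen_caar(c(1, -1), intercept = 0.2, noise_sd = 0.3, length = 80,
                seed = 12)
  f1 <- caar_forecast(x, 61, 1, p = 2)
  expect_equal(f1$predicted, caar_one_step(x, 61, 2))

  # rolling forecasts never look past the last forecast index
  full <- caar_forecast(x, 61, 10, p = 2)
  trunc <- caar_forecast(as.numeric(x)[1:70], 61, 10, p = 2)
  expect_identical(full$predicted, trunc$predicted)

  # translation equivariance: the refit intercept absorbs the offset
  sh <- caar_forecast(as.numeric(x) + 100, 61, 10, p = 2)
  expect_equal(sh$predicted, full$predicted + 100, tolerance = 1e-9)

  expect_error(caar_forecast(x, 75, 10, p = 2), "recursive")
  rec <- caar_forecast(x, 75, 10, p = 2, mode = "recursive")
  expect_length(rec$predicted, 10)
  expect_null(rec$rmse)
})

test_that("the AR baseline rolls, refits and degrades gracefully", {
  x <- gen_ar(0.7, noise_sd = 1, length = 600, seed = 31)
  f <- ar_forecast(x, 501, 50, p = 1, method = "ls")
  expect_lt(f$rmse, 1.5)
  f2 <- ar_forecast(x, 501, 50, p = 1, method = "yw", train_window = 200)
  expect_lt(f2$rmse, 1.5)
  # constant history cannot be fit: NaN predictions, NaN RMSE
  y <- c(rep(1, 50), stats::rnorm(10))
  fbad <- ar_forecast(y, 51, 5, p = 2)
  expect_true(all(is.nan(fbad$predicted[1])))
  expect_true(is.nan(fbad$rmse))
})
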