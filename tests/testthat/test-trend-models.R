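test_that("unweighted linear fit matches the normal-equations oracle", {
  f <- fit_linear(c(0, 1, 2), c(30, 28, 26))
  expect_equal(f$alpha, 30)
  expect_equal(f$beta, -2)
  f0 <- fit_linear(0:3, rep(25, 4))
  expect_equal(f0$beta, 0)
  expect_equal(f0$alpha, 25)
  set.seed(7)
  x <- sort(runif(5, 0, 10)); y <- 28 - 0.8 * x + rnorm(5)
  f <- fit_linear(x, y)
  X <- cbind(1, x)
  cf <- solve(t(X) %*% X, t(X) %*% y)   # independent closed form
  expect_equal(f$alpha, cf[1], tolerance = 1e-10)
  expect_equal(f$beta, cf[2], tolerance = 1e-10)
  # residuals of the uncensored fit sum to zero
  expect_lt(abs(sum(y - (f$alpha + f$beta * x))), 1e-9)
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)), "degenerate")
  expect_error(fit_linear(0:1, c(1, 2)), "at least 3")
})

test_that("weighted linear regression obeys the WLS identities", {
  set.seed(11)
  for (i in 1:20) {
    x <- sort(runif(6, 0, 12)); y <- 30 - runif(1) * x + rnorm(6, 0, 2)
    w <- rep(runif(1, 0.1, 5), 6)
    fw <- fit_weighted_linear(x, y, w)
    fo <- fit_linear(x, y)
    expect_equal(fw$alpha, fo$alpha, tolerance = 1e-10)
    expect_equal(fw$beta, fo$beta, tolerance = 1e-10)
  }
  # weight 2 on one point is the same as duplicating it
  x <- c(0, 2, 4, 6); y <- c(30, 27, 26, 20)
  fw <- fit_weighted_linear(x, y, c(2, 1, 1, 1))
  fd <- fit_linear(c(0, x), c(30, y))
  expect_equal(fw$alpha, fd$alpha, tolerance = 1e-10)
  expect_equal(fw$beta, fd$beta, tolerance = 1e-10)
  # exact-line data recovers the line whatever the weights
  fl <- fit_weighted_linear(0:3, 30 - 2 * (0:3), c(9, 1, 4, 0.5))
  expect_equal(fl$alpha, 30, tolerance = 1e-12)
  expect_equal(fl$beta, -2, tolerance = 1e-12)
  expect_error(fit_weighted_linear(0:3, 1:4, c(1, 1, -1, 1)), "positive")
})

test_that("noise-model weights are reciprocal variances at observed dB", {
  const2 <- loglinear_noise_model(log(2), 0)   # sigma == 2 everywhere
  ws <- weights_from_noise_model(c(10, 20, 20), const2)
  expect_equal(ws$v, rep(4, 3))
  expect_equal(ws$w, rep(0.25, 3))
  expect_equal(ws$w[2], ws$w[3])
  anchors <- anchor_noise_model()
  wa <- weights_from_noise_model(c(11, 33), anchors)
  expect_lt(wa$w[1], wa$w[2])   # noisier 11 dB observation downweighted
  bad <- loglinear_noise_model(-50, 0)
  expect_silent(weights_from_noise_model(20, bad)) # tiny but positive is fine
})

test_that("exponential fits are exact OLS in log space with direction routing", {
  t <- 0:4
  f <- fit_exponential(t, exp(3 - 0.2 * t))
  expect_equal(f$kind, "exp_decay")
  expect_equal(f$alpha, 3, tolerance = 1e-12)
  expect_equal(f$beta, -0.2, tolerance = 1e-12)
  # exponentiating the log-space line reproduces fitted dB values
  expect_equal(predict(f, t), exp(3 - 0.2 * t), tolerance = 1e-12)

  t2 <- 0:6
  y2 <- 35 - exp(2 - 0.3 * t2)
  f2 <- fit_exponential(t2, y2, ceiling_Y = 35)
  expect_equal(f2$kind, "exp_improve")
  expect_equal(f2$alpha, 2, tolerance = 1e-8)
  expect_equal(f2$beta, -0.3, tolerance = 1e-8)
  expect_equal(predict(f2, t2), y2, tolerance = 1e-8)

  # a 0 dB observation is handled by the documented 0.5 dB clamp
  f3 <- fit_exponential(0:3, c(8, 4, 1, 0))
  expect_equal(f3$kind, "exp_decay")
  expect_true(is.finite(f3$alpha) && is.finite(f3$beta))
  # improvement branch without a ceiling errors
  expect_error(fit_exponential(0:3, c(10, 12, 14, 16)), "ceiling")
})

test_that("logistic least squares recovers noiseless parameters", {
  t <- seq(0, 14, by = 2)
  y <- 30 / (1 + exp(-2 + 0.5 * t))
  f <- fit_logistic(t, y)
  expect_true(f$converged)
  expect_equal(f$zeta, 30, tolerance = 1e-6)
  expect_equal(f$alpha, -2, tolerance = 1e-6)
  expect_equal(f$beta, 0.5, tolerance = 1e-6)
  # constant data: flat curve limit
  fc <- fit_logistic(0:5, rep(18, 6))
  expect_true(fc$converged)
  expect_equal(unname(predict(fc, 0:5)), rep(18, 6), tolerance = 1e-4)
  expect_lt(abs(fc$beta), 1e-3)
  # fitted values stay inside (0, zeta)
  p <- predict(f, seq(-5, 30, by = 0.5))
  expect_true(all(p > 0 & p < f$zeta))
})

test_that("predictions are censored at the floor and normative ceiling", {
  lin <- fit_linear(0:3, c(5, 3, 1, -1) + c(0, 0, 0, 1)) # slope approx -2
  lin$alpha <- 5; lin$beta <- -2
  expect_equal(unname(predict(lin, 4)), 0)           # raw -3 floored
  lin2 <- fit_linear(0:2, c(30, 32, 34))
  expect_equal(unname(predict(lin2, 5, ceiling_Y = 34)), 34)
  ed <- fit_exponential(0:4, exp(3 - 0.2 * (0:4)))
  expect_equal(unname(predict(ed, 0)), exp(3), tolerance = 1e-12)
  # monotone in t given the slope sign, and bounded
  tt <- seq(0, 20, by = 0.25)
  expect_true(all(diff(predict(lin, tt, ceiling_Y = 33)) <= 0))
  expect_true(all(diff(predict(ed, tt)) <= 0))
  expect_true(all(predict(lin, tt, ceiling_Y = 33) >= 0 &
                  predict(lin, tt, ceiling_Y = 33) <= 33))
})

test_that("whole-field fitting respects context and records failures", {
  series <- make_linear_series(times = 0:7, base = 28, slope = -0.5)
  fits <- fit_all_locations(series, "linear", context = "variability")
  expect_length(fits, 52L)
  expect_length(attr(fits, "failures"), 0L)
  # floor-locked location excluded in the modeling context only
  S <- sensitivity_matrix(series)
  S[5, ] <- 0
  s2 <- make_series_from_matrix(S, exam_times(series))
  f_var <- fit_all_locations(s2, "linear", context = "variability")
  f_mod <- fit_all_locations(s2, "linear", context = "modeling")
  g <- grid_24_2()
  expect_true(as.character(g$index[5]) %in% names(f_var))
  expect_false(as.character(g$index[5]) %in% names(f_mod))
  # determinism
  f_again <- fit_all_locations(series, "linear", context = "variability")
  expect_identical(fits_to_table(fits), fits_to_table(f_again))
  # serialisation carries one row per fitted location
  tab <- fits_to_table(fits, eye_id = "lin")
  expect_equal(nrow(tab), 52L)
  expect_true(all(tab$kind == "linear"))
})
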