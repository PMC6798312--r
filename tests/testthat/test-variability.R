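test_that("pooled residuals vanish on exact-line data and count correctly", {
  cohort <- list(make_linear_series(0:6, base = 28, slope = -0.4, eye_id = "a"),
                 make_linear_series(0:6, base = 24, slope = -0.2, eye_id = "b"))
  res <- pool_residuals(cohort, "linear", min_exams = 6, min_followup = 3)
  expect_equal(nrow(res), 2 * 52 * 7)   # eyes x non-blind-spot x exams
  expect_true(all(abs(res$residual) < 1e-9))
  # exponential and linear fits give different residual sets on curved data
  S <- matrix(rep(30 * exp(-0.15 * (0:6)), each = 54), 54, 7)
  curved <- list(make_series_from_matrix(S, 0:6, eye_id = "c"))
  r_exp <- pool_residuals(curved, "exponential", min_followup = 3)
  r_lin <- pool_residuals(curved, "linear", min_followup = 3)
  expect_gt(max(abs(r_exp$residual - r_lin$residual)), 0.01)
  expect_lt(max(abs(r_exp$residual)), 1e-8)   # truth is exponential
  expect_error(pool_residuals(list(), "linear"), "empty")
  # series below the entry criteria are skipped
  short <- list(make_linear_series(0:3, eye_id = "s"))
  expect_error(pool_residuals(short, "linear"), "criteria")
})

test_that("binned SD uses the sample (n-1) estimator per observed dB", {
  rec <- make_residual_records(rep(1L, 4), rep(20, 4), c(1, -1, 1, -1))
  cur <- sd_by_sensitivity(rec, min_count = 2)
  expect_s3_class(cur, "vf_sd_curve")
  expect_equal(cur$sd_db[cur$sensitivity_db == 20], sqrt(4 / 3)) # 1.1547
  expect_equal(cur$n[cur$sensitivity_db == 20], 4L)
  expect_equal(sum(cur$n), 4L)
  zero <- sd_by_sensitivity(make_residual_records(1L, c(10, 10, 10),
                                                  rep(0, 3)), min_count = 2)
  expect_equal(zero$sd_db[zero$sensitivity_db == 10], 0)
  # bins below min_count flagged unreliable
  expect_false(cur$reliable[cur$sensitivity_db == 0])
})

test_that("binned SD is calibrated on pooled normal residuals", {
  set.seed(31)
  n <- 2e4
  rec <- make_residual_records(rep(1L, 3 * n),
                               rep(c(5, 18, 30), each = n),
                               rnorm(3 * n))
  cur <- sd_by_sensitivity(rec)
  for (b in c(5, 18, 30)) {
    expect_equal(cur$sd_db[cur$sensitivity_db == b], 1, tolerance = 0.03)
  }
})

test_that("per-location SD conserves counts and sees injected inflation", {
  set.seed(5)
  n <- 4000
  rec <- rbind(
    make_residual_records(rep(10L, n), rep(20, n), rnorm(n, 0, 2)),
    make_residual_records(rep(40L, n), rep(20, n), rnorm(n, 0, 4))
  )
  by_loc <- sd_by_location(rec, min_count = 25)
  pooled <- sd_by_sensitivity(rec, min_count = 25)
  agg <- tapply(by_loc$n, by_loc$sensitivity_db, sum)
  expect_equal(unname(agg[as.character(pooled$sensitivity_db)]),
               pooled$n, ignore_attr = TRUE)
  sd10 <- by_loc$sd_db[by_loc$location == 10 & by_loc$sensitivity_db == 20]
  sd40 <- by_loc$sd_db[by_loc$location == 40 & by_loc$sensitivity_db == 20]
  expect_equal(sd40 / sd10, 2, tolerance = 0.1)
})

test_that("band comparison flags inflated central variability", {
  g <- grid_24_2()
  set.seed(9)
  n_per <- 400
  recs <- do.call(rbind, lapply(g$index[!g$is_blind_spot], function(i) {
    band <- g$band[g$index == i]
    mult <- if (band == "central10") 1.5 else 1
    obs <- rep(5:30, length.out = n_per)
    make_residual_records(rep(as.integer(i), n_per), obs,
                          rnorm(n_per, 0, 2 * mult))
  }))
  cmp <- compare_bands(recs, min_count = 25)
  expect_setequal(names(cmp$curves),
                  c("central10", "mid10to20", "peripheral_gt20"))
  tc <- cmp$tests
  cen <- tc[tc$band_a == "central10" | tc$band_b == "central10", ]
  expect_true(all(cen$higher_band == "central10"))
  expect_true(all(cen$p_adj < 0.01))
  # equal-noise bands show no difference
  mid_per <- tc[tc$band_a == "mid10to20" & tc$band_b == "peripheral_gt20" |
                tc$band_a == "peripheral_gt20" & tc$band_b == "mid10to20", ]
  expect_gt(mid_per$p_adj, 0.05)
})

test_that("log-linear SD fit round-trips generating coefficients exactly", {
  fit <- fit_loglinear_sd(loglinear_curve(1.79, -0.027))
  expect_equal(fit$beta, -0.027, tolerance = 1e-12)
  expect_equal(fit$alpha, 1.79, tolerance = 1e-12)
  fit2 <- fit_loglinear_sd(loglinear_curve(2.34, -0.048), s_min = 10,
                           s_max = 35)
  expect_equal(fit2$beta, -0.048, tolerance = 1e-12)
  expect_equal(fit2$alpha, 2.34, tolerance = 1e-12)
  flat <- fit_loglinear_sd(sd_curve(0:35, rep(2.5, 36)))
  expect_equal(flat$beta, 0, tolerance = 1e-12)
  withzero <- sd_curve(0:10, c(0, exp(1.79 - 0.027 * (1:10))))
  expect_warning(fz <- fit_loglinear_sd(withzero, s_max = 10), "zero-SD")
  expect_equal(fz$beta, -0.027, tolerance = 1e-10)
})

test_that("two-knot spline SD fit round-trips the continuous form exactly", {
  cur <- spline_curve(1.39, c(0.029, -0.090, 0.104), c(14, 32))
  fit <- fit_spline_sd(cur, knots = c(14, 32))
  expect_equal(fit$alpha, 1.39, tolerance = 1e-10)
  expect_equal(fit$betas, c(0.029, -0.090, 0.104), tolerance = 1e-10)
  # evaluation at the variability peak is consistent with the peak SD
  expect_equal(log(evaluate_sd_model(fit, 11)), 1.39 + 0.029 * 11,
               tolerance = 1e-10)
  expect_equal(evaluate_sd_model(fit, 11), 5.5, tolerance = 0.01)
  # knots beyond the data collapse to the log-linear fit
  short <- loglinear_curve(1.5, -0.02, s = 0:10)
  deg <- fit_spline_sd(short, knots = c(14, 32), s_max = 10)
  expect_equal(deg$betas[1], -0.02, tolerance = 1e-10)
  expect_equal(deg$betas[2:3], c(0, 0))
  # a segment with a single bin errors, naming the segment
  sparse <- sd_curve(c(0, 5, 10, 15, 33), exp(c(1.3, 1.4, 1.5, 1.2, 1.0)))
  expect_error(fit_spline_sd(sparse, knots = c(14, 32)), "segment")
})

test_that("sigma evaluation covers all model kinds with continuity and clamping", {
  ll <- fit_loglinear_sd(loglinear_curve(1.79, -0.027))
  expect_equal(evaluate_sd_model(ll, 0), exp(1.79), tolerance = 1e-10)
  cur <- sd_curve(c(10, 12), c(4, 6), n = c(100, 100))
  expect_equal(evaluate_sd_model(cur, 11), 5)
  sp <- fit_spline_sd(spline_curve(1.39, c(0.029, -0.09, 0.104), c(14, 32)),
                      knots = c(14, 32))
  for (k in c(14, 32)) {
    expect_lt(abs(evaluate_sd_model(sp, k - 1e-9) -
                  evaluate_sd_model(sp, k + 1e-9)), 1e-9)
  }
  expect_warning(out <- evaluate_sd_model(ll, 40), "clamped")
  expect_equal(out, evaluate_sd_model(ll, 35))
  expect_true(all(evaluate_sd_model(anchor_noise_model(), 0:35) > 0))
})
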