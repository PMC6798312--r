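test_that("prediction schedules match the rolling protocol", {
  expect_equal(schedule_for(10)$windows, 5:9)
  expect_equal(schedule_for(15)$windows, c(5L, 7L, 9L, 11L, 13L))
  expect_equal(schedule_for(20)$windows, c(5L, 8L, 11L, 14L, 17L))
  expect_error(schedule_for(12), "schedule")
  custom <- schedule_for(12, windows = c(5, 8, 11))
  expect_equal(custom$windows, c(5L, 8L, 11L))
  expect_error(schedule_for(8, windows = c(5, 9)))  # window beyond target
})

test_that("fit RMSE is zero on exact data and matches the residual oracle", {
  perfect <- make_linear_series(0:9, base = 30, slope = -0.6)
  r <- fit_rmse(perfect, "linear")
  expect_equal(r$rmse, 0, tolerance = 1e-9)
  expect_equal(r$n_locations, 52L)
  # symmetric +/-1 deviations around a flat 20 dB line give RMSE exactly 1
  S <- matrix(rep(20 + c(1, -1, -1, 1), each = 54), 54, 4)
  alt <- make_series_from_matrix(S, 0:3)
  expect_equal(fit_rmse(alt, "linear")$rmse, 1, tolerance = 1e-9)
  # RMSE is invariant to a constant shift of the field
  S2 <- sensitivity_matrix(perfect) ; S2 <- S2 + 4
  set.seed(2); S2 <- pmin(S2 + matrix(rnorm(length(S2)), nrow(S2)), 50)
  shifted <- make_series_from_matrix(S2, 0:9)
  shifted5 <- make_series_from_matrix(S2 - 4, 0:9)
  expect_equal(fit_rmse(shifted, "linear")$rmse,
               fit_rmse(shifted5, "linear")$rmse, tolerance = 1e-9)
  # RMSE recomputed from exponential fits equals the exported-residual oracle
  set.seed(3)
  S3 <- pmax(sensitivity_matrix(perfect) +
             matrix(rnorm(54 * 10, 0, 2), 54, 10), 0)
  noisy <- make_series_from_matrix(S3, 0:9)
  r3 <- fit_rmse(noisy, "exponential", normative = normative_hill())
  res <- pool_residuals(list(noisy), "exponential",
                        normative = normative_hill(), min_followup = 3)
  mask <- location_inclusion_mask(noisy)
  res <- res[res$location %in% grid_24_2()$index[mask], ]
  expect_equal(r3$rmse, sqrt(mean(res$residual^2)), tolerance = 1e-9)
})

test_that("prediction RMSE is exact on noiseless trends and matches its oracle", {
  lin <- make_linear_series(seq(0, 18, by = 1), base = 30, slope = -0.5)
  r <- predict_rmse(lin, "linear", window = 5, target = 15)
  expect_equal(r$rmse, 0, tolerance = 1e-9)
  expect_error(predict_rmse(lin, "linear", window = 5, target = 25), "exams")
  # oracle recomputation from serialized per-location fits
  set.seed(8)
  S <- pmin(pmax(30 - 0.5 * matrix(rep(0:18, each = 54), 54) +
                 matrix(rnorm(54 * 19, 0, 2), 54), 0), 35)
  noisy <- make_series_from_matrix(S, 0:18)
  r2 <- predict_rmse(noisy, "linear", window = 7, target = 15)
  train <- make_series_from_matrix(S[, 1:7], 0:6)
  fits <- fit_all_locations(train, "linear", context = "variability")
  mask <- location_inclusion_mask(noisy)
  keep <- intersect(names(fits), as.character(grid_24_2()$index[mask]))
  err <- vapply(keep, function(k) {
    S[as.integer(k) + 1L, 15] - unname(predict(fits[[k]], 14))
  }, numeric(1))
  expect_equal(r2$rmse, sqrt(mean(err^2)), tolerance = 1e-9)
})

test_that("model comparison reports medians, pairing and signed-rank tests", {
  set.seed(21)
  eyes <- sprintf("e%03d", 1:100)
  base <- rexp(100, 1 / 2) + 1
  mk <- function(model, shift) {
    data.frame(eye_id = eyes, model = model, context = "prediction",
               target = 10L, window = 5L, rmse = base + shift,
               n_locations = 52L)
  }
  # identical vectors: p = 1, nothing flagged
  cmp_eq <- compare_models(rbind(mk("a", 0), mk("b", 0)))
  expect_equal(cmp_eq$tests$p_value, 1)
  expect_false(any(cmp_eq$medians$best))
  # a uniformly better model is flagged with a tiny p-value
  cmp <- compare_models(rbind(mk("a", 0), mk("b", -1)))
  expect_true(cmp$medians$best[cmp$medians$model == "b"])
  expect_lt(cmp$tests$p_adj, 1e-10)
  expect_equal(cmp$medians$median_rmse[cmp$medians$model == "a"],
               median(base))
  # unpaired eyes are dropped with a warning
  r <- rbind(mk("a", 0), mk("b", -1)[1:90, ])
  expect_warning(cmp2 <- compare_models(r), "unpaired")
  expect_equal(unique(cmp2$medians$n_eyes), 90L)
})

test_that("weighted and unweighted linear agree under constant noise", {
  set.seed(14)
  S <- pmin(pmax(28 - 0.3 * matrix(rep(0:9, each = 54), 54) +
                 matrix(rnorm(540, 0, 2), 54), 0), 35)
  series <- make_series_from_matrix(S, 0:9)
  const <- loglinear_noise_model(log(2), 0)
  rw <- fit_rmse(series, "weighted_linear", noise_model = const)
  ru <- fit_rmse(series, "linear")
  expect_equal(rw$rmse, ru$rmse, tolerance = 1e-10)
})

test_that("the benchmark bundle is complete, paired and deterministic", {
  spec <- cohort_spec("modeling", n_eyes = 4, seed = 19, n_exams = 20,
                      follow_up_years = 14, progressing_fraction = 1)
  co <- generate_cohort(spec)
  bm <- run_benchmark(co$series, models = c("linear", "exponential"),
                      targets = c(10, 15))
  expect_equal(nrow(bm$fit), 4 * 2)
  expect_equal(nrow(bm$prediction), 4 * 2 * 10)  # 2 targets x 5 windows
  m <- bm$comparisons$medians
  expect_equal(nrow(m), 2 * (10 + 1))            # 10 prediction cells + fit
  # pairing integrity: identical eye sets across models in every cell
  by_cell <- split(bm$prediction,
                   paste(bm$prediction$target, bm$prediction$window))
  for (cell in by_cell) {
    sets <- split(cell$eye_id, cell$model)
    expect_equal(sort(sets[[1]]), sort(sets[[2]]))
  }
  bm2 <- run_benchmark(co$series, models = c("linear", "exponential"),
                       targets = c(10, 15))
  expect_identical(bm$prediction, bm2$prediction)
})
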