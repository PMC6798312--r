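# Model-comparison harness: whole-series goodness-of-fit RMSE and the rolling
# prediction protocol (predict exam 10/15/20 from growing initial windows),
# with paired nonparametric comparison across models.

#' Rolling prediction schedule for a target exam
#'
#' The training windows used to predict a future exam: exam 10 is predicted
#' from the first 5, 6, 7, 8 and 9 exams; exam 15 from 5, 7, 9, 11, 13;
#' exam 20 from 5, 8, 11, 14, 17.
#'
#' @param target exam number to predict (10, 15 or 20), or any exam number if
#'   `windows` is supplied
#' @param windows custom training-window sizes (numbers of initial exams),
#'   strictly increasing and all below `target`
#' @return list with `target` and `windows`
#' @examples
#' schedule_for(15)$windows # 5 7 9 11 13
#' @export
schedule_for <- function(target, windows = NULL) {
  if (is.null(windows)) {
    windows <- switch(as.character(target),
      "10" = 5:9,
      "15" = seq(5, 13, by = 2),
      "20" = seq(5, 17, by = 3),
      stop("no built-in schedule for target ", target,
           "; supply windows explicitly")
    )
  }
  windows <- as.integer(windows)
  stopifnot(all(diff(windows) > 0), all(windows < target), all(windows >= 3))
  list(target = as.integer(target), windows = windows)
}

.rmse_row <- function(eye_id, model, context, target, window, err, n_loc) {
  data.frame(eye_id = eye_id, model = model, context = context,
             target = target, window = window,
             rmse = sqrt(mean(err^2)), n_locations = n_loc)
}

#' Goodness-of-fit RMSE for one eye
#'
#' Fits the model at every included location (modeling context) over the full
#' follow-up and returns the per-eye RMSE across all location-exam pairs.
#'
#' @param series a [vf_series()]
#' @param model_kind one of the [fit_all_locations()] kinds
#' @param noise_model sigma(s) model (weighted linear only)
#' @param normative a `vf_normative`
#' @param grid the test grid
#' @return one-row RMSE data frame
#' @export
fit_rmse <- function(series, model_kind, noise_model = NULL,
                     normative = normative_hill(), grid = grid_24_2()) {
  fits <- fit_all_locations(series, model_kind, noise_model = noise_model,
                            normative = normative, context = "modeling",
                            grid = grid)
  if (length(fits) == 0L) stop("no included locations for eye ", series$eye_id)
  times <- exam_times(series)
  S <- sensitivity_matrix(series)
  err <- unlist(lapply(names(fits), function(k) {
    i <- as.integer(k) + 1L
    S[i, ] - predict(fits[[k]], times)
  }))
  .rmse_row(series$eye_id, model_kind, "fit", NA_integer_, NA_integer_, err,
            length(fits))
}

#' Prediction RMSE for one eye, window and target
#'
#' Fits each included location on the first `window` exams and predicts the
#' sensitivity at the time of exam number `target`; the RMSE is computed
#' across locations against the observed values of the target exam. Location
#' inclusion is decided on the full series so every window of the same eye
#' scores the same locations.
#'
#' @inheritParams fit_rmse
#' @param window number of initial exams used for training
#' @param target exam number (1-based) to predict
#' @return one-row RMSE data frame
#' @export
predict_rmse <- function(series, model_kind, window, target,
                         noise_model = NULL, normative = normative_hill(),
                         grid = grid_24_2()) {
  n <- length(series$exams)
  if (n < target) {
    stop("series has ", n, " exams; cannot predict exam ", target)
  }
  stopifnot(window < target, window >= 3)
  include <- location_inclusion_mask(series, grid)
  train <- series
  train$exams <- series$exams[seq_len(window)]
  fits <- fit_all_locations(train, model_kind, noise_model = noise_model,
                            normative = normative, context = "variability",
                            grid = grid)
  fits <- fits[names(fits) %in% as.character(grid$index[include])]
  if (length(fits) == 0L) stop("no included locations for eye ", series$eye_id)
  t_target <- series$exams[[target]]$time_years
  obs <- series$exams[[target]]$sensitivities
  err <- vapply(names(fits), function(k) {
    obs[as.integer(k) + 1L] - predict(fits[[k]], t_target)
  }, numeric(1))
  .rmse_row(series$eye_id, model_kind, "prediction", target, window, err,
            length(fits))
}

#' Compare models on paired per-eye RMSE
#'
#' For every context/target/window cell, reports each model's median and IQR
#' RMSE and all pairwise two-sided Wilcoxon signed-rank tests (paired by eye,
#' Holm-adjusted within the cell). The model with the smallest median is
#' flagged. Eyes missing from any model in a cell are dropped with a warning.
#'
#' @param results rows from [fit_rmse()] / [predict_rmse()], stacked
#' @return list with `medians` and `tests` data frames
#' @export
compare_models <- function(results) {
  stopifnot(length(unique(results$model)) >= 2L)
  key <- paste(results$context, results$target, results$window)
  cells <- split(results, key)
  medians <- list()
  tests <- list()
  for (cell in cells) {
    models <- unique(cell$model)
    wide <- lapply(models, function(m) {
      r <- cell[cell$model == m, ]
      stats::setNames(r$rmse, r$eye_id)
    })
    names(wide) <- models
    eyes <- Reduce(intersect, lapply(wide, names))
    n_all <- length(unique(cell$eye_id))
    if (length(eyes) < n_all) {
      warning(n_all - length(eyes), " unpaired eye(s) dropped in cell ",
              cell$context[1], "/", cell$target[1], "/", cell$window[1])
    }
    meds <- vapply(wide, function(v) stats::median(v[eyes]), numeric(1))
    # flag the smallest median; ties flag nothing
    is_best <- meds == min(meds) & sum(meds == min(meds)) == 1L
    medians[[length(medians) + 1L]] <- data.frame(
      context = cell$context[1], target = cell$target[1],
      window = cell$window[1], model = models,
      median_rmse = meds,
      q1 = vapply(wide, function(v) unname(stats::quantile(v[eyes], 0.25)),
                  numeric(1)),
      q3 = vapply(wide, function(v) unname(stats::quantile(v[eyes], 0.75)),
                  numeric(1)),
      n_eyes = length(eyes),
      best = is_best
    )
    prs <- utils::combn(models, 2, simplify = FALSE)
    pv <- vapply(prs, function(p) {
      a <- wide[[p[1]]][eyes]; b <- wide[[p[2]]][eyes]
      if (isTRUE(all.equal(unname(a), unname(b)))) return(1)
      stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
    }, numeric(1))
    tests[[length(tests) + 1L]] <- data.frame(
      context = cell$context[1], target = cell$target[1],
      window = cell$window[1],
      model_a = vapply(prs, `[`, character(1), 1),
      model_b = vapply(prs, `[`, character(1), 2),
      median_diff = vapply(prs, function(p)
        stats::median(wide[[p[1]]][eyes] - wide[[p[2]]][eyes]), numeric(1)),
      p_value = pv,
      p_adj = stats::p.adjust(pv, method = "holm")
    )
  }
  list(medians = do.call(rbind, medians), tests = do.call(rbind, tests))
}

#' Run the full model-comparison benchmark on a cohort
#'
#' Computes goodness-of-fit RMSE for every model and eye, plus every
#' schedule's prediction RMSEs. Eyes with fewer exams than a target are
#' skipped for that target; per-eye failures are logged in the `failures`
#' element rather than aborting.
#'
#' @param cohort list of [vf_series()]
#' @param models model kinds to compare
#' @param targets prediction targets with built-in schedules
#' @param noise_model sigma(s) model for the weighted model
#' @param normative a `vf_normative`
#' @param grid the test grid
#' @return list with `fit`, `prediction` (RMSE data frames), `comparisons`
#'   (from [compare_models()]) and `failures`
#' @export
run_benchmark <- function(cohort, models = c("linear", "weighted_linear",
                                             "exponential"),
                          targets = c(10, 15, 20),
                          noise_model = anchor_noise_model(),
                          normative = normative_hill(), grid = grid_24_2()) {
  failures <- list()
  fit_rows <- list()
  pred_rows <- list()
  for (series in cohort) {
    for (m in models) {
      r <- tryCatch(fit_rmse(series, m, noise_model, normative, grid),
                    error = function(e) e)
      if (inherits(r, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(eye_id = series$eye_id, model = m, context = "fit",
                     message = conditionMessage(r))
      } else fit_rows[[length(fit_rows) + 1L]] <- r
    }
    for (tg in targets) {
      if (length(series$exams) < tg) next
      sched <- schedule_for(tg)
      for (w in sched$windows) {
        for (m in models) {
          r <- tryCatch(
            predict_rmse(series, m, w, tg, noise_model, normative, grid),
            error = function(e) e)
          if (inherits(r, "error")) {
            failures[[length(failures) + 1L]] <-
              data.frame(eye_id = series$eye_id, model = m,
                         context = "prediction",
                         message = conditionMessage(r))
          } else pred_rows[[length(pred_rows) + 1L]] <- r
        }
      }
    }
  }
  fit <- do.call(rbind, fit_rows)
  prediction <- do.call(rbind, pred_rows)
  all_rows <- rbind(fit, prediction)
  comparisons <- if (length(models) >= 2L && !is.null(all_rows))
    compare_models(all_rows) else NULL
  list(fit = fit, prediction = prediction, comparisons = comparisons,
       failures = if (length(failures)) do.call(rbind, failures) else NULL)
}
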