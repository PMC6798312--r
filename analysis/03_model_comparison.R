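#!/usr/bin/env Rscript

# Step 3: compare unweighted linear, variance-weighted linear and exponential
# pointwise regression for data fit and future-exam prediction on the
# simulated modeling cohort.
#
# The weighted model uses reciprocal-variance weights from the estimated SD
# curve of step 2 (falling back to the anchor model if step 2 has not run).
# Prediction follows the rolling protocol: exam 10 from the first 5..9 exams,
# exam 15 from 5,7,9,11,13, exam 20 from 5,8,11,14,17. Models are compared
# per window by median (IQR) per-eye RMSE with paired Wilcoxon signed-rank
# tests, Holm-adjusted.

suppressMessages(library(vfvar))

cfg <- list(seed = 20252L, targets = c(10, 15, 20),
            models = c("linear", "weighted_linear", "exponential"))
cohort <- read_cohort("results/cohort_modeling.csv")
message("Read ", length(cohort), " series")

noise <- if (file.exists("results/sd_curve.tsv")) {
  message("Using the SD curve estimated in step 2 for the weights")
  table_noise_model(read_sd_curve("results/sd_curve.tsv"))
} else {
  message("SD curve not found; using the anchor noise model for the weights")
  anchor_noise_model()
}

bm <- run_benchmark(cohort, models = cfg$models, targets = cfg$targets,
                    noise_model = noise, normative = normative_hill())
write_results_tsv(bm$fit, "results/rmse_fit.tsv")
write_results_tsv(bm$prediction, "results/rmse_prediction.tsv")
write_results_tsv(bm$comparisons$medians, "results/model_medians.tsv")
write_results_tsv(bm$comparisons$tests, "results/model_tests.tsv")
if (!is.null(bm$failures)) {
  write_results_tsv(bm$failures, "results/benchmark_failures.tsv")
  message(nrow(bm$failures), " per-eye failures logged")
}

m <- bm$comparisons$medians
fit_m <- m[m$context == "fit", ]
message("Data-fit median RMSE per model:")
print(fit_m[, c("model", "median_rmse", "q1", "q3", "n_eyes")],
      row.names = FALSE)
for (tg in cfg$targets) {
  w5 <- m[m$context == "prediction" & m$target == tg & m$window == 5, ]
  if (nrow(w5) == 0) next
  message("Predicting exam ", tg, " from 5 exams - best model: ",
          w5$model[w5$best], " (median RMSE ",
          round(min(w5$median_rmse), 2), " dB)")
}
write_run_config(cfg, "results/config_model_comparison.json")
message("Done; outputs in results/")
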