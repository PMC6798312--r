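# Synthetic longitudinal cohorts with known ground truth and
# sensitivity-dependent (heteroscedastic) Gaussian noise, floor/ceiling
# censored and rounded like real perimetric output. The stand-in for clinical
# datasets in simulation and recovery tests.

#' Ground-truth trajectory for one eye
#'
#' Describes the noiseless sensitivity path of every grid location. Kinds:
#' `stable` (constant at baseline), `linear` (baseline + rate * t, clamped to
#' \[0, ceiling\]), `exponential` (baseline * exp(rate * t)), `logistic`
#' (zeta / (1 + exp(a + rate * t)) with `a` chosen to match the baseline).
#'
#' @param baseline true baseline sensitivity per location (dB)
#' @param kinds per-location trajectory kind (recycled)
#' @param rates per-location rate: dB/year for linear, per-year log rate for
#'   exponential, per-year logit rate for logistic (recycled)
#' @param ceiling per-location ceiling used by the linear clamp (recycled)
#' @param zeta logistic upper asymptote (recycled)
#' @return an object of class `vf_truth`
#' @export
truth_trajectory <- function(baseline, kinds = "stable", rates = 0,
                             ceiling = 35, zeta = 35) {
  n <- length(baseline)
  structure(
    list(baseline = baseline, kinds = rep_len(kinds, n),
         rates = rep_len(rates, n), ceiling = rep_len(ceiling, n),
         zeta = rep_len(zeta, n)),
    class = "vf_truth"
  )
}

#' True sensitivities at a time point
#'
#' @param truth a [truth_trajectory()]
#' @param t time in years (scalar)
#' @return numeric vector of true sensitivities, one per location
#' @export
true_sensitivity <- function(truth, t) {
  stopifnot(inherits(truth, "vf_truth"), length(t) == 1L)
  s0 <- truth$baseline
  out <- s0
  k <- truth$kinds
  lin <- k == "linear"
  out[lin] <- clamp(s0[lin] + truth$rates[lin] * t, 0, truth$ceiling[lin])
  ex <- k == "exponential"
  out[ex] <- s0[ex] * exp(truth$rates[ex] * t)
  lo <- k == "logistic"
  if (any(lo)) {
    a <- log(pmax(truth$zeta[lo] / pmax(s0[lo], 1e-3) - 1, 1e-9))
    out[lo] <- truth$zeta[lo] / (1 + exp(a + truth$rates[lo] * t))
  }
  if (any(!k %in% c("stable", "linear", "exponential", "logistic"))) {
    stop("unknown trajectory kind")
  }
  out
}

#' Simulate one eye's visual-field series
#'
#' At each exam time the observed field is
#' `round(clamp(s*(t) + e, 0, 35))` with `e ~ Normal(0, sigma(s*(t)))`: noise
#' SD is keyed to the true sensitivity, the generative counterpart of binning
#' estimated residuals by observed sensitivity. Reliability indices are drawn
#' uniformly below the reliability cut-offs so every simulated exam passes
#' [is_reliable()].
#'
#' @param truth a [truth_trajectory()]
#' @param exam_times strictly increasing times in years, first usually 0
#' @param noise a sigma(s) model for [evaluate_sd_model()]; use a constant
#'   via `loglinear_noise_model(log(sd), 0)` or zero noise via `NULL`
#' @param baseline_age age at the first exam
#' @param seed RNG seed for reproducibility (optional)
#' @param eye_id identifier
#' @return a [vf_series()]
#' @export
generate_eye <- function(truth, exam_times, noise, baseline_age = 60,
                         seed = NULL, eye_id = "sim") {
  stopifnot(all(diff(exam_times) > 0))
  with_seed(seed, {
    exams <- lapply(exam_times, function(t) {
      s_true <- true_sensitivity(truth, t)
      if (is.null(noise)) {
        e <- 0
      } else {
        sigma <- evaluate_sd_model(noise, clamp(s_true, 0, 35))
        e <- stats::rnorm(length(s_true), 0, sigma)
      }
      obs <- round(clamp(s_true + e, 0, 35))
      vf_exam(time_years = t, sensitivities = obs,
              fp_rate = stats::runif(1, 0, 0.15),
              fn_rate = stats::runif(1, 0, 0.20),
              fixation_losses = stats::runif(1, 0, 0.5))
    })
    vf_series(eye_id = eye_id, baseline_age_years = baseline_age,
              exams = exams)
  })
}

#' Cohort specification
#'
#' Presets emulate the two study populations: `"variability"` (glaucoma eyes
#' with >= 6 exams and >= 3 years, median ~9 exams over ~9.5 years, baseline
#' pseudo-MD around -3 dB, half the eyes slowly progressing) and
#' `"modeling"` (POAG eyes with >= 10 exams and >= 6 years, median ~20 exams
#' over ~15 years, most eyes progressing). `truth = "stable"` freezes all
#' trajectories at baseline regardless of preset.
#'
#' @param preset `"variability"` or `"modeling"`
#' @param n_eyes number of eyes
#' @param seed master seed; all randomness derives from it
#' @param n_exams fixed exams per eye, or `NULL` for the preset distribution
#' @param follow_up_years fixed follow-up, or `NULL` for the preset
#'   distribution
#' @param truth `"preset"` (progression mix of the preset) or `"stable"`
#' @param noise a sigma(s) model; defaults to [anchor_noise_model()]
#' @param normative a `vf_normative`
#' @param progressing_fraction override the preset's fraction of progressing
#'   eyes
#' @param severity_median median of the per-eye baseline damage severity
#'   (mean field depression, dB). The default 3.2 matches the reported median
#'   baseline mean deviation; stable cohorts meant to reproduce the pooled
#'   observed-sensitivity distribution of a progressing population need a
#'   larger value since they lack progression-driven deepening.
#' @param min_gap minimum spacing between exams in years
#' @return an object of class `vf_cohort_spec`
#' @export
cohort_spec <- function(preset = c("variability", "modeling"), n_eyes = 100L,
                        seed = 1L, n_exams = NULL, follow_up_years = NULL,
                        truth = c("preset", "stable"),
                        noise = anchor_noise_model(),
                        normative = normative_hill(),
                        progressing_fraction = NULL, severity_median = 3.2,
                        min_gap = 0.25) {
  preset <- match.arg(preset)
  truth <- match.arg(truth)
  p <- if (preset == "variability") {
    list(min_exams = 6L, min_followup = 3, exams_mu = 4, exams_size = 2,
         gap_scale = 0.5, age_mean = 66, prog_frac = 0.7)
  } else {
    list(min_exams = 10L, min_followup = 6, exams_mu = 10, exams_size = 3,
         gap_scale = 0.28, age_mean = 63, prog_frac = 0.8)
  }
  if (!is.null(progressing_fraction)) p$prog_frac <- progressing_fraction
  if (truth == "stable") p$prog_frac <- 0
  if (!is.null(n_exams) && !is.null(follow_up_years) &&
      (n_exams - 1) * min_gap > follow_up_years) {
    stop("infeasible spec: ", n_exams, " exams cannot fit in ",
         follow_up_years, " years with a ", min_gap, "-year minimum gap")
  }
  structure(
    c(list(preset = preset, n_eyes = as.integer(n_eyes), seed = seed,
           n_exams = n_exams, follow_up_years = follow_up_years,
           truth = truth, noise = noise, normative = normative,
           severity_median = severity_median, min_gap = min_gap), p),
    class = "vf_cohort_spec"
  )
}

# Baseline damage field: a per-eye general-height offset and per-location
# jitter around the normative surface (between-subject spread), minus a
# diffuse depression and 0-2 focal Gaussian-shaped defects. Calibrated so the
# pooled observed sensitivities form a smooth distribution spanning the
# dynamic range with a long left tail and the median baseline pseudo-MD sits
# near -3 dB.
.random_baseline <- function(grid, normative, age, severity_median = 3.2) {
  normal <- normal_mean(normative, grid, age)
  height <- stats::rnorm(1, 0.5, 1.3)
  # between-subject spread taken from the normative SD surface
  jitter <- stats::rnorm(nrow(grid), 0, normal_sd(normative, grid, age))
  # eye severity = mean depression over the field, heavily right-skewed
  # (many mild eyes, few severe): median `severity_median` dB, long tail
  severity <- min(stats::rlnorm(1, log(severity_median), 1.25), 30)
  diffuse <- severity * stats::runif(1, 0.15, 0.5)
  focal_target <- severity - diffuse
  eligible <- which(!grid$is_blind_spot)
  shape <- rep(0, nrow(grid))
  n_clusters <- sample(1:3, 1, prob = c(0.45, 0.4, 0.15))
  for (i in seq_len(n_clusters)) {
    c_idx <- sample(eligible, 1)
    radius <- stats::runif(1, 5, 14)
    rel <- stats::runif(1, 0.5, 1)
    dist <- sqrt((grid$x_deg - grid$x_deg[c_idx])^2 +
                 (grid$y_deg - grid$y_deg[c_idx])^2)
    shape <- shape + rel * exp(-(dist / radius)^2)
  }
  focal <- shape * focal_target / mean(shape[eligible])
  base <- clamp(normal + height + jitter - diffuse - focal, 0, 35)
  base[grid$is_blind_spot] <- stats::runif(sum(grid$is_blind_spot), 0, 4)
  base
}

.random_truth <- function(grid, normative, age, prog_frac, stable = FALSE,
                          severity_median = 3.2) {
  baseline <- .random_baseline(grid, normative, age, severity_median)
  n <- nrow(grid)
  if (stable) {
    return(truth_trajectory(baseline, "stable", 0,
                            ceiling = ceiling_value(normative, grid, age)))
  }
  # all locations undergo slow physiologic (age-related) linear decay ...
  kinds <- rep("linear", n)
  rates <- rep(-(normative$age_slope %||% 0.065), n)
  if (stats::runif(1) < prog_frac) {
    # ... and progressing eyes add exponential loss where damage sits
    w <- (36 - baseline) + 3
    w[grid$is_blind_spot] <- 0
    n_prog <- sample(6:20, 1)
    prog <- sample.int(n, n_prog, prob = w / sum(w))
    kinds[prog] <- "exponential"
    rates[prog] <- -stats::runif(n_prog, 0.01, 0.15)
  }
  truth_trajectory(baseline, kinds, rates,
                   ceiling = ceiling_value(normative, grid, age))
}

.exam_times <- function(spec) {
  n <- spec$n_exams %||% (spec$min_exams +
    stats::rnbinom(1, size = spec$exams_size, mu = spec$exams_mu))
  jitter <- stats::rgamma(n - 1, shape = 2, scale = spec$gap_scale)
  if (!is.null(spec$follow_up_years)) {
    # scale only the jitter above the minimum gap so spacing stays feasible
    slack <- spec$follow_up_years - (n - 1) * spec$min_gap
    gaps <- spec$min_gap + jitter * slack / sum(jitter)
  } else {
    gaps <- spec$min_gap + jitter
    total <- sum(gaps)
    if (total < spec$min_followup) gaps <- gaps * spec$min_followup / total
  }
  c(0, cumsum(gaps))
}

#' Generate a synthetic cohort
#'
#' Draws per-eye exam schedules, ground-truth trajectories and noisy observed
#' series according to a [cohort_spec()]. All randomness flows from the
#' spec's master seed; the returned ground-truth record (per-eye seed,
#' trajectory parameters, exam times) suffices to regenerate every
#' observation.
#'
#' @param spec a [cohort_spec()]
#' @return list with `series` (list of [vf_series()]), `truth` (per-eye
#'   ground-truth records), `spec`, and `summary` (median exams, follow-up,
#'   baseline pseudo-MD and pseudo-MD slope across eyes)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "vf_cohort_spec"))
  grid <- grid_24_2()
  out <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_eyes), function(i) {
      age <- clamp(stats::rnorm(1, spec$age_mean, 9), 40, 82)
      times <- .exam_times(spec)
      truth <- .random_truth(grid, spec$normative, age, spec$prog_frac,
                             stable = spec$truth == "stable",
                             severity_median = spec$severity_median)
      eye_seed <- child_seed(spec$seed, i)
      series <- generate_eye(truth, times, spec$noise, baseline_age = age,
                             seed = eye_seed, eye_id = sprintf("eye%04d", i))
      list(series = series, truth = truth, seed = eye_seed, times = times,
           age = age)
    })
  })
  series <- lapply(out, `[[`, "series")
  truth <- lapply(out, function(o) o[c("truth", "seed", "times", "age")])
  names(truth) <- vapply(series, `[[`, character(1), "eye_id")
  md0 <- vapply(out, function(o)
    pseudo_md(o$series$exams[[1]], spec$normative, o$age, grid), numeric(1))
  md_slope <- vapply(out, function(o) {
    mds <- vapply(seq_along(o$series$exams), function(j)
      pseudo_md(o$series$exams[[j]], spec$normative,
                o$age + o$times[j], grid), numeric(1))
    .ols(o$times, mds)[2]
  }, numeric(1))
  summary <- data.frame(
    n_eyes = spec$n_eyes,
    median_exams = stats::median(vapply(series, function(s)
      length(s$exams), integer(1))),
    median_followup = stats::median(vapply(series, function(s)
      max(exam_times(s)), numeric(1))),
    median_baseline_md = stats::median(md0),
    median_md_slope = stats::median(md_slope)
  )
  list(series = series, truth = truth, spec = spec, summary = summary)
}

#' Pseudo mean deviation of an exam
#'
#' Mean over non-blind-spot locations of observed minus normal mean
#' sensitivity: the simulation stand-in for the device's MD index.
#'
#' @param exam a [vf_exam()] on the 24-2 grid
#' @param normative a `vf_normative`
#' @param age age at the exam
#' @param grid the test grid
#' @return pseudo-MD in dB (negative = depressed field)
#' @export
pseudo_md <- function(exam, normative, age, grid = grid_24_2()) {
  keep <- !grid$is_blind_spot
  mean(exam$sensitivities[keep] - normal_mean(normative, grid[keep, ], age))
}
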