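# Containers for a single perimetric exam and a longitudinal series of exams.

#' A single visual-field examination
#'
#' @param time_years years since the first exam of the series (>= 0)
#' @param sensitivities threshold sensitivities in dB, one per grid location
#'   (54 for 24-2, 76 for 30-2), each in \[0, 50\]
#' @param fp_rate,fn_rate false-positive / false-negative response rates in
#'   \[0, 1\]; may be `NA`
#' @param fixation_losses fixation-loss rate, unrestricted and optional
#' @return an object of class `vf_exam`
#' @export
vf_exam <- function(time_years, sensitivities, fp_rate = NA_real_,
                    fn_rate = NA_real_, fixation_losses = NA_real_) {
  stopifnot(is.numeric(time_years), length(time_years) == 1L, time_years >= 0,
            is.numeric(sensitivities),
            length(sensitivities) %in% c(54L, 76L))
  if (any(sensitivities < 0 | sensitivities > 50, na.rm = TRUE)) {
    stop("sensitivities must lie in [0, 50] dB")
  }
  for (r in list(fp_rate, fn_rate)) {
    if (!is.na(r) && (r < 0 || r > 1)) stop("fp/fn rates must lie in [0, 1]")
  }
  structure(
    list(time_years = time_years, sensitivities = as.numeric(sensitivities),
         fp_rate = fp_rate, fn_rate = fn_rate,
         fixation_losses = fixation_losses),
    class = "vf_exam"
  )
}

#' A longitudinal series of visual-field exams for one eye
#'
#' @param eye_id identifier for the eye
#' @param baseline_age_years age at the first exam
#' @param exams list of [vf_exam()] with strictly increasing `time_years`;
#'   at least two exams
#' @return an object of class `vf_series`
#' @export
vf_series <- function(eye_id, baseline_age_years, exams) {
  stopifnot(length(exams) >= 2L,
            all(vapply(exams, inherits, logical(1), "vf_exam")))
  times <- vapply(exams, `[[`, numeric(1), "time_years")
  if (any(diff(times) <= 0)) {
    stop("exam times must be strictly increasing within a series")
  }
  ns <- vapply(exams, function(e) length(e$sensitivities), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("all exams in a series must share the same grid")
  }
  structure(
    list(eye_id = eye_id, baseline_age_years = baseline_age_years,
         exams = exams),
    class = "vf_series"
  )
}

#' @export
print.vf_series <- function(x, ...) {
  times <- exam_times(x)
  cat("<vf_series> eye", x$eye_id, "-", length(x$exams), "exams over",
      round(max(times), 2), "years; baseline age",
      round(x$baseline_age_years, 1), "\n")
  invisible(x)
}

#' Exam times of a series
#' @param series a [vf_series()]
#' @return numeric vector of years since baseline
#' @export
exam_times <- function(series) {
  vapply(series$exams, `[[`, numeric(1), "time_years")
}

#' Sensitivity matrix of a series
#' @param series a [vf_series()]
#' @return locations x exams matrix of sensitivities (dB)
#' @export
sensitivity_matrix <- function(series) {
  vapply(series$exams, `[[`,
         numeric(length(series$exams[[1]]$sensitivities)), "sensitivities")
}

#' Keep only reliable exams of a series
#'
#' Drops exams failing [is_reliable()]. Errors if fewer than `min_exams`
#' remain.
#'
#' @param series a [vf_series()]
#' @param min_exams minimum number of surviving exams
#' @inheritParams is_reliable
#' @return a filtered [vf_series()]
#' @export
filter_reliable <- function(series, min_exams = 2L,
                            missing_policy = c("reject", "accept")) {
  missing_policy <- match.arg(missing_policy)
  keep <- vapply(series$exams, is_reliable, logical(1),
                 missing_policy = missing_policy)
  if (sum(keep) < min_exams) {
    stop("fewer than ", min_exams, " reliable exams remain for eye ",
         series$eye_id)
  }
  series$exams <- series$exams[keep]
  series
}

#' Mirror a left eye into right-eye convention
#'
#' A left eye tested on the 24-2 pattern produces the horizontal mirror image
#' of the right-eye point set (nasal extension and blind spot on the opposite
#' side). This reorders per-location sensitivities stored in screen order for
#' a left eye onto the canonical right-eye grid, so that anatomically
#' homologous locations share an index: blind spot maps to blind spot, nasal
#' extension to nasal extension. The permutation is an involution (each grid
#' row reverses).
#'
#' @param series a [vf_series()] on the 24-2 grid, left-eye orientation
#' @param grid the test grid
#' @return the mirrored [vf_series()]
#' @export
mirror_left_eye <- function(series, grid = grid_24_2()) {
  # storage order of the x-negated (left-eye) pattern; sends screen position
  # k to canonical position ord[k]
  ord <- order(-grid$y_deg, -grid$x_deg)
  series$exams <- lapply(series$exams, function(e) {
    out <- e$sensitivities
    out[ord] <- e$sensitivities
    e$sensitivities <- out
    e
  })
  series
}
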