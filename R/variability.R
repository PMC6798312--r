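# Residual-based variability estimation: pool pointwise regression residuals
# across a cohort, bin their SD by observed sensitivity (and location/band),
# and summarise the SD-vs-sensitivity relationship with log-linear and
# continuous piecewise-linear (spline) fits.

#' Pool pointwise regression residuals across a cohort
#'
#' For every eye, fits the requested model at each non-blind-spot location
#' (variability context: no 0-dB inclusion mask) and returns one record per
#' observation with its fitted value and residual (observed - fitted).
#' By default only series with at least `min_exams` exams and `min_followup`
#' years of follow-up enter the pool.
#'
#' @param cohort list of [vf_series()]
#' @param model_kind `"exponential"` (the primary choice), `"linear"` or
#'   `"logistic"`
#' @param normative a `vf_normative`; required for the exponential
#'   improvement branch
#' @param min_exams,min_followup series inclusion criteria; set to 0 to
#'   disable
#' @param grid the test grid
#' @return data frame of class `vf_residuals`: `eye_id`, `location`,
#'   `time_years`, `observed`, `fitted`, `residual`, `model`
#' @export
pool_residuals <- function(cohort, model_kind = c("exponential", "linear",
                                                  "logistic"),
                           normative = normative_hill(), min_exams = 6L,
                           min_followup = 3, grid = grid_24_2()) {
  model_kind <- match.arg(model_kind)
  if (length(cohort) == 0L) stop("empty cohort")
  out <- vector("list", length(cohort))
  for (k in seq_along(cohort)) {
    series <- cohort[[k]]
    times <- exam_times(series)
    if (length(times) < min_exams || max(times) < min_followup) next
    fits <- fit_all_locations(series, model_kind, normative = normative,
                              context = "variability", grid = grid)
    if (length(fits) == 0L) next
    S <- sensitivity_matrix(series)
    idx <- as.integer(names(fits))
    rows <- lapply(seq_along(fits), function(j) {
      i <- idx[j] + 1L
      fitted <- predict(fits[[j]], times)
      data.frame(eye_id = series$eye_id, location = idx[j],
                 time_years = times, observed = S[i, ],
                 fitted = fitted, residual = S[i, ] - fitted,
                 model = model_kind)
    })
    out[[k]] <- do.call(rbind, rows)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) stop("no series met the variability criteria")
  res <- do.call(rbind, out)
  class(res) <- c("vf_residuals", "data.frame")
  res
}

#' Build an SD curve object
#'
#' Low-level constructor for a per-dB residual-SD curve; used by
#' [sd_by_sensitivity()] and to assemble curves from known values (for
#' round-trip tests or external tables). Bins with fewer than `min_count`
#' residuals are flagged unreliable; unknown counts (`NA`) are treated as
#' reliable.
#'
#' @param sensitivity_db integer dB bin centres
#' @param sd_db residual SD per bin
#' @param n residual count per bin (`NA` if unknown)
#' @param min_count reliability threshold
#' @return a `vf_sd_curve` data frame
#' @export
sd_curve <- function(sensitivity_db, sd_db, n = NA_integer_, min_count = 25L) {
  d <- data.frame(sensitivity_db = as.integer(sensitivity_db), sd_db = sd_db,
                  n = as.integer(rep_len(n, length(sensitivity_db))))
  d$reliable <- (is.na(d$n) | d$n >= min_count) & is.finite(d$sd_db)
  attr(d, "min_count") <- min_count
  class(d) <- c("vf_sd_curve", "data.frame")
  d
}

#' Residual SD binned by observed sensitivity
#'
#' Residuals are grouped by their observed sensitivity rounded to integer dB
#' (0..35) and the sample SD (n-1 denominator) computed per bin.
#'
#' @param records a `vf_residuals` data frame (or any data frame with
#'   `observed` and `residual` columns)
#' @param min_count bins with fewer residuals are flagged unreliable
#' @return a `vf_sd_curve` over s = 0..35 with per-bin counts
#' @export
sd_by_sensitivity <- function(records, min_count = 25L) {
  stopifnot(nrow(records) >= 1L)
  s <- clamp(round(records$observed), 0, 35)
  bins <- 0:35
  grp <- factor(s, levels = bins)
  n <- as.integer(table(grp))
  sds <- tapply(records$residual, grp, stats::sd)
  sd_curve(bins, as.numeric(sds), n, min_count = min_count)
}

#' Residual SD curves per test location
#'
#' @inheritParams sd_by_sensitivity
#' @return data frame with one row per (location, dB bin): `location`,
#'   `sensitivity_db`, `sd_db`, `n`, `reliable`
#' @export
sd_by_location <- function(records, min_count = 25L) {
  stopifnot(all(c("location", "observed", "residual") %in% names(records)))
  parts <- split(records, records$location)
  out <- do.call(rbind, lapply(names(parts), function(loc) {
    cur <- sd_by_sensitivity(parts[[loc]], min_count = min_count)
    cbind(location = as.integer(loc), as.data.frame(cur))
  }))
  rownames(out) <- NULL
  out
}

#' Compare residual variability across eccentricity bands
#'
#' Computes a residual-SD curve per eccentricity band and tests each pair of
#' bands with a paired two-sided Wilcoxon signed-rank test across matched dB
#' bins that are reliable in both bands, Holm-adjusted over the three
#' comparisons.
#'
#' @inheritParams sd_by_sensitivity
#' @param grid the test grid supplying the band of each location
#' @return list with `curves` (per-band `vf_sd_curve`s) and `tests` (data
#'   frame: band pair, number of matched bins, median paired SD difference,
#'   raw and Holm-adjusted p-values, and which band is more variable)
#' @export
compare_bands <- function(records, grid = grid_24_2(), min_count = 25L) {
  band <- grid$band[match(records$location, grid$index)]
  present <- droplevels(unique(band))
  if (length(unique(band)) < 2L) stop("records span fewer than 2 bands")
  curves <- lapply(split(records, band), function(r) {
    if (nrow(r) == 0L) return(NULL)
    sd_by_sensitivity(r, min_count = min_count)
  })
  empty <- names(curves)[vapply(curves, is.null, logical(1))]
  if (length(empty)) {
    warning("bands with no data excluded: ", paste(empty, collapse = ", "))
  }
  bands <- names(curves)[!vapply(curves, is.null, logical(1))]
  pairs <- utils::combn(bands, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- curves[[p[1]]]; b <- curves[[p[2]]]
    ok <- a$reliable & b$reliable
    if (sum(ok) < 3L) {
      return(data.frame(band_a = p[1], band_b = p[2], n_bins = sum(ok),
                        median_diff = NA_real_, p_value = NA_real_))
    }
    d <- a$sd_db[ok] - b$sd_db[ok]
    w <- stats::wilcox.test(a$sd_db[ok], b$sd_db[ok], paired = TRUE,
                            exact = FALSE)
    data.frame(band_a = p[1], band_b = p[2], n_bins = sum(ok),
               median_diff = stats::median(d), p_value = w$p.value)
  }))
  tests$p_adj <- stats::p.adjust(tests$p_value, method = "holm")
  tests$higher_band <- ifelse(is.na(tests$median_diff), NA_character_,
                              ifelse(tests$median_diff > 0, tests$band_a,
                                     tests$band_b))
  list(curves = curves[bands], tests = tests)
}

.reliable_log_bins <- function(curve, s_min, s_max) {
  ok <- curve$reliable & curve$sensitivity_db >= s_min &
    curve$sensitivity_db <= s_max & is.finite(curve$sd_db)
  zero <- ok & curve$sd_db <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-SD bin(s) excluded from the log-scale fit")
    ok <- ok & curve$sd_db > 0
  }
  curve[ok, ]
}

#' Log-linear fit of the SD-vs-sensitivity curve
#'
#' Ordinary least squares of ln(SD) on sensitivity over the reliable bins in
#' \[`s_min`, `s_max`\]. Bins are equally weighted (one point per dB);
#' `count_weighted = TRUE` weights each bin by its residual count instead.
#'
#' @param curve a `vf_sd_curve`
#' @param s_min,s_max sensitivity range of the fit
#' @param count_weighted weight bins by their counts
#' @return a `vf_loglinear_sd` with fields `alpha` (intercept, ln dB) and
#'   `beta` (slope per dB)
#' @export
fit_loglinear_sd <- function(curve, s_min = 0, s_max = 35,
                             count_weighted = FALSE) {
  stopifnot(inherits(curve, "vf_sd_curve"))
  d <- .reliable_log_bins(curve, s_min, s_max)
  if (nrow(d) < 3L) stop("need at least 3 reliable bins in the fit range")
  w <- if (count_weighted) d$n else NULL
  cf <- .ols(d$sensitivity_db, log(d$sd_db), w = w)
  structure(list(alpha = unname(cf[1]), beta = unname(cf[2]),
                 s_range = c(s_min, s_max), n_bins = nrow(d)),
            class = "vf_loglinear_sd")
}

#' Continuous piecewise-linear (spline) fit of the SD-vs-sensitivity curve
#'
#' Fits ln(SD) as a continuous piecewise-linear function of sensitivity with
#' the given knots, by OLS on the truncated-power basis
#' \{1, s, (s-k1)+, (s-k2)+\}. Each segment must contain at least 2 reliable
#' bins; knots outside the data range collapse the corresponding basis column
#' and the model degrades gracefully toward the log-linear fit.
#'
#' @inheritParams fit_loglinear_sd
#' @param knots knot positions in dB, strictly increasing
#' @return a `vf_spline_sd` with `alpha`, `betas` (baseline slope and knot
#'   increments) and `knots`
#' @export
fit_spline_sd <- function(curve, knots = c(14, 32), s_min = 0, s_max = 35,
                          count_weighted = FALSE) {
  stopifnot(inherits(curve, "vf_sd_curve"), all(diff(knots) > 0))
  d <- .reliable_log_bins(curve, s_min, s_max)
  s <- d$sensitivity_db
  edges <- c(-Inf, knots, Inf)
  seg_n <- vapply(seq_len(length(knots) + 1L), function(j)
    sum(s > edges[j] & s <= edges[j + 1]), integer(1))
  active <- which(seg_n[-1] > 0)          # knots with data beyond them
  if (any(seg_n[c(1, active + 1)] < 2)) {
    bad <- which(seg_n < 2 & seq_along(seg_n) %in% c(1, active + 1))
    stop("segment ", paste(bad, collapse = ", "),
         " has fewer than 2 reliable bins")
  }
  X <- cbind(1, s)
  for (k in knots[active]) X <- cbind(X, pmax(s - k, 0))
  cf <- stats::.lm.fit(if (count_weighted) X * sqrt(d$n) else X,
                       if (count_weighted) log(d$sd_db) * sqrt(d$n)
                       else log(d$sd_db))$coefficients
  betas <- numeric(length(knots) + 1L)
  betas[1] <- cf[2]
  betas[active + 1L] <- cf[-(1:2)]
  structure(list(alpha = unname(cf[1]), betas = unname(betas), knots = knots,
                 continuous = TRUE, n_bins = nrow(d)),
            class = "vf_spline_sd")
}

#' @export
print.vf_loglinear_sd <- function(x, ...) {
  cat(sprintf("<vf_loglinear_sd> ln(SD) = %.4g %+.4g * s  (s in [%g, %g], %d bins)\n",
              x$alpha, x$beta, x$s_range[1], x$s_range[2], x$n_bins))
  invisible(x)
}

#' @export
print.vf_spline_sd <- function(x, ...) {
  cat(sprintf("<vf_spline_sd> ln(SD) = %.4g %+.4g*s", x$alpha, x$betas[1]))
  for (j in seq_along(x$knots)) {
    cat(sprintf(" %+.4g*(s-%g)+", x$betas[j + 1], x$knots[j]))
  }
  cat(sprintf("  (%d bins)\n", x$n_bins))
  invisible(x)
}
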