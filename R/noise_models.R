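# sigma(sensitivity) noise models: the bridge between estimated residual
# variability, simulation noise, and weighted-regression weights.

new_noise_model <- function(kind, ..., s_range = c(0, 35)) {
  structure(list(kind = kind, s_range = s_range, ...),
            class = "vf_noise_model")
}

#' Anchor-interpolated noise model
#'
#' sigma(s) by linear interpolation through the three reported residual-SD
#' anchors of the variability analysis — 3.4 dB at 0 dB, a 5.5 dB peak at
#' 11 dB, and a 2.0 dB minimum at 33 dB — with flat extrapolation above 33 dB.
#'
#' @param anchors data frame with columns `s` and `sd` (dB); the defaults are
#'   the three reported anchors
#' @return a `vf_noise_model` of kind `"anchor_interp"`
#' @examples
#' nm <- anchor_noise_model()
#' evaluate_sd_model(nm, c(0, 11, 33)) # 3.4, 5.5, 2.0
#' @export
anchor_noise_model <- function(anchors = data.frame(s = c(0, 11, 33),
                                                    sd = c(3.4, 5.5, 2.0))) {
  stopifnot(all(diff(anchors$s) > 0), all(anchors$sd > 0))
  new_noise_model("anchor_interp", anchors = anchors)
}

#' Log-linear noise model
#'
#' sigma(s) = exp(alpha + beta s). The defaults are the full-range
#' coefficients of the fitted log-linear variability curve.
#'
#' @param alpha intercept of ln(SD)
#' @param beta slope of ln(SD) per dB
#' @return a `vf_noise_model` of kind `"loglinear"`
#' @export
loglinear_noise_model <- function(alpha = 1.79, beta = -0.027) {
  new_noise_model("loglinear", alpha = alpha, beta = beta)
}

#' Spline noise model
#'
#' sigma(s) = exp of a continuous piecewise-linear function of s with two
#' knots. Defaults are the fitted two-knot variability spline (knots at 14
#' and 32 dB).
#'
#' @param alpha intercept of ln(SD)
#' @param betas slopes: baseline and the two knot increments
#' @param knots knot positions in dB
#' @return a `vf_noise_model` of kind `"spline"`
#' @export
spline_noise_model <- function(alpha = 1.39, betas = c(0.029, -0.090, 0.104),
                               knots = c(14, 32)) {
  stopifnot(length(betas) == length(knots) + 1L, all(diff(knots) > 0))
  new_noise_model("spline", alpha = alpha, betas = betas, knots = knots)
}

#' Table noise model
#'
#' sigma(s) by linear interpolation of a per-dB SD table (for example an
#' estimated [sd_by_sensitivity()] curve exported earlier), with flat
#' extrapolation beyond the tabulated range.
#'
#' @param table data frame with columns `sensitivity_db` and `sd_db`
#' @return a `vf_noise_model` of kind `"table"`
#' @export
table_noise_model <- function(table) {
  stopifnot(all(c("sensitivity_db", "sd_db") %in% names(table)))
  tab <- table[is.finite(table$sd_db) & table$sd_db > 0, ]
  if (nrow(tab) < 2L) stop("noise table needs at least 2 usable rows")
  new_noise_model("table", table = tab[order(tab$sensitivity_db), ])
}

#' Evaluate a sigma(sensitivity) model
#'
#' Accepts any noise model built by the constructors above, a fitted
#' log-linear or spline SD curve ([fit_loglinear_sd()], [fit_spline_sd()]),
#' or a raw [sd_by_sensitivity()] curve (interpolated across its reliable
#' bins). Sensitivities outside \[0, 35\] are clamped with a warning.
#'
#' @param model the sigma model
#' @param s sensitivities in dB
#' @return sigma values in dB (strictly positive)
#' @export
evaluate_sd_model <- function(model, s) {
  UseMethod("evaluate_sd_model")
}

# arguments modified before UseMethod() are not forwarded, so each method
# clamps for itself
.clamp_s <- function(s) {
  if (any(s < 0 | s > 35)) {
    warning("sensitivity outside [0, 35]; clamped")
    s <- clamp(s, 0, 35)
  }
  s
}

#' @export
evaluate_sd_model.vf_noise_model <- function(model, s) {
  s <- .clamp_s(s)
  out <- switch(model$kind,
    anchor_interp = stats::approx(model$anchors$s, model$anchors$sd, xout = s,
                                  rule = 2)$y,
    loglinear = exp(model$alpha + model$beta * s),
    spline = {
      ln <- model$alpha + model$betas[1] * s
      for (j in seq_along(model$knots)) {
        ln <- ln + model$betas[j + 1] * pmax(s - model$knots[j], 0)
      }
      exp(ln)
    },
    table = stats::approx(model$table$sensitivity_db, model$table$sd_db,
                          xout = s, rule = 2)$y,
    stop("unknown noise model kind: ", model$kind)
  )
  out
}

#' @export
evaluate_sd_model.vf_loglinear_sd <- function(model, s) {
  s <- .clamp_s(s)
  exp(model$alpha + model$beta * s)
}

#' @export
evaluate_sd_model.vf_spline_sd <- function(model, s) {
  s <- .clamp_s(s)
  ln <- model$alpha + model$betas[1] * s
  for (j in seq_along(model$knots)) {
    ln <- ln + model$betas[j + 1] * pmax(s - model$knots[j], 0)
  }
  exp(ln)
}

#' @export
evaluate_sd_model.vf_sd_curve <- function(model, s) {
  s <- .clamp_s(s)
  ok <- model$reliable & is.finite(model$sd_db) & model$sd_db > 0
  if (sum(ok) < 2L) stop("SD curve has fewer than 2 reliable bins")
  stats::approx(model$sensitivity_db[ok], model$sd_db[ok], xout = s,
                rule = 2)$y
}
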