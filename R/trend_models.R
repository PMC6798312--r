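# Pointwise trend models of threshold sensitivity over time: ordinary and
# variance-weighted linear regression, log-linearised exponential decay /
# improvement models, and a three-parameter logistic fitted by Newton-Raphson
# least squares. Floor/ceiling censoring is applied to predictions only.

LOG_FLOOR_DB <- 0.5 # half the instrument step; clamp before taking logs

new_trend_fit <- function(kind, alpha, beta, zeta = NA_real_,
                          ceiling_Y = NA_real_, n_obs, converged = TRUE) {
  structure(
    list(kind = kind, alpha = unname(alpha), beta = unname(beta),
         zeta = unname(zeta), ceiling_Y = unname(ceiling_Y),
         n_obs = as.integer(n_obs), converged = converged),
    class = "vf_trend_fit"
  )
}

#' @export
print.vf_trend_fit <- function(x, ...) {
  cat(sprintf("<vf_trend_fit %s> alpha=%.4g beta=%.4g", x$kind, x$alpha,
              x$beta))
  if (!is.na(x$zeta)) cat(sprintf(" zeta=%.4g", x$zeta))
  if (!is.na(x$ceiling_Y)) cat(sprintf(" Y=%.4g", x$ceiling_Y))
  cat(sprintf(" (n=%d%s)\n", x$n_obs, if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

.check_xy <- function(times, sens, min_n = 3L) {
  stopifnot(is.numeric(times), is.numeric(sens),
            length(times) == length(sens))
  if (length(times) < min_n) {
    stop("need at least ", min_n, " observations, got ", length(times))
  }
  if (diff(range(times)) == 0) stop("degenerate times: all equal")
}

# Weighted/unweighted simple linear regression via the QR in .lm.fit;
# returns c(intercept, slope).
.ols <- function(x, y, w = NULL) {
  X <- cbind(1, x)
  if (!is.null(w)) {
    sw <- sqrt(w)
    X <- X * sw
    y <- y * sw
  }
  stats::.lm.fit(X, y)$coefficients
}

#' Unweighted pointwise linear regression
#'
#' Ordinary least squares of sensitivity (dB) on time (years) at a single
#' location.
#'
#' @param times exam times in years
#' @param sens observed sensitivities in dB
#' @param ceiling_Y optional normative ceiling stored for later censoring of
#'   predictions
#' @return a `vf_trend_fit` with `kind = "linear"`
#' @examples
#' fit_linear(c(0, 1, 2), c(30, 28, 26)) # alpha 30, beta -2
#' @export
fit_linear <- function(times, sens, ceiling_Y = NA_real_) {
  .check_xy(times, sens)
  cf <- .ols(times, sens)
  new_trend_fit("linear", cf[1], cf[2], ceiling_Y = ceiling_Y,
                n_obs = length(times))
}

#' Variance-weighted pointwise linear regression
#'
#' Weighted least squares minimising sum(w_i (y_i - alpha - beta x_i)^2),
#' where the weights are the reciprocal observation variances (see
#' [weights_from_noise_model()]).
#'
#' @inheritParams fit_linear
#' @param weights a `vf_weight_spec` from [weights_from_noise_model()], or a
#'   numeric vector of positive weights
#' @return a `vf_trend_fit` with `kind = "weighted_linear"`
#' @export
fit_weighted_linear <- function(times, sens, weights, ceiling_Y = NA_real_) {
  .check_xy(times, sens)
  w <- if (inherits(weights, "vf_weight_spec")) weights$w else as.numeric(weights)
  stopifnot(length(w) == length(times))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be finite and strictly positive")
  }
  cf <- .ols(times, sens, w = w)
  fit <- new_trend_fit("weighted_linear", cf[1], cf[2], ceiling_Y = ceiling_Y,
                       n_obs = length(times))
  fit$weights <- w
  fit
}

#' Observation weights from a noise model
#'
#' Each observation y_i receives variance v_i = sigma(y_i)^2, with sigma
#' evaluated at the observed sensitivity rounded to integer dB, and weight
#' w_i = 1 / v_i.
#'
#' @param observed_sens observed sensitivities in dB
#' @param noise_model any model accepted by [evaluate_sd_model()]
#' @return a `vf_weight_spec` data frame with columns `v` (dB^2) and `w`
#' @export
weights_from_noise_model <- function(observed_sens, noise_model) {
  s <- clamp(round(observed_sens), 0, 35)
  sigma <- evaluate_sd_model(noise_model, s)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("noise model returned a non-positive sigma")
  }
  structure(data.frame(v = sigma^2, w = 1 / sigma^2),
            class = c("vf_weight_spec", "data.frame"))
}

#' Pointwise exponential regression (decay or improvement)
#'
#' The trend direction is first determined by unweighted linear regression.
#' A non-positive slope selects the decay model, OLS of ln(y) on time; a
#' positive slope selects the improvement model, OLS of ln(Y - y) on time,
#' where Y is the normative ceiling (normal age- and location-matched mean
#' + 2 SD). Values of y (or Y - y) below 0.5 dB are clamped to 0.5 dB before
#' taking logarithms.
#'
#' @inheritParams fit_linear
#' @param ceiling_Y normative ceiling in dB; a scalar or one value per
#'   observation (required only when the improvement branch is taken)
#' @return a `vf_trend_fit` with `kind` `"exp_decay"` or `"exp_improve"`;
#'   `alpha` and `beta` are on the log scale
#' @export
fit_exponential <- function(times, sens, ceiling_Y = NA_real_) {
  .check_xy(times, sens)
  slope <- .ols(times, sens)[2]
  if (slope <= 0) {
    z <- log(pmax(sens, LOG_FLOOR_DB))
    cf <- .ols(times, z)
    fit <- new_trend_fit("exp_decay", cf[1], cf[2],
                         ceiling_Y = if (length(ceiling_Y) > 1)
                           max(ceiling_Y) else ceiling_Y,
                         n_obs = length(times))
  } else {
    if (anyNA(ceiling_Y)) {
      stop("improvement model requires a normative ceiling_Y")
    }
    Y <- rep_len(ceiling_Y, length(sens))
    z <- log(pmax(Y - sens, LOG_FLOOR_DB))
    cf <- .ols(times, z)
    fit <- new_trend_fit("exp_improve", cf[1], cf[2], ceiling_Y = max(Y),
                         n_obs = length(times))
  }
  fit
}

# --- logistic least squares ------------------------------------------------

# Mean function zeta / (1 + exp(alpha + beta x)) and its derivatives.
.logis_mu <- function(p, x) {
  u <- 1 / (1 + exp(p[2] + p[3] * x))
  list(mu = p[1] * u, u = u)
}

.logis_sse <- function(p, x, y) {
  sum((y - .logis_mu(p, x)$mu)^2)
}

# Gradient and full Hessian of the residual sum of squares in (zeta, alpha,
# beta). Second derivatives of the mean are retained (Newton, not
# Gauss-Newton).
.logis_derivs <- function(p, x, y) {
  m <- .logis_mu(p, x)
  u <- m$u
  r <- y - m$mu
  du <- -u * (1 - u)                 # d u / d eta, eta = alpha + beta x
  # first derivatives of mu wrt (zeta, alpha, beta)
  J <- cbind(u, p[1] * du, p[1] * du * x)
  g <- -2 * colSums(r * J)
  # second derivatives of mu
  d2u <- -(1 - 2 * u) * du           # d^2 u / d eta^2
  H <- matrix(0, 3, 3)
  # mu_zz = 0; mu_za = du; mu_zb = du x; mu_aa = zeta d2u; etc.
  M <- list(
    c(1, 2, sum(r * du)), c(1, 3, sum(r * du * x)),
    c(2, 2, p[1] * sum(r * d2u)), c(2, 3, p[1] * sum(r * d2u * x)),
    c(3, 3, p[1] * sum(r * d2u * x^2))
  )
  H <- 2 * crossprod(J)
  for (m2 in M) {
    H[m2[1], m2[2]] <- H[m2[1], m2[2]] - 2 * m2[3]
    if (m2[1] != m2[2]) H[m2[2], m2[1]] <- H[m2[2], m2[1]] - 2 * m2[3]
  }
  list(g = g, H = H)
}

.logis_start <- function(times, sens, zeta_max, bump = 1) {
  zeta0 <- min(max(sens) + bump, zeta_max)
  z <- log(pmax(zeta0 / pmax(sens, 0.1) - 1, 1e-6))
  cf <- tryCatch(.ols(times, z), error = function(e) c(z[1], 0))
  beta0 <- cf[2]
  alpha0 <- z[1] - beta0 * times[1]
  c(zeta0, alpha0, beta0)
}

#' Pointwise logistic regression
#'
#' Fits y = zeta / (1 + exp(alpha + beta x)) by least squares using
#' Newton-Raphson on the sum-of-squares gradient, with step-halving and a
#' small set of deterministic restarts from perturbed starting values. The
#' upper asymptote is bounded to (0, 50\] dB, the instrument range.
#'
#' Starting values: zeta at max(y) + 1, beta from OLS on the logit transform,
#' alpha chosen to match the first observation. Convergence is declared when
#' the parameter change drops below `tol`.
#'
#' @inheritParams fit_linear
#' @param zeta_max upper bound for the asymptote (dB)
#' @param tol convergence tolerance on the parameter step
#' @param max_iter maximum Newton iterations per start
#' @param n_restarts perturbed restarts tried before giving up
#' @return a `vf_trend_fit` with `kind = "logistic"`; `converged` is FALSE if
#'   no start converged (the best iterate is still returned)
#' @export
fit_logistic <- function(times, sens, zeta_max = 50, tol = 1e-8,
                         max_iter = 200L, n_restarts = 5L) {
  .check_xy(times, sens, min_n = 4L)
  # deterministic perturbation table for restarts
  bumps <- c(1, 0.25, 3, 8, 0.5, 15)[seq_len(n_restarts + 1L)]
  best <- NULL
  for (b in bumps) {
    p <- .logis_start(times, sens, zeta_max, bump = b)
    res <- .logis_newton(p, times, sens, zeta_max, tol, max_iter)
    if (is.null(best) || res$sse < best$sse ||
        (res$converged && !best$converged && res$sse <= best$sse * (1 + 1e-6))) {
      best <- res
    }
    if (best$converged) break
  }
  if (is.null(best)) stop("logistic fit failed: singular Hessian at all starts")
  fit <- new_trend_fit("logistic", best$p[2], best$p[3], zeta = best$p[1],
                       n_obs = length(times), converged = best$converged)
  fit
}

.logis_newton <- function(p, x, y, zeta_max, tol, max_iter) {
  sse <- .logis_sse(p, x, y)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d <- .logis_derivs(p, x, y)
    step <- tryCatch(solve(d$H, d$g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # ridge fallback keeps iterating past indefinite Hessians
      step <- tryCatch(solve(d$H + diag(3) * (1e-6 + max(abs(diag(d$H)))* 1e-8),
                             d$g),
                       error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
    }
    # step-halving line search on the SSE
    lambda <- 1
    improved <- FALSE
    for (h in 1:30) {
      cand <- p - lambda * step
      cand[1] <- clamp(cand[1], 1e-3, zeta_max)
      s2 <- .logis_sse(cand, x, y)
      if (is.finite(s2) && s2 <= sse + 1e-12) {
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    delta <- max(abs(cand - p))
    p <- cand
    sse <- s2
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(p = p, sse = sse, converged = converged)
}

# --- prediction ------------------------------------------------------------

#' Predict sensitivity from a trend fit
#'
#' Linear and weighted-linear predictions are censored at the 0 dB floor and,
#' when available, at the normative ceiling Y. The exponential models tend
#' asymptotically toward their floor (decay) or ceiling (improvement) and need
#' no upper censoring; improvement predictions are floored at 0. Logistic
#' predictions lie in (0, zeta) by construction.
#'
#' @param object a `vf_trend_fit`
#' @param t times (years) at which to predict
#' @param ceiling_Y ceiling override in dB; defaults to the ceiling stored in
#'   the fit, or no upper censoring when none is available
#' @param ... unused
#' @return predicted sensitivities in dB
#' @export
predict.vf_trend_fit <- function(object, t, ceiling_Y = NULL, ...) {
  Y <- ceiling_Y %||% object$ceiling_Y
  if (is.null(Y) || anyNA(Y)) Y <- Inf
  eta <- object$alpha + object$beta * t
  switch(object$kind,
    linear = ,
    weighted_linear = clamp(eta, 0, Y),
    exp_decay = exp(eta),
    exp_improve = pmax(object$ceiling_Y - exp(eta), 0),
    logistic = object$zeta / (1 + exp(eta)),
    stop("unknown fit kind: ", object$kind)
  )
}

# --- whole-field fitting ---------------------------------------------------

#' Fit one trend model at every analysed location of a series
#'
#' In the `"variability"` context only the two blind-spot locations are
#' excluded; in the `"modeling"` context locations failing
#' [location_inclusion_mask()] (0 dB in two of the first three exams) are
#' excluded as well. Per-location fit failures are collected in the
#' `"failures"` attribute rather than aborting the pipeline.
#'
#' @param series a [vf_series()]
#' @param model_kind one of `"linear"`, `"weighted_linear"`, `"exponential"`,
#'   `"logistic"`
#' @param noise_model required for `"weighted_linear"`: the sigma(s) model
#'   used to build observation weights
#' @param normative a `vf_normative`; required for `"exponential"` (ceiling of
#'   the improvement branch) and used to censor linear predictions
#' @param context `"variability"` or `"modeling"` (see above)
#' @param grid the test grid
#' @return named list (by location index, 0-based) of `vf_trend_fit`;
#'   failures, if any, in `attr(, "failures")`
#' @export
fit_all_locations <- function(series, model_kind = c("linear",
                              "weighted_linear", "exponential", "logistic"),
                              noise_model = NULL, normative = NULL,
                              context = c("variability", "modeling"),
                              grid = grid_24_2()) {
  model_kind <- match.arg(model_kind)
  context <- match.arg(context)
  stopifnot(inherits(series, "vf_series"))
  include <- !grid$is_blind_spot
  if (context == "modeling") {
    include <- include & location_inclusion_mask(series, grid)
  }
  times <- exam_times(series)
  ages <- series$baseline_age_years + times
  S <- sensitivity_matrix(series)
  fits <- list()
  failures <- list()
  for (i in which(include)) {
    loc <- grid[i, ]
    Y <- if (!is.null(normative)) ceiling_value(normative, loc, ages) else NA_real_
    fit <- tryCatch(
      switch(model_kind,
        linear = fit_linear(times, S[i, ],
                            ceiling_Y = if (anyNA(Y)) NA_real_ else max(Y)),
        weighted_linear = {
          if (is.null(noise_model)) stop("weighted_linear needs a noise_model")
          fit_weighted_linear(times, S[i, ],
                              weights_from_noise_model(S[i, ], noise_model),
                              ceiling_Y = if (anyNA(Y)) NA_real_ else max(Y))
        },
        exponential = fit_exponential(times, S[i, ], ceiling_Y = Y),
        logistic = fit_logistic(times, S[i, ])
      ),
      error = function(e) e
    )
    key <- as.character(grid$index[i])
    if (inherits(fit, "error")) {
      failures[[key]] <- conditionMessage(fit)
    } else {
      fits[[key]] <- fit
    }
  }
  attr(fits, "failures") <- failures
  fits
}

#' Serialise per-location fits to a table
#'
#' @param fits output of [fit_all_locations()]
#' @param eye_id identifier recorded in the table
#' @return data frame with one row per fitted location
#' @export
fits_to_table <- function(fits, eye_id = NA) {
  if (length(fits) == 0L) {
    return(data.frame(eye_id = character(), location = integer(),
                      kind = character(), alpha = numeric(), beta = numeric(),
                      zeta = numeric(), ceiling = numeric(), n_obs = integer(),
                      converged = logical()))
  }
  do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(eye_id = eye_id, location = as.integer(k), kind = f$kind,
               alpha = f$alpha, beta = f$beta, zeta = f$zeta,
               ceiling = f$ceiling_Y, n_obs = f$n_obs,
               converged = f$converged)
  }))
}
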