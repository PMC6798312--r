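# Shared fixtures, built in code.

# A series where every location follows sens = base + slope * t exactly.
make_linear_series <- function(times = 0:5, base = 25, slope = 0,
                               eye_id = "lin", age = 60, fp = 0.05,
                               fn = 0.05) {
  exams <- lapply(times, function(t) {
    vf_exam(t, rep(pmin(pmax(base + slope * t, 0), 50), 54), fp_rate = fp,
            fn_rate = fn)
  })
  vf_series(eye_id, age, exams)
}

# A series with arbitrary per-exam constant fields.
make_series_from_matrix <- function(S, times, eye_id = "mat", age = 60) {
  exams <- lapply(seq_along(times), function(j) {
    vf_exam(times[j], S[, j], fp_rate = 0.05, fn_rate = 0.05)
  })
  vf_series(eye_id, age, exams)
}

# Residual records with prescribed noise, bypassing the regression step.
make_residual_records <- function(locations, observed, residuals,
                                  eye_id = "rec") {
  data.frame(eye_id = eye_id, location = locations,
             time_years = seq_along(observed), observed = observed,
             fitted = observed - residuals, residual = residuals,
             model = "exponential")
}

# An SD curve generated exactly from a log-linear law.
loglinear_curve <- function(alpha, beta, s = 0:35) {
  sd_curve(s, exp(alpha + beta * s))
}

# An SD curve generated exactly from a continuous two-knot spline.
spline_curve <- function(alpha, betas, knots, s = 0:35) {
  ln <- alpha + betas[1] * s
  for (j in seq_along(knots)) ln <- ln + betas[j + 1] * pmax(s - knots[j], 0)
  sd_curve(s, exp(ln))
}
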