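# vfvar

Heteroscedastic variability and pointwise trend models for longitudinal
visual fields.

## What this is for

Glaucoma progression is monitored with standard automated perimetry: repeated
24-2 visual-field exams, each yielding threshold sensitivities (dB) at 54
locations. Pointwise regression of sensitivity on time is the workhorse for
quantifying progression, but perimetric noise is heteroscedastic — its SD
depends on the sensitivity level, peaking in the mid range and shrinking near
the dynamic-range limits — and the instrument is bounded below at 0 dB and
above near the age-matched normal ceiling. `vfvar` is for researchers who
need to

* estimate the residual-SD-versus-sensitivity curve from longitudinal series
  (pooled pointwise regression residuals, binned by observed integer dB, with
  log-linear and two-knot spline summaries of `ln(SD)` vs sensitivity and
  eccentricity-band comparisons),
* fit and compare pointwise trend models — unweighted linear,
  variance-weighted linear (weights `w_i = 1/σ(y_i)²`), exponential
  decay/improvement (`ln(y) = α + βx`, `ln(Y − y) = α + βx` with the
  normative ceiling `Y = normal mean + 2 SD`), and logistic
  (`y = ζ / (1 + e^{α+βx})`) — with floor/ceiling censoring of predictions,
* simulate longitudinal cohorts with known ground truth and
  sensitivity-dependent Gaussian noise (`observed = round(clamp(s*(t) + e, 0,
  35))`, `e ~ N(0, σ(s*))`), and
* benchmark the models for data fit and for predicting exams 10, 15 and 20
  from growing initial windows, by per-eye RMSE with paired signed-rank
  comparisons.

The methods vignette (`vignettes/vf-variability-methods.Rmd`) documents the
models, the numerical contracts and the known limits of the
simulate-then-estimate loop.

## Worked example

```r
library(vfvar)

# simulate a glaucoma cohort: >=6 exams, >=3 years, 70% progressing,
# anchor-interpolated heteroscedastic noise
spec <- cohort_spec("variability", n_eyes = 40, seed = 7)
cohort <- generate_cohort(spec)
cohort$summary
#>   n_eyes median_exams median_followup median_baseline_md median_md_slope
#> 1     40           10        11.36033          -2.955375       -0.214165

# pool pointwise exponential-regression residuals and bin their SD
res <- pool_residuals(cohort$series, "exponential", normative = spec$normative)
curve <- sd_by_sensitivity(res)
subset(as.data.frame(curve), sensitivity_db %in% c(0, 11, 22, 33))
#>    sensitivity_db    sd_db    n reliable
#> 1               0 1.579789  496     TRUE
#> 12             11 4.468351  171     TRUE
#> 23             22 3.688000  585     TRUE
#> 34             33 1.913035 1244     TRUE

fit_loglinear_sd(curve)
#> <vf_loglinear_sd> ln(SD) = 1.39 -0.01442 * s  (s in [0, 35], 36 bins)

# a single location's trend and censored predictions
f <- fit_exponential(c(0, 1.1, 2, 3.2, 4.1), c(28, 26, 25, 22, 21))
f
#> <vf_trend_fit exp_decay> alpha=3.34 beta=-0.07241 (n=5)
round(predict(f, c(5, 8)), 2)
#> [1] 19.64 15.80
```

The residual SD rises from the 33 dB bin (≈1.9 dB) toward the mid range
(≈4.5 dB near 11 dB) and collapses at the floor bin, where censoring
truncates the residuals — the characteristic inverted-U of perimetric
variability.

## Analysis workflow

Three numbered drivers under `analysis/` run the full study on synthetic
cohorts and write their tables to `results/`:

```sh
Rscript analysis/01_simulate_cohorts.R     # cohorts + ground truth + summaries
Rscript analysis/02_variability_analysis.R # SD curve, log-linear/spline fits, bands
Rscript analysis/03_model_comparison.R     # fit + prediction RMSE benchmark
```

Every step writes a JSON config copy (including its seed) next to its
outputs, so each table can be regenerated exactly.

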