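# Normative sensitivity surface: age- and location-matched normal mean and SD,
# and the ceiling (mean + 2 SD) used by improvement models and censoring.

#' Parametric hill-of-vision normative surface
#'
#' A configurable stand-in for published normative perimetric tables, which
#' are not redistributable here. Normal mean sensitivity declines linearly
#' with eccentricity (the hill of vision) and with age past a reference age;
#' the normal between-subject SD grows slowly with eccentricity. Defaults are
#' calibrated qualitatively: ~0.07 dB per degree of eccentricity and
#' ~0.065 dB per year after age 45, peaking near 34 dB parafoveally.
#'
#' @param peak_db mean normal sensitivity at fixation for the reference age
#' @param ecc_slope decline in dB per degree of eccentricity
#' @param age_slope decline in dB per year of age past `age_ref`
#' @param age_ref age (years) at which age-related decline starts
#' @param sd_base normal SD (dB) at fixation
#' @param sd_ecc_slope increase of the normal SD per degree of eccentricity
#' @param age_range supported ages; queries outside this range error
#' @return an object of class `vf_normative`
#' @examples
#' nm <- normative_hill()
#' ceiling_value(nm, grid_24_2()[1, ], age = 60)
#' @export
normative_hill <- function(peak_db = 34, ecc_slope = 0.07, age_slope = 0.065,
                           age_ref = 45, sd_base = 1.5, sd_ecc_slope = 0.02,
                           age_range = c(20, 115)) {
  stopifnot(ecc_slope > 2 * sd_ecc_slope) # ceiling must fall with eccentricity
  structure(
    list(kind = "hill", peak_db = peak_db, ecc_slope = ecc_slope,
         age_slope = age_slope, age_ref = age_ref, sd_base = sd_base,
         sd_ecc_slope = sd_ecc_slope, age_range = age_range),
    class = "vf_normative"
  )
}

#' Table-driven normative surface
#'
#' Wraps a user-supplied per-location table of normal means and SDs at a
#' reference age, with a linear age correction.
#'
#' @param table data frame with columns `index`, `normal_mean_db`,
#'   `normal_sd_db`, valid at `age_ref`
#' @param age_slope decline in dB per year past `age_ref`
#' @param age_ref reference age of the table
#' @param age_range supported ages
#' @return an object of class `vf_normative`
#' @export
normative_table <- function(table, age_slope = 0.065, age_ref = 45,
                            age_range = c(20, 100)) {
  stopifnot(all(c("index", "normal_mean_db", "normal_sd_db") %in% names(table)),
            all(table$normal_sd_db > 0))
  structure(
    list(kind = "table", table = table[order(table$index), ],
         age_slope = age_slope, age_ref = age_ref, age_range = age_range),
    class = "vf_normative"
  )
}

.check_age <- function(normative, age) {
  if (any(age < normative$age_range[1] | age > normative$age_range[2])) {
    stop("age outside the normative model's supported range [",
         normative$age_range[1], ", ", normative$age_range[2], "]")
  }
}

.loc_ecc <- function(location) {
  if (is.data.frame(location)) location$eccentricity_deg
  else as.numeric(location)
}

#' Normal mean sensitivity at a location and age
#'
#' @param normative a `vf_normative` model
#' @param location grid rows (data frame with `eccentricity_deg` and, for
#'   table models, `index`) or, for the hill model, eccentricities in degrees
#' @param age age in years
#' @return normal mean sensitivity in dB (vectorised over locations)
#' @export
normal_mean <- function(normative, location, age) {
  stopifnot(inherits(normative, "vf_normative"))
  .check_age(normative, age)
  age_drop <- normative$age_slope * pmax(age - normative$age_ref, 0)
  if (normative$kind == "hill") {
    normative$peak_db - normative$ecc_slope * .loc_ecc(location) - age_drop
  } else {
    idx <- if (is.data.frame(location)) location$index else as.integer(location)
    m <- normative$table$normal_mean_db[match(idx, normative$table$index)]
    if (anyNA(m)) stop("location index not present in normative table")
    m - age_drop
  }
}

#' Normal between-subject SD at a location and age
#' @inheritParams normal_mean
#' @return normal SD in dB
#' @export
normal_sd <- function(normative, location, age) {
  stopifnot(inherits(normative, "vf_normative"))
  .check_age(normative, age)
  if (normative$kind == "hill") {
    normative$sd_base + normative$sd_ecc_slope * .loc_ecc(location)
  } else {
    idx <- if (is.data.frame(location)) location$index else as.integer(location)
    s <- normative$table$normal_sd_db[match(idx, normative$table$index)]
    if (anyNA(s)) stop("location index not present in normative table")
    s
  }
}

#' Normative ceiling: normal mean + 2 SD
#'
#' The upper censoring bound for linear predictions and the asymptote of the
#' exponential improvement model.
#'
#' @inheritParams normal_mean
#' @return ceiling in dB
#' @export
ceiling_value <- function(normative, location, age) {
  normal_mean(normative, location, age) + 2 * normal_sd(normative, location, age)
}
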