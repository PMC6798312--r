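# File interfaces: long-format cohort CSV, SD-curve and RMSE tables, ground
# truth JSON, and run configuration with a single master seed.

.cohort_cols <- c("eye_id", "exam_index", "time_years", "age",
                  "location_index", "x_deg", "y_deg", "sensitivity_db",
                  "fp_rate", "fn_rate")

#' Write a cohort to long-format CSV
#'
#' One row per (eye, exam, location): columns `eye_id`, `exam_index`
#' (1-based), `time_years`, `age`, `location_index` (0-based 24-2 index),
#' `x_deg`, `y_deg`, `sensitivity_db`, `fp_rate`, `fn_rate`. Comma-separated,
#' UTF-8, '.' decimal, missing values empty.
#'
#' @param cohort list of [vf_series()]
#' @param path output file
#' @param grid the test grid
#' @return `path`, invisibly
#' @export
write_cohort <- function(cohort, path, grid = grid_24_2()) {
  rows <- lapply(cohort, function(series) {
    do.call(rbind, lapply(seq_along(series$exams), function(j) {
      e <- series$exams[[j]]
      data.frame(eye_id = series$eye_id, exam_index = j,
                 time_years = e$time_years,
                 age = series$baseline_age_years + e$time_years,
                 location_index = grid$index, x_deg = grid$x_deg,
                 y_deg = grid$y_deg, sensitivity_db = e$sensitivities,
                 fp_rate = e$fp_rate, fn_rate = e$fn_rate)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from long-format CSV
#'
#' Validates the schema written by [write_cohort()]: known location indices,
#' strictly increasing exam times per eye, sensitivities in \[0, 50\], no
#' duplicated (eye, exam, location) rows. Errors report offending row
#' numbers. An optional `side` column ("L"/"left") mirrors left eyes into the
#' right-eye frame.
#'
#' @param path CSV file
#' @param grid the test grid
#' @return list of [vf_series()]
#' @export
read_cohort <- function(path, grid = grid_24_2()) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohort_cols, names(d))
  if (length(missing)) {
    stop("cohort file lacks columns: ", paste(missing, collapse = ", "))
  }
  bad <- which(!d$location_index %in% grid$index)
  if (length(bad)) {
    stop("unknown location index at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(d$sensitivity_db < 0 | d$sensitivity_db > 50)
  if (length(bad)) {
    stop("sensitivity outside [0, 50] dB at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  key <- paste(d$eye_id, d$exam_index, d$location_index)
  if (anyDuplicated(key)) {
    stop("duplicated (eye, exam, location) at row(s) ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  lapply(split(d, d$eye_id), function(de) {
    exams_idx <- sort(unique(de$exam_index))
    exams <- lapply(exams_idx, function(j) {
      dj <- de[de$exam_index == j, ]
      dj <- dj[match(grid$index, dj$location_index), ]
      if (anyNA(dj$sensitivity_db)) {
        stop("eye ", de$eye_id[1], " exam ", j, " is missing locations")
      }
      vf_exam(time_years = dj$time_years[1],
              sensitivities = dj$sensitivity_db,
              fp_rate = dj$fp_rate[1], fn_rate = dj$fn_rate[1])
    })
    times <- vapply(exams, `[[`, numeric(1), "time_years")
    if (any(diff(times) <= 0)) {
      stop("non-monotone exam times for eye ", de$eye_id[1])
    }
    series <- vf_series(eye_id = de$eye_id[1],
                        baseline_age_years = de$age[de$exam_index ==
                          exams_idx[1]][1] - times[1],
                        exams = exams)
    if ("side" %in% names(de) &&
        tolower(de$side[1]) %in% c("l", "left", "os")) {
      series <- mirror_left_eye(series, grid)
    }
    series
  })
}

#' Write / read an SD curve as a tab-separated table
#'
#' Columns `sensitivity_db`, `sd_db`, `n` — the package's exchange format for
#' per-dB variability estimates.
#'
#' @param curve a `vf_sd_curve`
#' @param path file path
#' @return `path` (write) or a `vf_sd_curve` (read)
#' @export
write_sd_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve)[c("sensitivity_db", "sd_db", "n")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sd_curve
#' @param min_count reliability threshold applied on read
#' @export
read_sd_curve <- function(path, min_count = 25L) {
  d <- utils::read.delim(path)
  stopifnot(all(c("sensitivity_db", "sd_db", "n") %in% names(d)))
  sd_curve(d$sensitivity_db, d$sd_db, d$n, min_count = min_count)
}

#' Write ground truth of a generated cohort as JSON
#'
#' Serialises per-eye trajectory parameters, exam times, age and the child
#' seed, sufficient (with the package) to regenerate every observation.
#'
#' @param truth the `truth` element of [generate_cohort()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(lapply(truth, function(t)
    list(seed = t$seed, age = t$age, times = t$times,
         baseline = t$truth$baseline, kinds = t$truth$kinds,
         rates = t$truth$rates, ceiling = t$truth$ceiling)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a run configuration
#'
#' A run configuration is a named list with at least a `seed`; JSON and (if
#' the yaml package is installed) YAML files are supported. A serialised copy
#' should be written alongside any output directory so every result can be
#' regenerated.
#'
#' @param path config file (.json, .yml or .yaml)
#' @return named list
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$seed)) stop("config must carry a seed")
  cfg
}

#' @rdname read_run_config
#' @param config named list to write
#' @return `path`, invisibly
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write an RMSE or comparison table as TSV
#' @param table data frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_results_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
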