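# The 24-2 and 30-2 test-point grids, eccentricity bands, and the
# reliability / location-inclusion filters applied before any regression.

.band_levels <- c("central10", "mid10to20", "peripheral_gt20")

# Band is a pure function of eccentricity with cut-points at 10 and 20 deg.
band_of <- function(ecc) {
  factor(ifelse(ecc <= 10, "central10",
                ifelse(ecc <= 20, "mid10to20", "peripheral_gt20")),
         levels = .band_levels)
}

.make_grid <- function(rows, blind_spot) {
  xs <- unlist(lapply(rows, `[[`, "x"))
  ys <- unlist(mapply(function(r) rep(r$y, length(r$x)), rows,
                      SIMPLIFY = FALSE))
  ord <- order(-ys, xs)
  xs <- xs[ord]; ys <- ys[ord]
  ecc <- sqrt(xs^2 + ys^2)
  data.frame(
    index = seq_along(xs) - 1L,
    x_deg = xs,
    y_deg = ys,
    is_blind_spot = mapply(function(x, y)
      any(x == blind_spot$x & y == blind_spot$y), xs, ys),
    eccentricity_deg = ecc,
    band = band_of(ecc),
    stringsAsFactors = FALSE
  )
}

#' The 24-2 test-point grid
#'
#' Returns the standard 54-point 24-2 perimetric grid in right-eye convention
#' (temporal eccentricity positive on x, superior positive on y). The two rows
#' at y = +/-3 carry the nasal extension to -27 degrees, and the two points at
#' (15, +/-3) fall on the physiologic blind spot. Locations are ordered top to
#' bottom, nasal to temporal, and indexed 0..53.
#'
#' Each location carries its Euclidean distance from fixation
#' (`eccentricity_deg`) and an eccentricity band: `central10` (<= 10 deg),
#' `mid10to20` (10-20 deg) or `peripheral_gt20` (> 20 deg).
#'
#' @return A 54-row data frame with columns `index`, `x_deg`, `y_deg`,
#'   `is_blind_spot`, `eccentricity_deg`, `band`.
#' @examples
#' g <- grid_24_2()
#' sum(!g$is_blind_spot)      # 52 analysed locations
#' table(g$band)
#' @export
grid_24_2 <- function() {
  rows <- list(
    list(y =  21, x = seq(-9, 9, by = 6)),
    list(y =  15, x = seq(-15, 15, by = 6)),
    list(y =   9, x = seq(-21, 21, by = 6)),
    list(y =   3, x = seq(-27, 21, by = 6)),
    list(y =  -3, x = seq(-27, 21, by = 6)),
    list(y =  -9, x = seq(-21, 21, by = 6)),
    list(y = -15, x = seq(-15, 15, by = 6)),
    list(y = -21, x = seq(-9, 9, by = 6))
  )
  .make_grid(rows, blind_spot = list(x = 15, y = c(3, -3)))
}

#' The 30-2 test-point grid
#'
#' The 76-point 30-2 grid in the same right-eye convention as [grid_24_2()].
#' The 54 locations of the 24-2 pattern are a subset of this grid.
#'
#' @return A 76-row data frame with the same columns as [grid_24_2()].
#' @export
grid_30_2 <- function() {
  rows <- list(
    list(y =  27, x = seq(-9, 9, by = 6)),
    list(y =  21, x = seq(-15, 15, by = 6)),
    list(y =  15, x = seq(-21, 21, by = 6)),
    list(y =   9, x = seq(-27, 27, by = 6)),
    list(y =   3, x = seq(-27, 27, by = 6)),
    list(y =  -3, x = seq(-27, 27, by = 6)),
    list(y =  -9, x = seq(-27, 27, by = 6)),
    list(y = -15, x = seq(-21, 21, by = 6)),
    list(y = -21, x = seq(-15, 15, by = 6)),
    list(y = -27, x = seq(-9, 9, by = 6))
  )
  .make_grid(rows, blind_spot = list(x = 15, y = c(3, -3)))
}

#' Restrict a 30-2 exam to the 24-2 locations
#'
#' Series acquired on the 30-2 pattern are analysed on the shared 24-2
#' locations only. Sensitivities are re-ordered to match [grid_24_2()] index
#' order; an exam already on the 54-point grid is returned unchanged.
#'
#' @param exam a [vf_exam()] whose `sensitivities` are indexed on the 76-point
#'   30-2 grid (or already on the 24-2 grid).
#' @return a [vf_exam()] on the 54-point 24-2 grid.
#' @export
subset_30_2 <- function(exam) {
  stopifnot(inherits(exam, "vf_exam"))
  n <- length(exam$sensitivities)
  if (n == 54L) return(exam)
  if (n != 76L) {
    stop("exam has ", n, " locations; expected 76 (30-2) or 54 (24-2)")
  }
  g24 <- grid_24_2()
  g30 <- grid_30_2()
  pos <- match(paste(g24$x_deg, g24$y_deg), paste(g30$x_deg, g30$y_deg))
  if (anyNA(pos)) stop("malformed 30-2 exam: shared 24-2 location missing")
  exam$sensitivities <- exam$sensitivities[pos]
  exam
}

#' Reliability filter for a single exam
#'
#' An exam is reliable when false positives are 20% or fewer and false
#' negatives 25% or fewer; fixation losses are not limited. Missing
#' false-positive or false-negative rates are treated according to
#' `missing_policy` ("reject", the conservative default, or "accept").
#'
#' @param exam a [vf_exam()]
#' @param missing_policy what to do when fp/fn rates are missing
#' @return logical flag
#' @examples
#' is_reliable(vf_exam(0, rep(30, 54), fp_rate = 0.20, fn_rate = 0.25))
#' @export
is_reliable <- function(exam, missing_policy = c("reject", "accept")) {
  stopifnot(inherits(exam, "vf_exam"))
  missing_policy <- match.arg(missing_policy)
  fp <- exam$fp_rate
  fn <- exam$fn_rate
  if (is.null(fp) || is.null(fn) || is.na(fp) || is.na(fn)) {
    if (missing_policy == "reject") {
      warning("missing reliability indices; exam treated as unreliable")
      return(FALSE)
    }
    return(TRUE)
  }
  fp <= 0.20 && fn <= 0.25
}

#' Per-location inclusion mask for the modeling pipeline
#'
#' Locations with a sensitivity of 0 dB in two of the first three examinations
#' are excluded from trend modeling, as are the two blind-spot locations. The
#' mask is used by the modeling/evaluation pipeline only; variability
#' estimation excludes just the blind spot.
#'
#' @param series a [vf_series()] with at least 3 exams
#' @param grid the test grid (defaults to [grid_24_2()])
#' @return logical vector of length 54, TRUE where the location is analysed
#' @export
location_inclusion_mask <- function(series, grid = grid_24_2()) {
  stopifnot(inherits(series, "vf_series"))
  if (length(series$exams) < 3L) {
    stop("location_inclusion_mask needs at least 3 exams")
  }
  first3 <- vapply(series$exams[1:3], function(e) e$sensitivities,
                   numeric(nrow(grid)))
  n_zero <- rowSums(first3 == 0)
  !grid$is_blind_spot & n_zero < 2
}

#' Export a grid as a tab-separated table
#' @param grid a grid data frame from [grid_24_2()] or [grid_30_2()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_grid_tsv <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
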