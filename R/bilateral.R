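## Core algorithm: mirror flip the right-eye map, take the cellwise absolute
## difference against the left-eye map, summarise the central 1.5-mm zone.

DIFF_MODALITIES <- c("FK", "FE", "BE", "CP")
PARAM_NAMES <- c("dFKmax", "dFKmean", "dFKsd",
                 "dFEmax", "dFEmean", "dFEsd",
                 "dBEmax", "dBEmean", "dBEsd",
                 "dCPmax", "dCPmean", "dCPsd")
PARAM_UNITS <- c(dFKmax = "D", dFKmean = "D", dFKsd = "D",
                 dFEmax = "um", dFEmean = "um", dFEsd = "um",
                 dBEmax = "um", dBEmean = "um", dBEsd = "um",
                 dCPmax = "um", dCPmean = "um", dCPsd = "um")

#' Bilateral differential map
#'
#' Computes the cellwise absolute difference between the left-eye map and
#' the mirror-flipped right-eye map of the same modality:
#' `|OS - flip(OD)|`. A cell is missing in the result iff it is missing in
#' either operand (after the flip). Because of the absolute value the result
#' is invariant, up to a column flip, under swapping the two eyes; the
#' central-zone summaries are therefore eye-order independent.
#'
#' @param os_map left-eye [topography_map].
#' @param od_map right-eye [topography_map]; flipped internally (pass an
#'   unflipped map).
#' @return An object of class `differential_map` with non-negative `values`.
#' @examples
#' od <- topography_map(matrix(43, 121, 121), "FK", "OD")
#' os <- topography_map(matrix(44, 121, 121), "FK", "OS")
#' d <- differential_map(os, od)
#' range(d$values)  # all cells 1
#' @export
differential_map <- function(os_map, od_map) {
  stopifnot(inherits(os_map, "topography_map"),
            inherits(od_map, "topography_map"))
  if (os_map$modality != od_map$modality)
    stop("modality mismatch: ", os_map$modality, " vs ", od_map$modality,
         call. = FALSE)
  flipped <- mirror_flip(od_map)
  vals <- abs(os_map$values - flipped$values)
  structure(list(values = vals, modality = os_map$modality,
                 units = os_map$units, spacing_mm = os_map$spacing_mm),
            class = "differential_map")
}

#' @export
print.differential_map <- function(x, ...) {
  cat(sprintf("differential_map: d%sM (%s), %d unmeasured cells, max %s\n",
              x$modality, x$units, sum(is.na(x$values)),
              format(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Central-zone mask on the topography lattice
#'
#' Enumerates the cell offsets `(di, dj)` around the vertex whose Euclidean
#' distance `spacing * sqrt(di^2 + dj^2)` does not exceed `radius_mm`
#' (boundary inclusive). For the default 1.5-mm radius at 0.1-mm spacing the
#' mask contains N = 709 cells; N is the divisor of the mean and of the
#' population standard deviation in [characteristic_triplet()].
#'
#' @param radius_mm zone radius in mm (default 1.5).
#' @param spacing_mm lattice spacing in mm (default 0.1).
#' @return An object of class `roi_mask` with fields `offsets` (two-column
#'   integer matrix), `n`, `radius_mm`, `spacing_mm`.
#' @examples
#' roi_mask(1.5)$n  # 709
#' roi_mask(0)$n    # 1 (vertex only)
#' @export
roi_mask <- function(radius_mm = 1.5, spacing_mm = GRID_SPACING_MM) {
  if (!is.numeric(radius_mm) || length(radius_mm) != 1 || radius_mm < 0)
    stop("'radius_mm' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("'spacing_mm' must be a single positive number", call. = FALSE)
  k <- floor(radius_mm / spacing_mm + 1e-9)
  idx <- seq.int(-k, k)
  grid <- expand.grid(di = idx, dj = idx)
  d <- spacing_mm * sqrt(grid$di^2 + grid$dj^2)
  keep <- d <= radius_mm + 1e-9  # tolerance guards exact boundary cells
  offsets <- as.matrix(grid[keep, , drop = FALSE])
  rownames(offsets) <- NULL
  structure(list(offsets = offsets, n = nrow(offsets),
                 radius_mm = radius_mm, spacing_mm = spacing_mm),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask: radius %.2f mm @ %.2f mm spacing, N = %d cells\n",
              x$radius_mm, x$spacing_mm, x$n))
  invisible(x)
}

roi_values <- function(diff, roi, center = CENTER_INDEX) {
  rows <- center + roi$offsets[, "di"]
  cols <- center + roi$offsets[, "dj"]
  if (any(rows < 1 | rows > nrow(diff$values) |
          cols < 1 | cols > ncol(diff$values)))
    stop("zone extends beyond the grid", call. = FALSE)
  diff$values[cbind(rows, cols)]
}

#' Max / mean / population-SD of a differential map's central zone
#'
#' Extracts the zone cells of a [differential_map] and returns their
#' maximum, arithmetic mean and standard deviation. The SD uses the
#' population divisor N (not N - 1), matching the defining formula
#' `sqrt((1/N) * sum((x_k - mean)^2))`.
#'
#' @param diff a [differential_map].
#' @param roi a [roi_mask] (default: 1.5-mm radius).
#' @param allow_missing if `FALSE` (default) any missing zone cell is an
#'   error; if `TRUE` the summaries use the present cells and the effective
#'   N is reported.
#' @return Named numeric vector `c(max, mean, sd)` with attribute `n`
#'   (effective cell count).
#' @export
characteristic_triplet <- function(diff, roi = roi_mask(),
                                   allow_missing = FALSE) {
  stopifnot(inherits(diff, "differential_map"), inherits(roi, "roi_mask"))
  x <- roi_values(diff, roi)
  if (anyNA(x)) {
    if (!allow_missing)
      stop(sum(is.na(x)), " missing cell(s) inside the ", roi$radius_mm,
           "-mm zone (use allow_missing = TRUE to summarise present cells)",
           call. = FALSE)
    x <- x[!is.na(x)]
    if (length(x) == 0) stop("no measured cells inside the zone", call. = FALSE)
  }
  m <- mean(x)
  out <- c(max = max(x), mean = m, sd = sqrt(mean((x - m)^2)))
  attr(out, "n") <- length(x)
  out
}

#' The twelve bilateral differential characteristic parameters
#'
#' For each of the four modalities FK, FE, BE and CP, forms the bilateral
#' differential map `|OS - flip(OD)|` and summarises its central zone into
#' (max, mean, population SD), yielding the twelve parameters
#' `dFKmax ... dCPsd`. Keratometry parameters are in diopters, elevation and
#' pachymetry parameters in micrometres.
#'
#' @param od right-eye [eye_exam] carrying FK, FE, BE, CP maps.
#' @param os left-eye [eye_exam] carrying the same modalities.
#' @param radius_mm zone radius in mm.
#' @param allow_missing passed to [characteristic_triplet()].
#' @return Named numeric vector of length 12, attribute `units`.
#' @examples
#' pair <- simulate_pair(pair_profile(seed = 7))
#' round(compute_parameters(pair$od, pair$os), 2)
#' @export
compute_parameters <- function(od, os, radius_mm = 1.5,
                               allow_missing = FALSE) {
  stopifnot(inherits(od, "eye_exam"), inherits(os, "eye_exam"))
  roi <- roi_mask(radius_mm)
  out <- numeric(0)
  for (mod in DIFF_MODALITIES) {
    if (is.null(od$maps[[mod]]) || is.null(os$maps[[mod]]))
      stop("modality ", mod, " missing from ",
           if (is.null(od$maps[[mod]])) "OD" else "OS", " exam", call. = FALSE)
    d <- differential_map(os$maps[[mod]], od$maps[[mod]])
    tri <- characteristic_triplet(d, roi, allow_missing = allow_missing)
    names(tri) <- paste0("d", mod, c("max", "mean", "sd"))
    out <- c(out, tri)
  }
  out <- out[PARAM_NAMES]
  attr(out, "units") <- PARAM_UNITS
  out
}

#' Differential parameters for every subject of a paired cohort
#'
#' @param cohort a `paired_cohort` from [load_cohort()] or
#'   [simulate_cohort()].
#' @param radius_mm zone radius in mm.
#' @param allow_missing passed through to [characteristic_triplet()].
#' @return Data frame with `subject_id`, `group` and the twelve parameter
#'   columns, one row per subject.
#' @export
cohort_parameters <- function(cohort, radius_mm = 1.5,
                              allow_missing = FALSE) {
  rows <- lapply(cohort, function(s) {
    p <- compute_parameters(s$od, s$os, radius_mm = radius_mm,
                            allow_missing = allow_missing)
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p)))
  })
  do.call(rbind, rows)
}
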