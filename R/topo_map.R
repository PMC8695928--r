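#' @keywords internal
"_PACKAGE"

## Grid conventions shared by every module: 121 x 121 cells, 0.1 mm spacing,
## corneal vertex at cell (61, 61) (1-based). Unmeasured cells are NA.
GRID_DIM <- 121L
GRID_SPACING_MM <- 0.1
CENTER_INDEX <- 61L

MODALITIES <- c("FK", "BK", "FE", "BE", "CP")
MODALITY_UNITS <- c(FK = "D", BK = "D", FE = "um", BE = "um", CP = "um")

#' Construct a single-eye topography map
#'
#' A `topography_map` holds one modality's 121 x 121 grid for one eye:
#' front/back keratometry (`FK`/`BK`, diopters), front/back elevation
#' (`FE`/`BE`, micrometres) or corneal pachymetry (`CP`, micrometres).
#' Cells are spaced 0.1 mm apart with the corneal vertex at cell (61, 61);
#' unmeasured cells (the corners of the square grid lie outside the imaged
#' zone) are `NA`.
#'
#' Sign conventions follow device exports: FK and CP values are positive,
#' BK values negative (the posterior surface has negative refractive power
#' under the keratometric index convention), elevations may take either sign.
#' Violations raise a warning by default and an error when `strict = TRUE`,
#' since exported BK sign conventions vary between device firmwares.
#'
#' @param values numeric 121 x 121 matrix; `NA` marks unmeasured cells.
#' @param modality one of `"FK"`, `"BK"`, `"FE"`, `"BE"`, `"CP"`.
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param strict logical; escalate sign-convention violations to errors.
#' @return An object of class `topography_map` with attributes `modality`,
#'   `laterality`, `units`, `spacing_mm` and `mirrored`.
#' @examples
#' m <- topography_map(matrix(43.3, 121, 121), "FK", "OD")
#' m$values[61, 61]
#' @export
topography_map <- function(values, modality, laterality, strict = FALSE) {
  modality <- match.arg(modality, MODALITIES)
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) != GRID_DIM || ncol(values) != GRID_DIM)
    stop(sprintf("grid must be %d x %d, got %d x %d",
                 GRID_DIM, GRID_DIM, nrow(values), ncol(values)),
         call. = FALSE)
  check_modality_signs(values, modality, strict)
  structure(
    list(values = values, modality = modality, laterality = laterality,
         units = unname(MODALITY_UNITS[modality]),
         spacing_mm = GRID_SPACING_MM, mirrored = FALSE),
    class = "topography_map")
}

check_modality_signs <- function(values, modality, strict) {
  present <- values[!is.na(values)]
  bad <- switch(modality,
    FK = sum(present <= 0),
    CP = sum(present <= 0),
    BK = sum(present >= 0),
    0L)
  if (bad > 0) {
    msg <- sprintf("%d cell(s) violate the %s sign convention (%s)",
                   bad, modality,
                   if (modality == "BK") "expected negative" else "expected positive")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.topography_map <- function(x, ...) {
  n_na <- sum(is.na(x$values))
  cat(sprintf("topography_map: %s (%s), %s%s, %dx%d grid @ %.1f mm, %d unmeasured cells\n",
              x$modality, x$units, x$laterality,
              if (isTRUE(x$mirrored)) " [mirrored]" else "",
              nrow(x$values), ncol(x$values), x$spacing_mm, n_na))
  cat(sprintf("  vertex (61,61): %s\n", format(x$values[CENTER_INDEX, CENTER_INDEX])))
  invisible(x)
}

#' Mirror-flip a topography map about the vertical meridian
#'
#' Reverses the column order (column c maps to column 122 - c, 1-based) so
#' that a right-eye map becomes directly comparable with the fellow left-eye
#' map: fellow eyes are approximate enantiomorphs and mirror about the
#' nasal-temporal (vertical) meridian. Rows are unchanged; the central
#' column 61 is fixed pointwise. The operation is an involution.
#'
#' @param map a [topography_map].
#' @return A `topography_map` with reversed columns and the `mirrored`
#'   attribute toggled.
#' @examples
#' m <- topography_map(matrix(rnorm(121^2) + 50, 121, 121), "FK", "OD")
#' identical(mirror_flip(mirror_flip(m))$values, m$values)
#' @export
mirror_flip <- function(map) {
  stopifnot(inherits(map, "topography_map"))
  map$values <- map$values[, rev(seq_len(ncol(map$values))), drop = FALSE]
  map$mirrored <- !isTRUE(map$mirrored)
  map
}

#' Bundle one eye's modality maps and scalar summaries
#'
#' An `eye_exam` collects the per-modality [topography_map]s for one eye
#' together with the scalar indices a topographer reports: flat/steep/mean/
#' maximum front keratometry (FK1, FK2, FKm, FKmax, diopters), the same for
#' the back surface (BK1...BKmax), thinnest corneal thickness (TCT) and
#' thickness at the vertex (CTV, micrometres).
#'
#' @param subject_id subject identifier.
#' @param laterality `"OD"` or `"OS"`.
#' @param maps named list of [topography_map]s; names from
#'   `c("FK","BK","FE","BE","CP")`. FK, FE, BE and CP are required for
#'   differential computation; BK is optional.
#' @param scalars optional named numeric vector (FK1, FK2, FKm, FKmax, BK1,
#'   BK2, BKm, BKmax, TCT, CTV).
#' @return An object of class `eye_exam`.
#' @export
eye_exam <- function(subject_id, laterality, maps, scalars = NULL) {
  laterality <- match.arg(laterality, c("OD", "OS"))
  if (!is.list(maps) || is.null(names(maps)))
    stop("'maps' must be a named list of topography_map objects", call. = FALSE)
  if (!all(names(maps) %in% MODALITIES))
    stop("unknown modality name(s): ",
         paste(setdiff(names(maps), MODALITIES), collapse = ", "), call. = FALSE)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!inherits(m, "topography_map"))
      stop("maps[['", nm, "']] is not a topography_map", call. = FALSE)
    if (m$modality != nm)
      stop("maps[['", nm, "']] has modality ", m$modality, call. = FALSE)
    if (m$laterality != laterality)
      stop("maps[['", nm, "']] has laterality ", m$laterality,
           " but the exam is ", laterality, call. = FALSE)
  }
  if (!is.null(scalars)) {
    sc <- scalars
    chk <- function(cond, what)
      if (isTRUE(cond)) stop("scalar ordering violated: ", what, call. = FALSE)
    has <- function(...) all(c(...) %in% names(sc)) && !anyNA(sc[c(...)])
    if (has("FK1", "FK2")) chk(sc[["FK1"]] > sc[["FK2"]] + 1e-9, "FK1 <= FK2")
    if (has("FK2", "FKmax")) chk(sc[["FK2"]] > sc[["FKmax"]] + 1e-9, "FK2 <= FKmax")
    if (has("TCT", "CTV")) chk(sc[["TCT"]] > sc[["CTV"]] + 1e-9, "TCT <= CTV")
  }
  structure(list(subject_id = as.character(subject_id), laterality = laterality,
                 maps = maps, scalars = scalars),
            class = "eye_exam")
}

#' @export
print.eye_exam <- function(x, ...) {
  cat(sprintf("eye_exam: subject %s, %s, modalities: %s\n",
              x$subject_id, x$laterality, paste(names(x$maps), collapse = " ")))
  if (!is.null(x$scalars)) {
    cat("  scalars:\n")
    print(round(x$scalars, 2))
  }
  invisible(x)
}
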