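## Matrix file dialect: 121 comma-separated values per line, 121 lines,
## no header, "NA" for unmeasured cells, '.' decimal separator. Chosen over
## spreadsheet workbooks so fixtures are deterministic and diffable.

#' Read a topography matrix file
#'
#' Parses a plain-text delimited 121 x 121 grid (one line per row, no
#' header) into a validated [topography_map]. Parsing is locale-independent:
#' the decimal separator is always `'.'` and the missing-cell sentinel is a
#' fixed token.
#'
#' @param path path to the matrix file.
#' @param modality one of `"FK"`, `"BK"`, `"FE"`, `"BE"`, `"CP"`.
#' @param laterality `"OD"` or `"OS"`.
#' @param sep field delimiter (default comma).
#' @param na_token sentinel for unmeasured cells (default `"NA"`).
#' @param strict escalate sign-convention violations to errors.
#' @return A [topography_map].
#' @seealso [write_topo_matrix()]
#' @export
read_topo_matrix <- function(path, modality, laterality, sep = ",",
                             na_token = "NA", strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != GRID_DIM)
    stop(sprintf("grid must be %d x %d, got %d rows in %s",
                 GRID_DIM, GRID_DIM, length(lines), path), call. = FALSE)
  fields <- strsplit(lines, sep, fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != GRID_DIM)) {
    bad <- which(ncols != GRID_DIM)[1]
    stop(sprintf("grid must be %d x %d, row %d of %s has %d columns",
                 GRID_DIM, GRID_DIM, bad, path, ncols[bad]), call. = FALSE)
  }
  vals <- matrix(NA_real_, GRID_DIM, GRID_DIM)
  for (i in seq_len(GRID_DIM)) {
    row <- trimws(fields[[i]])
    miss <- row == na_token
    parsed <- suppressWarnings(as.numeric(row))
    bad <- which(!miss & is.na(parsed))
    if (length(bad) > 0)
      stop(sprintf("unparseable cell at row %d, column %d of %s: '%s'",
                   i, bad[1], path, row[bad[1]]), call. = FALSE)
    parsed[miss] <- NA_real_
    vals[i, ] <- parsed
  }
  topography_map(vals, modality, laterality, strict = strict)
}

#' Write a topography map to a matrix file
#'
#' Output is deterministic: fixed delimiter, fixed number of decimal places
#' and a fixed missing-cell sentinel, so two writes of the same map are
#' byte-identical.
#'
#' @param map a [topography_map].
#' @param path output file path.
#' @param sep field delimiter.
#' @param digits decimal places written for each cell.
#' @param na_token sentinel written for unmeasured cells.
#' @return Invisibly, `path`.
#' @export
write_topo_matrix <- function(map, path, sep = ",", digits = 4,
                              na_token = "NA") {
  stopifnot(inherits(map, "topography_map"))
  txt <- matrix(na_token, nrow(map$values), ncol(map$values))
  ok <- !is.na(map$values)
  txt[ok] <- formatC(map$values[ok], format = "f", digits = digits)
  lines <- apply(txt, 1, paste, collapse = sep)
  con <- file(path, open = "wb")  # fixed LF endings for byte-identical output
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Load a paired cohort from a manifest
#'
#' The manifest is delimited text with a header row and columns
#' `subject_id`, `group` and per-eye matrix-file paths `od_fk`, `od_fe`,
#' `od_be`, `od_cp`, `os_fk`, `os_fe`, `os_be`, `os_cp` (optionally `od_bk`,
#' `os_bk`). Paths are resolved relative to `dir`. Subjects with any missing
#' or unreadable required file are skipped with a message; the skip count is
#' returned in the `n_skipped` attribute.
#'
#' @param dir directory containing the matrix files.
#' @param manifest path to the manifest file.
#' @param sep manifest field delimiter.
#' @param strict passed to [read_topo_matrix()].
#' @return A list of class `paired_cohort`: elements with fields
#'   `subject_id`, `group`, `od`, `os` ([eye_exam]s), plus attribute
#'   `n_skipped`.
#' @export
load_cohort <- function(dir, manifest, sep = ",", strict = FALSE) {
  tab <- utils::read.table(manifest, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty manifest: ", manifest, call. = FALSE)
  required <- c("subject_id", "group",
                "od_fk", "od_fe", "od_be", "od_cp",
                "os_fk", "os_fe", "os_be", "os_cp")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0)
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(tab$subject_id[duplicated(tab$subject_id)]), collapse = ", "),
         call. = FALSE)

  modal_cols <- c(FK = "fk", FE = "fe", BE = "be", CP = "cp")
  subjects <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    exams <- list()
    ok <- TRUE
    for (eye in c("od", "os")) {
      maps <- list()
      for (mod in names(modal_cols)) {
        col <- paste0(eye, "_", modal_cols[[mod]])
        f <- file.path(dir, row[[col]])
        if (is.na(row[[col]]) || !nzchar(row[[col]]) || !file.exists(f)) {
          ok <- FALSE
          break
        }
        maps[[mod]] <- read_topo_matrix(f, mod, toupper(eye), strict = strict)
      }
      if (!ok) break
      bk_col <- paste0(eye, "_bk")
      if (bk_col %in% names(tab) && !is.na(row[[bk_col]]) &&
          nzchar(row[[bk_col]]) && file.exists(file.path(dir, row[[bk_col]])))
        maps[["BK"]] <- read_topo_matrix(file.path(dir, row[[bk_col]]), "BK",
                                         toupper(eye), strict = strict)
      exams[[eye]] <- eye_exam(row$subject_id, toupper(eye), maps)
    }
    if (!ok) {
      n_skipped <- n_skipped + 1L
      message("skipping subject ", row$subject_id, ": incomplete exam pair")
      next
    }
    subjects[[length(subjects) + 1L]] <-
      list(subject_id = as.character(row$subject_id),
           group = as.character(row$group),
           od = exams$od, os = exams$os)
  }
  structure(subjects, class = "paired_cohort", n_skipped = n_skipped)
}

#' Write a per-subject characteristic-parameter table
#'
#' One row per subject: `subject_id`, `group` (if present) and the twelve
#' differential parameters in fixed column order
#' (`dFKmax, dFKmean, dFKsd, dFEmax, ..., dCPsd`).
#'
#' @param params data frame as produced by [cohort_parameters()].
#' @param path output path.
#' @param sep field delimiter.
#' @return Invisibly, `path`.
#' @export
write_parameter_table <- function(params, path, sep = ",") {
  utils::write.table(params, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
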