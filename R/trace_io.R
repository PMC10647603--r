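index_col_names <- c("", " ", "...1", "x", "x1", "row", "slice", "frame", "n", "a")

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an ImageJ Multi Measure intensity table
#'
#' Reads the delimited table produced by ImageJ's ROI manager Multi
#' Measure (with "Measure all slices" and "One row per slice"): one header
#' row, one row per frame, one mean-intensity column per ROI, and
#' optionally a leading row-number column. Both comma- and tab-delimited
#' files are accepted (the delimiter is sniffed from the header line).
#' Column naming varies between ImageJ versions ("Mean1" vs
#' "Mean(name)"), so every non-index column is treated as a ROI, in file
#' order. The exported file carries no time metadata, so the recording
#' duration must be supplied by the caller.
#'
#' By protocol the cell-free background region is traced last, so the
#' last ROI column is taken as the background unless `background` names
#' another column.
#'
#' @param path Path to the delimited file.
#' @param duration_s Recording duration in seconds.
#' @param background Optional background column name (default: last ROI
#'   column).
#' @return A [intensity_table()].
#' @export
read_multimeasure <- function(path, duration_s, background = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- sniff_delim(path)
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, show_col_types = FALSE,
    name_repair = "minimal"
  )
  if (nrow(raw) < 2L) abort("Intensity table must have at least 2 rows (frames).")
  n <- nrow(raw)
  # Drop a leading row-number column, recognized by name or by content 1..n.
  first <- names(raw)[1]
  first_num <- suppressWarnings(as.numeric(raw[[1]]))
  looks_index <- tolower(trimws(first)) %in% index_col_names ||
    (!grepl("mean", first, ignore.case = TRUE) &&
       all(is.finite(first_num)) && identical(first_num, as.numeric(seq_len(n))))
  if (looks_index && ncol(raw) > 1L) raw <- raw[-1]
  parsed <- vector("list", ncol(raw))
  for (j in seq_along(raw)) {
    num <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(!is.finite(num))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric or non-finite intensity in column '%s' at row %d (value '%s').",
        names(raw)[j], bad[1], raw[[j]][bad[1]]
      ))
    }
    parsed[[j]] <- num
  }
  df <- as_tibble(setNames(parsed, names(raw)))
  intensity_table(df, duration_s = duration_s, background = background)
}

#' Write an intensity table to CSV
#'
#' Writes the `frame` column plus all ROI columns in order, comma
#' delimited, readable back with [read_multimeasure()].
#'
#' @param table An [intensity_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_intensity_table <- function(table, path) {
  stopifnot(inherits(table, "ca_intensity"))
  out <- as_tibble(as.data.frame(table))
  names(out)[1] <- "Frame"
  readr::write_csv(out, path)
  invisible(path)
}

fmt_num <- function(x) {
  if (is.numeric(x)) ifelse(is.na(x), "", sprintf("%.9g", x)) else x
}

write_formatted_csv <- function(df, path) {
  out <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt_num))
  out <- dplyr::mutate(out, dplyr::across(
    dplyr::where(is.logical), function(x) ifelse(is.na(x), "", as.character(x))
  ))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write per-transient and per-cell feature tables
#'
#' Emits three comma-delimited files into `dir`: `transients.csv` (one row
#' per detected transient per cell, complete or not), `cells.csv` (one row
#' per cell: transient count, the eleven per-cell feature means, QC
#' counts) and `cells_transposed.csv` (the same summary with cells as
#' columns, convenient for pasting into graphing software). Numeric values
#' are written as decimal text with 9 significant digits; missing values
#' as empty fields.
#'
#' @param transients Per-transient tibble from [transient_features()].
#' @param cells Per-cell tibble from [summarize_cells()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_features <- function(transients, cells, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    transients = file.path(dir, "transients.csv"),
    cells = file.path(dir, "cells.csv"),
    cells_transposed = file.path(dir, "cells_transposed.csv")
  )
  write_formatted_csv(transients, paths[["transients"]])
  write_formatted_csv(cells, paths[["cells"]])
  tr <- tibble(field = setdiff(names(cells), "cell_id"))
  for (i in seq_len(nrow(cells))) {
    vals <- unlist(lapply(cells[i, tr$field], function(x) {
      if (is.numeric(x)) fmt_num(x) else as.character(x)
    }))
    tr[[cells$cell_id[i]]] <- unname(vals)
  }
  readr::write_csv(tr, paths[["cells_transposed"]], na = "")
  invisible(paths)
}

#' Read a detection edits file
#'
#' Manual point adjustments are supplied as a delimited file with columns
#' `cell_id`, `event`, `which` (`start`, `peak` or `end`) and `new_index`,
#' replacing interactive point dragging; see [adjust_event()].
#'
#' @param path Path to a CSV/TSV edits file.
#' @return A tibble of edits.
#' @export
read_edits <- function(path) {
  delim <- sniff_delim(path)
  ed <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          trim_ws = TRUE)
  need <- c("cell_id", "event", "which", "new_index")
  miss <- setdiff(need, names(ed))
  if (length(miss)) {
    abort(sprintf("Edits file is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  ed
}
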