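#' Construct an intensity table
#'
#' An intensity table holds the raw per-frame mean fluorescence of one or
#' more cell ROIs plus one designated cell-free background ROI, together
#' with the acquisition metadata (recording duration and frame count) that
#' the exported file itself does not carry. It is the common entry point of
#' the pipeline, whether the values come from an ImageJ Multi Measure
#' export ([read_multimeasure()]), from a labelled image stack
#' ([extract_mean_intensities()]), or from the simulator
#' ([simulate_traces()]).
#'
#' @param data Data frame of per-frame intensities, one row per frame, one
#'   numeric column per ROI. An optional `frame` column (1-based contiguous
#'   frame indices) is checked and retained; it is created if absent.
#' @param duration_s Recording duration in seconds (> 0).
#' @param background Name of the background ROI column. Defaults to the
#'   last ROI column, the conventional position of the cell-free region.
#'
#' @return A tibble of class `ca_intensity` with a `frame` column followed
#'   by the ROI columns, and attributes `duration_s`, `frame_count` and
#'   `background`.
#' @export
#' @examples
#' tbl <- intensity_table(
#'   data.frame(Mean1 = c(110, 120, 115), Mean2 = c(100, 100, 100)),
#'   duration_s = 0.3
#' )
#' background_column(tbl)
intensity_table <- function(data, duration_s, background = NULL) {
  data <- as_tibble(data)
  if (!is.numeric(duration_s) || length(duration_s) != 1L || !is.finite(duration_s) ||
      duration_s <= 0) {
    abort("`duration_s` must be a single positive number of seconds.")
  }
  n <- nrow(data)
  if (n < 2L) abort("An intensity table needs at least 2 frames (rows).")
  if ("frame" %in% names(data)) {
    if (!identical(as.integer(data$frame), seq_len(n))) {
      abort("`frame` must be contiguous 1-based frame indices.")
    }
    data$frame <- seq_len(n)
  } else {
    data <- dplyr::bind_cols(tibble(frame = seq_len(n)), data)
  }
  roi_cols <- setdiff(names(data), "frame")
  if (length(roi_cols) < 1L) abort("No ROI columns found.")
  for (nm in roi_cols) {
    x <- data[[nm]]
    if (!is.numeric(x)) abort(sprintf("ROI column '%s' is not numeric.", nm))
    bad <- which(!is.finite(x))
    if (length(bad)) {
      abort(sprintf("ROI column '%s' has a non-finite value at row %d.",
                    nm, bad[1]))
    }
  }
  background <- background %||% roi_cols[length(roi_cols)]
  if (!background %in% roi_cols) {
    abort(sprintf("Background column '%s' is not among the ROI columns (%s).",
                  background, paste(roi_cols, collapse = ", ")))
  }
  structure(
    data,
    duration_s  = as.numeric(duration_s),
    frame_count = n,
    background  = background,
    class = c("ca_intensity", class(data))
  )
}

#' Accessors for intensity-table metadata
#'
#' @param x An intensity table created by [intensity_table()].
#' @return `background_column()` the background ROI column name;
#'   `cell_columns()` the remaining (cell) ROI column names;
#'   `acquisition()` a list with `duration_s` and `frame_count`.
#' @export
background_column <- function(x) {
  stopifnot(inherits(x, "ca_intensity"))
  attr(x, "background")
}

#' @rdname background_column
#' @export
cell_columns <- function(x) {
  stopifnot(inherits(x, "ca_intensity"))
  setdiff(names(x), c("frame", attr(x, "background")))
}

#' @rdname background_column
#' @export
acquisition <- function(x) {
  stopifnot(inherits(x, "ca_intensity"))
  list(duration_s = attr(x, "duration_s"), frame_count = attr(x, "frame_count"))
}

#' @export
print.ca_intensity <- function(x, ...) {
  acq <- acquisition(x)
  cat(sprintf(
    "<ca_intensity> %d frames / %.6g s, %d cell ROI(s), background = '%s'\n",
    acq$frame_count, acq$duration_s, length(cell_columns(x)), background_column(x)
  ))
  NextMethod()
}
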