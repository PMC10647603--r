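#' Convert 1-based frame indices to seconds
#'
#' `t = frame_index * duration_s / frame_count`, the same transformation
#' applied when preparing ImageJ exports for analysis. Frames are 1-based
#' and end-inclusive: frame 156 of a 15 s / 156-frame recording maps to
#' 15 s, frame 1 to one sampling interval.
#'
#' @param frame_index Integer frame index (vector), `1..frame_count`.
#' @param duration_s Recording duration in seconds.
#' @param frame_count Number of frames in the recording.
#' @return Time in seconds.
#' @export
#' @examples
#' frames_to_time(156, 15, 156) # 15
frames_to_time <- function(frame_index, duration_s, frame_count) {
  stopifnot(duration_s > 0, frame_count >= 1)
  if (any(frame_index < 1 | frame_index > frame_count) ||
      any(frame_index != round(frame_index))) {
    abort(sprintf(
      "`frame_index` must be an integer in 1..%d (frames are 1-based).",
      frame_count
    ))
  }
  frame_index * duration_s / frame_count
}

new_ca_traces <- function(df, duration_s, frame_count, smoothing = "none") {
  structure(
    df,
    duration_s = duration_s,
    frame_count = frame_count,
    sampling_interval_s = duration_s / frame_count,
    smoothing = smoothing,
    class = c("ca_traces", class(as_tibble(df)))
  )
}

#' Normalize cell fluorescence to the background ROI
#'
#' Converts each cell's raw intensity to the dimensionless trace
#' `dff = (F_cell - F_background) / F_background`, frame by frame, and
#' attaches the uniform time grid from [frames_to_time()]. This is the
#' background normalization step performed on the ImageJ export before
#' transient analysis; it also cancels any photobleaching trend shared by
#' cell and background. The time grid is constructed here once, so all
#' downstream features are in seconds.
#'
#' @param table A [intensity_table()].
#' @return A long tibble of class `ca_traces` with columns `cell_id`,
#'   `frame`, `time_s`, `dff` (one row per cell per frame), carrying
#'   `duration_s`, `frame_count`, `sampling_interval_s` and `smoothing`
#'   attributes.
#' @export
#' @examples
#' tbl <- intensity_table(
#'   data.frame(Mean1 = c(110, 120), Mean2 = c(100, 100)),
#'   duration_s = 0.2
#' )
#' normalize_to_background(tbl)
normalize_to_background <- function(table) {
  stopifnot(inherits(table, "ca_intensity"))
  acq <- acquisition(table)
  bg <- table[[background_column(table)]]
  bad <- which(bg <= 0)
  if (length(bad)) {
    abort(sprintf(
      "Background intensity is not strictly positive at frame %d; cannot normalize.",
      bad[1]
    ))
  }
  cells <- cell_columns(table)
  if (length(cells) < 1L) abort("No cell ROI columns besides the background.")
  time_s <- frames_to_time(table$frame, acq$duration_s, acq$frame_count)
  long <- purrr::map_dfr(cells, function(nm) {
    tibble(
      cell_id = nm,
      frame = table$frame,
      time_s = time_s,
      dff = (table[[nm]] - bg) / bg
    )
  })
  new_ca_traces(long, acq$duration_s, acq$frame_count)
}

traces_meta <- function(traces) {
  stopifnot(inherits(traces, "ca_traces"))
  list(
    duration_s = attr(traces, "duration_s"),
    frame_count = attr(traces, "frame_count"),
    sampling_interval_s = attr(traces, "sampling_interval_s"),
    smoothing = attr(traces, "smoothing")
  )
}

#' @export
print.ca_traces <- function(x, ...) {
  m <- traces_meta(x)
  cat(sprintf(
    "<ca_traces> %d cell(s), %d frames / %.6g s (dt = %.6g s), smoothing: %s\n",
    dplyr::n_distinct(x$cell_id), m$frame_count, m$duration_s,
    m$sampling_interval_s, m$smoothing
  ))
  NextMethod()
}

fft_lowpass <- function(y, cutoff_hz, dt) {
  n <- length(y)
  # mean-pad to twice the length to soften wrap-around edge ringing
  yp <- c(y, rep(mean(y), n))
  np <- length(yp)
  k <- 0:(np - 1)
  freq <- pmin(k, np - k) / (np * dt)
  yf <- fft(yp)
  yf[freq > cutoff_hz] <- 0
  Re(fft(yf, inverse = TRUE) / np)[seq_len(n)]
}

moving_average <- function(y, window) {
  n <- length(y)
  h <- (window - 1L) / 2L
  # reflection padding at both edges
  yp <- c(rev(y[2:(h + 1)]), y, rev(y[(n - h):(n - 1)]))
  as.numeric(stats::filter(yp, rep(1 / window, window), sides = 2))[(h + 1):(h + n)]
}

#' Smooth normalized traces
#'
#' Optional smoothing for noisy recordings (poor signal during
#' acquisition). Two methods are available: a hard spectral low-pass
#' (`fft_lowpass`, zeroing all components above `cutoff_hz`, with the
#' trace mean-padded to reduce edge ringing) mirroring the FFT filter of
#' interactive analysis software, and a centred `moving_average` with
#' reflection padding at the edges. Smoothing is off by default in the
#' pipeline; apply it deliberately and record it.
#'
#' @param traces A `ca_traces` tibble from [normalize_to_background()].
#' @param method `"fft_lowpass"` or `"moving_average"`.
#' @param cutoff_hz Cutoff frequency in Hz for `fft_lowpass`
#'   (0 < cutoff < Nyquist).
#' @param window Odd window length >= 3 samples for `moving_average`.
#' @return The smoothed `ca_traces`, with its `smoothing` attribute set.
#' @export
smooth_traces <- function(traces, method = c("fft_lowpass", "moving_average"),
                          cutoff_hz = NULL, window = NULL) {
  method <- match.arg(method)
  m <- traces_meta(traces)
  dt <- m$sampling_interval_s
  if (method == "fft_lowpass") {
    nyquist <- 1 / (2 * dt)
    if (is.null(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
      abort(sprintf("`cutoff_hz` must be in (0, %.4g) Hz (Nyquist).", nyquist))
    }
    fun <- function(y) fft_lowpass(y, cutoff_hz, dt)
    desc <- sprintf("fft_lowpass(cutoff_hz=%g)", cutoff_hz)
  } else {
    if (is.null(window) || window < 3 || window %% 2 != 1) {
      abort("`window` must be an odd integer >= 3 samples.")
    }
    fun <- function(y) moving_average(y, as.integer(window))
    desc <- sprintf("moving_average(window=%d)", as.integer(window))
  }
  out <- traces %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::mutate(dff = fun(.data$dff)) %>%
    dplyr::ungroup()
  new_ca_traces(out, m$duration_s, m$frame_count, smoothing = desc)
}
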