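#' Transient detection parameters
#'
#' The three user-tunable parameters of interactive transient analysis,
#' plus a robust noise gate:
#' \describe{
#'   \item{window_size}{Minimum separation between detected peaks, in
#'     samples. Lowering it recognizes more peaks (anticipate this for
#'     high beating rates), raising it fewer.}
#'   \item{tol_peakstart}{Start threshold as a fraction of the transient
#'     amplitude above the pre-peak baseline. Raising it shifts transient
#'     starts later (to the right), lowering it earlier.}
#'   \item{tol_peakend}{Required recovery fraction of the amplitude after
#'     the peak. Raising it shifts transient ends later, lowering it
#'     earlier.}
#'   \item{prominence_k}{Peaks must rise at least `prominence_k` robust
#'     noise standard deviations above their surroundings; the noise
#'     scale is estimated from the median absolute deviation of the
#'     first differences of the trace. Set 0 to disable the gate.}
#' }
#' The tolerance formulas are fractional-amplitude conventions, the
#' simple choice under which both "raise to shift right" behaviours hold;
#' interactive implementations may differ numerically.
#'
#' @param window_size Samples, >= 1 (default 10).
#' @param tol_peakstart Fraction in \[0, 0.5\] (default 0.05).
#' @param tol_peakend Fraction in (0.5, 1\] (default 0.90).
#' @param prominence_k Noise multiplier >= 0 (default 4).
#' @return A list of class `ca_detection_params`.
#' @export
detection_params <- function(window_size = 10, tol_peakstart = 0.05,
                             tol_peakend = 0.90, prominence_k = 4) {
  if (window_size < 1 || window_size != round(window_size)) {
    abort("`window_size` must be an integer >= 1 (samples).")
  }
  if (tol_peakstart < 0 || tol_peakstart > 0.5) {
    abort("`tol_peakstart` must lie in [0, 0.5].")
  }
  if (tol_peakend <= 0.5 || tol_peakend > 1) {
    abort("`tol_peakend` must lie in (0.5, 1].")
  }
  if (prominence_k < 0) abort("`prominence_k` must be >= 0.")
  structure(
    list(window_size = as.integer(window_size),
         tol_peakstart = tol_peakstart,
         tol_peakend = tol_peakend,
         prominence_k = prominence_k),
    class = "ca_detection_params"
  )
}

#' @export
print.ca_detection_params <- function(x, ...) {
  cat(sprintf(
    "<ca_detection_params> window_size=%d tol_peakstart=%g tol_peakend=%g prominence_k=%g\n",
    x$window_size, x$tol_peakstart, x$tol_peakend, x$prominence_k
  ))
  invisible(x)
}

# Robust noise scale from first differences; for white noise of s.d. s the
# differences have s.d. s*sqrt(2), and MAD/0.6745 estimates an s.d.
noise_sigma_est <- function(dff) {
  mad(diff(dff), constant = 1) / (sqrt(2) * 0.6745)
}

peak_prominence <- function(dff, p) {
  n <- length(dff)
  higher_l <- which(dff[seq_len(p - 1)] > dff[p])
  lmin <- if (length(higher_l)) min(dff[(max(higher_l)):p]) else min(dff[1:p])
  right <- if (p < n) (p + 1):n else integer(0)
  higher_r <- right[dff[right] > dff[p]]
  rmin <- if (length(higher_r)) min(dff[p:min(higher_r)]) else min(dff[p:n])
  dff[p] - max(lmin, rmin)
}

#' Detect transient peaks in a normalized trace
#'
#' A sample is a peak when it strictly dominates every earlier sample and
#' weakly dominates every later sample within `window_size` samples (so
#' detected peaks are at least `window_size` samples apart, plateau ties
#' resolve to the earliest index, and trace endpoints are never peaks),
#' and when its topographic prominence exceeds `prominence_k` times the
#' robust noise scale of the trace. Raising `window_size` or
#' `prominence_k` can only reduce the number of detected peaks.
#'
#' @param dff Numeric vector, one cell's normalized trace (>= 3 samples).
#' @param params A [detection_params()] list.
#' @return Sorted integer vector of peak sample indices (possibly empty).
#' @export
#' @examples
#' detect_peaks(c(0, 0, 1, 0, 0, 2, 0), detection_params(window_size = 2,
#'                                                       prominence_k = 0))
detect_peaks <- function(dff, params = detection_params()) {
  if (length(dff) < 3L) abort("Trace must have at least 3 samples.")
  n <- length(dff)
  w <- params$window_size
  sigma <- noise_sigma_est(dff)
  gate <- params$prominence_k * sigma
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    lo <- max(1L, i - w + 1L)
    hi <- min(n, i + w - 1L)
    if (i > lo && any(dff[lo:(i - 1)] >= dff[i])) next
    if (hi > i && any(dff[(i + 1):hi] > dff[i])) next
    prom <- peak_prominence(dff, i)
    if (prom <= 0 || prom < gate) next
    peaks <- c(peaks, i)
  }
  peaks
}

#' Locate the start and end of each transient
#'
#' For each peak the pre-peak baseline is the minimum of the trace since
#' the previous peak (or the trace start), and the amplitude estimate is
#' peak minus that baseline. The transient start is the last sample
#' before the peak at or below `baseline + tol_peakstart * amplitude`;
#' the end is the first sample after the peak that has recovered at least
#' `tol_peakend * amplitude` from the peak, searching no further than the
#' next transient's start so transients never overlap. An event whose
#' recovery threshold is never reached (typically the final transient of
#' the recording) is marked `complete = FALSE`; incomplete events stay in
#' per-transient output but are excluded from per-cell averages.
#'
#' @param dff Numeric trace vector.
#' @param peaks Strictly increasing peak indices from [detect_peaks()].
#' @param params A [detection_params()] list.
#' @return Tibble with one row per peak: `event`, `start_idx`, `peak_idx`,
#'   `end_idx` (`NA` when no post-peak sample exists), `baseline` (trace
#'   value at the start), `complete`, `manually_adjusted`.
#' @export
locate_bounds <- function(dff, peaks, params = detection_params()) {
  n <- length(dff)
  if (length(peaks) == 0L) {
    return(tibble(
      event = integer(0), start_idx = integer(0), peak_idx = integer(0),
      end_idx = integer(0), baseline = numeric(0), complete = logical(0),
      manually_adjusted = logical(0)
    ))
  }
  if (any(diff(peaks) <= 0)) abort("`peaks` must be strictly increasing.")
  if (min(peaks) < 1 || max(peaks) > n) abort("`peaks` out of trace range.")
  k <- length(peaks)
  starts <- integer(k)
  amps <- numeric(k)
  for (i in seq_len(k)) {
    p <- peaks[i]
    seg_lo <- if (i == 1L) 1L else peaks[i - 1L] + 1L
    pre_base <- min(dff[seg_lo:p])
    amps[i] <- dff[p] - pre_base
    thresh <- pre_base + params$tol_peakstart * amps[i]
    if (p - 1L >= seg_lo) {
      idx <- (seg_lo:(p - 1L))[dff[seg_lo:(p - 1L)] <= thresh]
      starts[i] <- if (length(idx)) max(idx) else
        (seg_lo:(p - 1L))[which.min(dff[seg_lo:(p - 1L)])]
    } else {
      starts[i] <- max(1L, p - 1L)
    }
  }
  ends <- rep(NA_integer_, k)
  complete <- logical(k)
  for (i in seq_len(k)) {
    p <- peaks[i]
    limit <- if (i < k) starts[i + 1L] else n
    if (limit > p) {
      j <- (p + 1L):limit
      hit <- j[dff[p] - dff[j] >= params$tol_peakend * amps[i]]
      if (length(hit)) {
        ends[i] <- hit[1L]
        complete[i] <- TRUE
      } else {
        ends[i] <- limit
      }
    }
  }
  tibble(
    event = seq_len(k), start_idx = starts, peak_idx = as.integer(peaks),
    end_idx = ends, baseline = dff[starts], complete = complete,
    manually_adjusted = FALSE
  )
}

#' Detect transients in every cell of a trace set
#'
#' Runs [detect_peaks()] then [locate_bounds()] per cell.
#'
#' @param traces A `ca_traces` tibble from [normalize_to_background()].
#' @param params A [detection_params()] list.
#' @return Tibble with one row per detected transient: `cell_id` plus the
#'   columns of [locate_bounds()].
#' @export
#' @examples
#' sim <- simulate_traces(seed = 1)
#' traces <- normalize_to_background(sim$table)
#' detect_transients(traces)
detect_transients <- function(traces, params = detection_params()) {
  stopifnot(inherits(traces, "ca_traces"))
  traces %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::group_modify(function(df, key) {
      locate_bounds(df$dff, detect_peaks(df$dff, params), params)
    }) %>%
    dplyr::ungroup()
}

#' Manually adjust a detected transient point
#'
#' Scriptable replacement for interactive point dragging: moves the
#' start, peak or end of one event to a new sample index, preserving the
#' `start < peak < end` ordering (an illegal move errors and leaves the
#' events unchanged). The baseline is recomputed from the trace when the
#' start moves, and an adjusted end marks the event complete. Downstream
#' feature computation uses the adjusted coordinates as-is; detection is
#' not re-run (re-running it would reset the points).
#'
#' @param events Events tibble from [detect_transients()].
#' @param traces The `ca_traces` the events were detected on.
#' @param cell_id,event Identify the event to adjust.
#' @param which One of `"start"`, `"peak"`, `"end"`.
#' @param new_index New sample index within the trace.
#' @return The events tibble with the adjustment applied and
#'   `manually_adjusted = TRUE` for that event.
#' @export
adjust_event <- function(events, traces, cell_id, event,
                         which = c("start", "peak", "end"), new_index) {
  which <- match.arg(which)
  row <- which(events$cell_id == cell_id & events$event == event)
  if (length(row) != 1L) {
    abort(sprintf("No unique event %s/%s in `events`.", cell_id, event))
  }
  tr <- traces[traces$cell_id == cell_id, ]
  if (nrow(tr) == 0L) abort(sprintf("No trace for cell '%s'.", cell_id))
  new_index <- as.integer(new_index)
  if (new_index < 1L || new_index > nrow(tr)) {
    abort(sprintf("`new_index` must be in 1..%d.", nrow(tr)))
  }
  st <- events$start_idx[row]; pk <- events$peak_idx[row]; en <- events$end_idx[row]
  if (which == "start") st <- new_index
  if (which == "peak") pk <- new_index
  if (which == "end") en <- new_index
  if (!is.na(st) && !is.na(pk) && st >= pk) {
    abort(sprintf(
      "Illegal move: start (%d) must come before peak (%d); events unchanged.",
      st, pk
    ))
  }
  if (!is.na(en) && !is.na(pk) && en <= pk) {
    abort(sprintf(
      "Illegal move: end (%d) must come after peak (%d); events unchanged.",
      en, pk
    ))
  }
  events$start_idx[row] <- st
  events$peak_idx[row] <- pk
  events$end_idx[row] <- en
  if (which == "start") events$baseline[row] <- tr$dff[st]
  if (which == "end") events$complete[row] <- TRUE
  events$manually_adjusted[row] <- TRUE
  events
}

#' Apply a table of manual edits
#'
#' @param events Events tibble from [detect_transients()].
#' @param traces The corresponding `ca_traces`.
#' @param edits Tibble (or path readable by [read_edits()]) with columns
#'   `cell_id`, `event`, `which`, `new_index`, applied in order.
#' @return The adjusted events tibble.
#' @export
apply_edits <- function(events, traces, edits) {
  if (is.character(edits)) edits <- read_edits(edits)
  for (i in seq_len(nrow(edits))) {
    events <- adjust_event(events, traces, edits$cell_id[i], edits$event[i],
                           edits$which[i], edits$new_index[i])
  }
  events
}
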