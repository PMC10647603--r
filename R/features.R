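#' Names of the eleven per-cell transient features
#'
#' The per-cell summary carries exactly these features: average peak
#' height (transient amplitude), time to peak, transient duration,
#' average peak area (area under the curve), time to 50% baseline, time
#' to 90% baseline, upstroke velocity, decay tau, time between maxima,
#' inter-event interval, and transient frequency (beat rate).
#'
#' @return Character vector of length 11.
#' @export
ca_feature_names <- function() {
  c("amplitude", "time_to_peak_s", "duration_s", "auc", "t50_s", "t90_s",
    "upstroke_velocity", "decay_tau_s", "time_between_max_s",
    "inter_event_interval_s", "frequency_hz")
}

# Interpolated time (after the peak) at which the trace first recovers to
# `level`; NA when the level is never reached before `end`.
recovery_time <- function(time_s, dff, peak_idx, end_idx, level) {
  idx <- peak_idx:end_idx
  below <- idx[dff[idx] <= level]
  if (!length(below)) return(NA_real_)
  j <- below[1L]
  if (j == peak_idx) return(0)
  t_cross <- time_s[j - 1L] +
    (dff[j - 1L] - level) / (dff[j - 1L] - dff[j]) * (time_s[j] - time_s[j - 1L])
  t_cross - time_s[peak_idx]
}

#' Fit a mono-exponential decay time constant
#'
#' Nonlinear least squares of `y(t) = A * exp(-(t - t_peak)/tau) + C` to
#' the samples between the peak and the transient end (minpack.lm
#' Levenberg-Marquardt, constrained to `A > 0`, `tau > 0`). Initialized
#' at `A = y[peak] - baseline`, `C = baseline` and
#' `tau = t50 / ln 2` (falling back to a third of the fit span when the
#' half-recovery time is unavailable). When enough samples remain, the
#' peak sample itself is excluded: a sampled maximum can land just before
#' the true vertex on the rising limb, which would flatten the start of
#' the decay and inflate tau. Returns `NA` (never an error) when fewer
#' than 4 samples are available, the fit does not converge, the fitted
#' amplitude collapses to zero (flat tail), or the fitted tau is at least
#' as long as the fitted window — a curve that decays that slowly looks
#' linear over the window, so its time constant is not identifiable from
#' it. A failed fit simply leaves the feature missing.
#'
#' @param time_s,dff The cell's time grid and normalized trace.
#' @param peak_idx,end_idx Sample indices delimiting the decay limb.
#' @param baseline Transient baseline (trace value at its start).
#' @param t50_s Optional half-recovery time used to initialize tau.
#' @return Fitted tau in seconds, or `NA_real_`.
#' @export
#' @examples
#' t <- seq(0, 1.5, by = 0.096)
#' fit_decay_tau(t, exp(-t / 0.4), 1, length(t), baseline = 0)
fit_decay_tau <- function(time_s, dff, peak_idx, end_idx, baseline = 0,
                          t50_s = NA_real_) {
  if (is.na(end_idx) || end_idx - peak_idx + 1L < 4L) return(NA_real_)
  # Skip the peak sample itself when enough samples remain: the sampled
  # maximum can sit just before the true vertex (on the rising limb),
  # which would flatten the start of the decay and inflate tau.
  from <- if (end_idx - peak_idx >= 4L) peak_idx + 1L else peak_idx
  idx <- from:end_idx
  tt <- time_s[idx] - time_s[peak_idx]
  yy <- dff[idx]
  a0 <- max(yy[1L] - baseline, 1e-9)
  tau0 <- if (is.finite(t50_s) && t50_s > 0) t50_s / log(2) else
    max(tt[length(tt)] / 3, 1e-6)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ A * exp(-tt / tau) + C,
      start = list(A = a0, C = baseline, tau = tau0),
      lower = c(A = 1e-12, C = -Inf, tau = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(NA_real_)
  cf <- stats::coef(fit)
  tau <- unname(cf[["tau"]])
  # A time constant as long as the fitted window (the curve would look
  # linear over it) is not identifiable from that window, and an amplitude
  # stuck at its lower bound means there is no decay to fit: both are
  # failed fits, reported as missing.
  span <- tt[length(tt)] - tt[1L]
  if (!is.finite(tau) || tau <= 0 || tau >= span || cf[["A"]] <= 1e-10) {
    return(NA_real_)
  }
  tau
}

compute_one_transient <- function(time_s, dff, start_idx, peak_idx, end_idx,
                                  baseline, tau_fit_end = end_idx) {
  dt <- time_s[2L] - time_s[1L]
  amp <- dff[peak_idx] - baseline
  seg <- start_idx:end_idx
  excess <- pmax(dff[seg] - baseline, 0)
  t50 <- recovery_time(time_s, dff, peak_idx, end_idx, baseline + 0.5 * amp)
  t90 <- recovery_time(time_s, dff, peak_idx, end_idx, baseline + 0.1 * amp)
  rise <- start_idx:peak_idx
  tibble(
    amplitude = amp,
    time_to_peak_s = time_s[peak_idx] - time_s[start_idx],
    duration_s = time_s[end_idx] - time_s[start_idx],
    auc = pracma::trapz(time_s[seg], excess),
    t50_s = t50,
    t90_s = t90,
    upstroke_velocity = max(diff(dff[rise])) / dt,
    mean_upstroke_velocity = amp / (time_s[peak_idx] - time_s[start_idx]),
    decay_tau_s = fit_decay_tau(time_s, dff, peak_idx, tau_fit_end, baseline, t50)
  )
}

#' Per-transient features
#'
#' Computes, for every complete detected transient, the baseline-relative
#' features: amplitude (`dff` at the peak minus the baseline), time to
#' peak and duration (start-to-peak and start-to-end in seconds), area
#' under the curve (trapezoidal integral of the baseline-subtracted trace
#' over the event, negative excursions clipped to zero), the times from
#' the peak to 50% and to 90% recovery of the amplitude toward baseline
#' (linearly interpolated between samples; `NA` with a flag when the
#' trace never reaches the level before the event end), the upstroke
#' velocity (maximum discrete derivative on the rising limb; the mean
#' rise rate amplitude/time-to-peak is also reported as
#' `mean_upstroke_velocity` but does not enter the per-cell summary), and
#' the mono-exponential decay tau ([fit_decay_tau()]). The recovery times
#' are measured from the peak because they describe the decaying limb of
#' the transient. Incomplete events are retained with missing features.
#'
#' @param traces A `ca_traces` tibble.
#' @param events Events tibble from [detect_transients()] (possibly
#'   manually adjusted).
#' @return Tibble with one row per event: identifiers, start/peak/end
#'   times, `complete`, `manually_adjusted`, and the feature columns.
#' @export
#' @examples
#' sim <- simulate_traces(seed = 1)
#' traces <- normalize_to_background(sim$table)
#' transient_features(traces, detect_transients(traces))
transient_features <- function(traces, events) {
  stopifnot(inherits(traces, "ca_traces"))
  split_tr <- split(traces, traces$cell_id)
  # The decay-tau fit uses the whole decaying limb available to the event:
  # from its peak up to the sample before the next transient starts (trace
  # end for the last event), which is better conditioned than stopping at
  # the recovery threshold.
  events <- events %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::mutate(
      tau_fit_end = dplyr::coalesce(
        dplyr::lead(.data$start_idx) - 1L,
        vapply(.data$cell_id, function(cid) nrow(split_tr[[cid]]), 1L)
      )
    ) %>%
    dplyr::ungroup()
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    tr <- split_tr[[ev$cell_id]]
    base <- tibble(
      cell_id = ev$cell_id, event = ev$event,
      start_time_s = tr$time_s[ev$start_idx],
      peak_time_s = tr$time_s[ev$peak_idx],
      end_time_s = if (is.na(ev$end_idx)) NA_real_ else tr$time_s[ev$end_idx],
      complete = ev$complete, manually_adjusted = ev$manually_adjusted
    )
    if (!ev$complete) return(base)
    dplyr::bind_cols(base, compute_one_transient(
      tr$time_s, tr$dff, ev$start_idx, ev$peak_idx, ev$end_idx, ev$baseline,
      tau_fit_end = max(ev$tau_fit_end, ev$end_idx)
    ))
  }) %>%
    (function(df) {
      # events with no feature columns (all incomplete) still need them
      feat <- c("amplitude", "time_to_peak_s", "duration_s", "auc", "t50_s",
                "t90_s", "upstroke_velocity", "mean_upstroke_velocity",
                "decay_tau_s")
      for (nm in setdiff(feat, names(df))) df[[nm]] <- NA_real_
      df
    })
}

#' Average transient features to one value per cell
#'
#' Complete transients only: each per-transient feature is averaged
#' arithmetically (missing decay-tau or recovery-time values are dropped
#' pairwise from their own mean); the time between maxima is the mean
#' successive peak-to-peak interval and the inter-event interval the mean
#' end-to-next-start gap (floored at zero) — the two are distinct
#' features, not synonyms. Transient frequency is the number of complete
#' transients divided by the full recording duration, which stays defined
#' for single-event cells. Both interval features require at least two
#' complete transients and are missing otherwise. A cell with no complete
#' transient yields `n_transients = 0` with every feature missing.
#'
#' @param transients Per-transient tibble from [transient_features()].
#' @param duration_s Recording duration in seconds.
#' @param cell_ids Optional full roster of cells; cells with no detected
#'   transient then still get a summary row (`n_transients = 0`, features
#'   missing).
#' @return Tibble with one row per cell: `cell_id`, `n_transients`, the
#'   eleven features of [ca_feature_names()], and QC counts
#'   `n_incomplete` and `n_tau_missing`.
#' @export
summarize_cells <- function(transients, duration_s, cell_ids = NULL) {
  stopifnot(is.numeric(duration_s), duration_s > 0)
  mean_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  if (!is.null(cell_ids)) {
    missing_cells <- setdiff(cell_ids, transients$cell_id)
    if (length(missing_cells)) {
      transients <- dplyr::bind_rows(
        transients,
        tibble(cell_id = missing_cells, event = NA_integer_, complete = FALSE)
      )
    }
  }
  transients %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::group_modify(function(df, key) {
      comp <- df[df$complete, ]
      n <- nrow(comp)
      out <- tibble(
        n_transients = n,
        amplitude = NA_real_, time_to_peak_s = NA_real_,
        duration_s = NA_real_, auc = NA_real_, t50_s = NA_real_,
        t90_s = NA_real_, upstroke_velocity = NA_real_,
        decay_tau_s = NA_real_, time_between_max_s = NA_real_,
        inter_event_interval_s = NA_real_, frequency_hz = NA_real_,
        n_incomplete = sum(!df$complete & !is.na(df$event)),
        n_tau_missing = sum(df$complete & is.na(df$decay_tau_s))
      )
      if (n == 0L) return(out)
      out$amplitude <- mean(comp$amplitude)
      out$time_to_peak_s <- mean(comp$time_to_peak_s)
      out$duration_s <- mean(comp$duration_s)
      out$auc <- mean(comp$auc)
      out$t50_s <- mean_na(comp$t50_s)
      out$t90_s <- mean_na(comp$t90_s)
      out$upstroke_velocity <- mean(comp$upstroke_velocity)
      out$decay_tau_s <- mean_na(comp$decay_tau_s)
      if (n >= 2L) {
        out$time_between_max_s <- mean(diff(comp$peak_time_s))
        gaps <- comp$start_time_s[-1L] - comp$end_time_s[-n]
        out$inter_event_interval_s <- mean(pmax(gaps, 0))
      }
      out$frequency_hz <- n / duration_s
      out
    }) %>%
    dplyr::ungroup()
}

#' Detect and summarize in one call
#'
#' Convenience wrapper: [detect_transients()], optional [apply_edits()],
#' [transient_features()], [summarize_cells()].
#'
#' @param traces A `ca_traces` tibble.
#' @param params A [detection_params()] list.
#' @param edits Optional edits tibble or file path.
#' @return List with `events`, `transients` and `cells` tibbles.
#' @export
analyze_traces <- function(traces, params = detection_params(), edits = NULL) {
  events <- detect_transients(traces, params)
  if (!is.null(edits)) events <- apply_edits(events, traces, edits)
  transients <- transient_features(traces, events)
  cells <- summarize_cells(transients, traces_meta(traces)$duration_s,
                           cell_ids = unique(traces$cell_id))
  list(events = events, transients = transients, cells = cells)
}
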