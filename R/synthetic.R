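#' Unit calcium-transient waveform
#'
#' Piecewise waveform of one transient: linear rise from 0 to 1 over
#' `rise_time_s`, then mono-exponential decay with time constant
#' `decay_tau_s`; zero before the event. The decay time constant of this
#' shape is exactly the quantity the feature extractor must recover.
#'
#' @param s Time since event onset, seconds (vector).
#' @param rise_time_s Rise time, seconds (> 0).
#' @param decay_tau_s Decay time constant, seconds (> 0).
#' @return Dimensionless waveform values in \[0, 1\].
#' @export
transient_waveform <- function(s, rise_time_s, decay_tau_s) {
  out <- numeric(length(s))
  r <- s >= 0 & s < rise_time_s
  d <- s >= rise_time_s
  out[r] <- s[r] / rise_time_s
  out[d] <- exp(-(s[d] - rise_time_s) / decay_tau_s)
  out
}

resolve_event_times <- function(duration_s, event_times_s, rate_hz, rise_time_s) {
  if (!is.null(event_times_s) && !is.null(rate_hz)) {
    abort("Give either `event_times_s` or `rate_hz`, not both.")
  }
  if (is.null(event_times_s)) {
    rate_hz <- rate_hz %||% 1
    if (rate_hz <= 0) abort("`rate_hz` must be positive.")
    event_times_s <- (seq_len(floor(duration_s * rate_hz)) - 0.5) / rate_hz
  }
  event_times_s <- as.numeric(event_times_s)
  if (length(event_times_s) == 0L) return(event_times_s)
  if (any(diff(event_times_s) <= 0)) {
    abort("`event_times_s` must be strictly increasing.")
  }
  if (any(event_times_s < 0 | event_times_s >= duration_s)) {
    abort("All event times must lie within [0, duration_s).")
  }
  if (length(event_times_s) > 1L && min(diff(event_times_s)) < rise_time_s) {
    warn("Event spacing shorter than the rise time: transients overlap on the rising limb.")
  }
  event_times_s
}

#' Simulate intensity tables with known ground truth
#'
#' Generates per-frame mean-intensity tables that emulate what ImageJ
#' Multi Measure exports from a recording of spontaneously beating
#' cardiomyocytes: one column per cell plus a cell-free background column.
#' Each cell's fluorescence is
#' `F(t) = baseline_f0 * (1 + sum_k a_k * g(t - t_k)) * bleach(t) + noise`,
#' where `g` is [transient_waveform()] (linear rise, mono-exponential
#' decay), `bleach(t)` falls linearly from 1 to `1 - bleach_fraction` over
#' the recording, and the noise is i.i.d. Gaussian with standard deviation
#' `noise_sigma` (fluorescence units). The background column is
#' `background_b0 * bleach(t) + noise`. Frames are sampled at
#' `t_j = j * duration_s / frame_count` for `j = 1..frame_count` (1-based,
#' end-inclusive, so the last frame of a 15 s / 156-frame recording maps
#' to 15 s).
#'
#' Gaussian rather than Poisson noise is used because a ROI mean averages
#' many pixels, so photon shot noise at the ROI level is effectively
#' normal. Ground truth (per cell and per event: onset time, amplitude in
#' trace units, rise time, decay tau) is returned alongside the table and
#' is never regenerated from the seed downstream.
#'
#' @param n_cells Number of cell ROIs (>= 1).
#' @param duration_s,frame_count Recording length in seconds and number of
#'   frames (defaults: 15 s, 156 frames).
#' @param baseline_f0,background_b0 Resting cell and background
#'   fluorescence, arbitrary units (> 0). With the defaults (equal), the
#'   background-normalized trace amplitude equals `amplitude_dff` exactly;
#'   in general it is scaled by `baseline_f0 / background_b0`.
#' @param amplitude_dff Event amplitude as a fraction of baseline (>= 0).
#' @param rise_time_s,decay_tau_s Waveform kinetics, seconds (> 0).
#' @param event_times_s Strictly increasing event onset times in
#'   `[0, duration_s)`, or `NULL` to derive them from `rate_hz`.
#' @param rate_hz Beating rate; events are placed at `(k - 0.5) / rate_hz`.
#'   Mutually exclusive with `event_times_s`. Default 1 Hz if neither given.
#' @param noise_sigma Gaussian noise s.d., fluorescence units (>= 0).
#' @param bleach_fraction Linear intensity loss over the recording,
#'   in `[0, 1)`.
#' @param cell_cv Lognormal cell-to-cell coefficient of variation applied
#'   multiplicatively to amplitude and decay tau (0 = identical cells).
#' @param seed Integer seed; the generator restores the caller's RNG state.
#' @return A list of class `ca_simulation`: `table` (a [intensity_table()]
#'   with columns `Cell1..CellN` and `Background`), `truth` (tibble with
#'   one row per cell per event: `cell_id`, `event`, `time_s`,
#'   `amplitude_dff` (model amplitude in trace units),
#'   `sampled_amplitude_dff` (the amplitude as realized on the discrete
#'   sampling grid — the peak of a sharp transient falls between frames,
#'   so this is what a perfect analyzer of the recording can recover),
#'   `rise_time_s`, `decay_tau_s`, `peak_time_s`, and `recovery_complete`
#'   — whether, in closed form on the noiseless model, the event recovers
#'   90% of its amplitude above its own pre-onset baseline before the next
#'   event begins and before the recording ends), and `params`.
#' @export
#' @examples
#' sim <- simulate_traces(n_cells = 2, noise_sigma = 1, seed = 7)
#' sim$table
#' head(sim$truth)
simulate_traces <- function(n_cells = 1,
                            duration_s = 15,
                            frame_count = 156,
                            baseline_f0 = 100,
                            background_b0 = 100,
                            amplitude_dff = 1,
                            rise_time_s = 0.1,
                            decay_tau_s = 0.4,
                            event_times_s = NULL,
                            rate_hz = NULL,
                            noise_sigma = 0,
                            bleach_fraction = 0,
                            cell_cv = 0,
                            seed = NULL) {
  stopifnot(n_cells >= 1, duration_s > 0, frame_count >= 2,
            baseline_f0 > 0, background_b0 > 0, amplitude_dff >= 0,
            rise_time_s > 0, decay_tau_s > 0, noise_sigma >= 0,
            bleach_fraction >= 0, bleach_fraction < 1, cell_cv >= 0)
  events <- resolve_event_times(duration_s, event_times_s, rate_hz, rise_time_s)

  run <- function() {
    t_j <- seq_len(frame_count) * duration_s / frame_count
    bleach <- 1 - bleach_fraction * t_j / duration_s
    cols <- vector("list", n_cells)
    truth <- vector("list", n_cells)
    for (c_i in seq_len(n_cells)) {
      jit_a <- if (cell_cv > 0) rlnorm(1, -cell_cv^2 / 2, cell_cv) else 1
      jit_t <- if (cell_cv > 0) rlnorm(1, -cell_cv^2 / 2, cell_cv) else 1
      amp <- amplitude_dff * jit_a
      tau <- decay_tau_s * jit_t
      x <- numeric(frame_count)
      for (tk in events) {
        x <- x + amp * transient_waveform(t_j - tk, rise_time_s, tau)
      }
      f <- baseline_f0 * (1 + x) * bleach
      if (noise_sigma > 0) f <- f + rnorm(frame_count, 0, noise_sigma)
      cols[[c_i]] <- f
      # amplitude as realized on the sampling grid: for each event, the
      # maximum of the noiseless sampled trace in its window minus the
      # pre-onset minimum (what a perfect analyzer of this recording sees)
      scale <- baseline_f0 / background_b0
      samp_amp <- vapply(seq_along(events), function(k) {
        win <- t_j > events[k] &
          t_j <= (if (k < length(events)) events[k + 1] else duration_s)
        pre <- t_j <= events[k] &
          t_j > (if (k > 1) events[k - 1] else 0)
        if (!any(win)) return(NA_real_)
        pre_min <- if (any(pre)) min(x[pre]) else 0
        (max(x[win]) - pre_min) * scale
      }, 1.0)
      # Closed-form completeness: an event is recoverable when, relative to
      # its own pre-onset residue baseline r_k, the summed-exponential tail
      # from its peak p_k falls by 90% of (p_k - r_k) before the next event
      # begins (and before the recording ends). Sustained rhythms leave a
      # residue that elevates later baselines, so the first transient of a
      # train can be unrecoverable even mid-recording.
      ne <- length(events)
      r_k <- vapply(seq_len(ne), function(k) {
        if (k == 1L) return(0)
        j <- seq_len(k - 1L)
        sum(amp * exp(-pmax(events[k] - events[j] - rise_time_s, 0) / tau))
      }, 1.0)
      p_k <- vapply(seq_len(ne), function(k) {
        j <- seq_len(k - 1L)
        amp + (if (k == 1L) 0 else sum(amp * exp(-(events[k] - events[j]) / tau)))
      }, 1.0)
      s_avail <- pmin(c(events[-1L], Inf), duration_s) - (events + rise_time_s)
      drop_frac <- 0.9 * (p_k - r_k) / p_k
      s_req <- ifelse(drop_frac >= 1 | drop_frac <= 0, Inf,
                      tau * -log(1 - drop_frac))
      recoverable <- s_req <= s_avail
      truth[[c_i]] <- tibble(
        cell_id = paste0("Cell", c_i),
        event = seq_along(events),
        time_s = events,
        amplitude_dff = amp * baseline_f0 / background_b0,
        sampled_amplitude_dff = samp_amp,
        rise_time_s = rise_time_s,
        decay_tau_s = tau,
        peak_time_s = events + rise_time_s,
        recovery_complete = recoverable
      )
    }
    bg <- background_b0 * bleach
    if (noise_sigma > 0) bg <- bg + rnorm(frame_count, 0, noise_sigma)
    df <- setNames(
      c(cols, list(bg)),
      c(paste0("Cell", seq_len(n_cells)), "Background")
    )
    list(
      table = intensity_table(as_tibble(df), duration_s = duration_s,
                              background = "Background"),
      truth = dplyr::bind_rows(truth)
    )
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out$params <- list(
    n_cells = n_cells, duration_s = duration_s, frame_count = frame_count,
    baseline_f0 = baseline_f0, background_b0 = background_b0,
    amplitude_dff = amplitude_dff, rise_time_s = rise_time_s,
    decay_tau_s = decay_tau_s, event_times_s = events,
    noise_sigma = noise_sigma, bleach_fraction = bleach_fraction,
    cell_cv = cell_cv, seed = seed
  )
  class(out) <- "ca_simulation"
  out
}

#' @export
print.ca_simulation <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<ca_simulation> %d cell(s), %d events/cell, %.6g s / %d frames, noise %.3g\n",
    p$n_cells, length(p$event_times_s), p$duration_s, p$frame_count, p$noise_sigma
  ))
  invisible(x)
}

#' Render a simulated recording as an image stack with a label mask
#'
#' Builds a T x Y x X image stack in which each cell is a disjoint disc of
#' pixels whose per-frame value equals that cell's simulated ROI mean, and
#' every remaining pixel carries the background trace. The accompanying
#' Y x X integer label mask assigns 1..n_cells to the cell discs and a
#' reserved label (`n_cells + 1` by default) to the background, so
#' [extract_mean_intensities()] on the pair reproduces the simulated
#' intensity table exactly when `pixel_noise_sigma = 0`.
#'
#' @inheritParams simulate_traces
#' @param image_shape Integer `c(Y, X)` pixel dimensions.
#' @param cell_radius Disc radius in pixels.
#' @param pixel_noise_sigma Optional extra i.i.d. Gaussian noise per pixel
#'   (on top of the ROI-level noise already in the traces).
#' @param background_label Integer label reserved for the background
#'   region; defaults to `n_cells + 1`.
#' @param ... Passed to [simulate_traces()].
#' @return A list of class `ca_simulation_stack`: `stack` (T x Y x X
#'   array), `mask` (Y x X integer matrix), `background_label`, plus the
#'   `table`, `truth` and `params` of the underlying simulation.
#' @export
#' @examples
#' st <- simulate_stack(n_cells = 2, image_shape = c(32, 32), cell_radius = 4)
#' dim(st$stack)
#' table(st$mask)
simulate_stack <- function(n_cells = 4,
                           image_shape = c(64, 64),
                           cell_radius = 5,
                           pixel_noise_sigma = 0,
                           background_label = NULL,
                           seed = NULL,
                           ...) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 4),
            cell_radius >= 1, pixel_noise_sigma >= 0)
  sim <- simulate_traces(n_cells = n_cells, seed = seed, ...)
  ny <- image_shape[1]; nx <- image_shape[2]
  g <- ceiling(sqrt(n_cells))
  pitch_y <- ny / g; pitch_x <- nx / g
  if (2 * cell_radius + 1 > min(pitch_y, pitch_x)) {
    abort(sprintf(
      "Cannot place %d disjoint cells of radius %d in a %dx%d image.",
      n_cells, cell_radius, ny, nx
    ))
  }
  background_label <- as.integer(background_label %||% (n_cells + 1L))
  if (background_label %in% seq_len(n_cells)) {
    abort("`background_label` collides with a cell label.")
  }
  mask <- matrix(background_label, ny, nx)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  for (c_i in seq_len(n_cells)) {
    gy <- (c_i - 1L) %/% g; gx <- (c_i - 1L) %% g
    cy <- round((gy + 0.5) * pitch_y); cx <- round((gx + 0.5) * pitch_x)
    disc <- (yy - cy)^2 + (xx - cx)^2 <= cell_radius^2
    mask[disc] <- c_i
  }
  tbl <- sim$table
  nt <- attr(tbl, "frame_count")
  stack <- array(0, dim = c(nt, ny, nx))
  flat_mask <- as.vector(mask)
  bg_vals <- tbl[["Background"]]
  fill <- function() {
    for (t_i in seq_len(nt)) {
      fr <- rep(bg_vals[t_i], ny * nx)
      for (c_i in seq_len(n_cells)) {
        fr[flat_mask == c_i] <- tbl[[paste0("Cell", c_i)]][t_i]
      }
      if (pixel_noise_sigma > 0) fr <- fr + rnorm(ny * nx, 0, pixel_noise_sigma)
      stack[t_i, , ] <<- matrix(fr, ny, nx)
    }
  }
  if (pixel_noise_sigma > 0 && !is.null(seed)) {
    withr::with_seed(seed + 1L, fill())
  } else {
    fill()
  }
  out <- list(stack = stack, mask = mask, background_label = background_label,
              table = sim$table, truth = sim$truth, params = sim$params)
  class(out) <- "ca_simulation_stack"
  out
}

#' Write and read simulated image stacks and label masks as TIFF
#'
#' Stacks are stored as multi-page 32-bit float TIFF with intensities
#' divided by `scale` (TIFF float storage is defined on \[0, 1\]); masks as
#' single-page 16-bit integer TIFF. `read_stack_tiff()` multiplies by the
#' same `scale` to recover intensities.
#'
#' @param stack T x Y x X numeric array.
#' @param mask Y x X integer matrix.
#' @param path Output/input file path.
#' @param scale Intensity scale factor (default 65535).
#' @return File path (writers, invisibly); array/matrix (readers).
#' @export
write_stack_tiff <- function(stack, path, scale = 65535) {
  stopifnot(length(dim(stack)) == 3L, max(stack) <= scale, min(stack) >= 0)
  pages <- lapply(seq_len(dim(stack)[1]), function(i) stack[i, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]] * scale
  arr
}

#' @rdname write_stack_tiff
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(is.matrix(mask), max(mask) <= 65535, min(mask) >= 0)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_label_mask <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
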