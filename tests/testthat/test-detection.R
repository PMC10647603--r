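test_that("constant and degenerate traces yield no peaks", {
  expect_equal(detect_peaks(rep(1, 50)), integer(0))
  expect_equal(detect_peaks(seq(0, 1, length.out = 30)), integer(0))
  expect_error(detect_peaks(c(1, 2)), "3 samples")
})

test_that("noiseless well-separated events are each found within one sample", {
  sim <- simulate_traces(rate_hz = 1 / 3, duration_s = 15) # 5 events
  tr <- normalize_to_background(sim$table)
  pk <- detect_peaks(tr$dff)
  expect_length(pk, 5)
  dt <- 15 / 156
  expect_true(all(abs(tr$time_s[pk] - sim$truth$peak_time_s) <= dt + 1e-12))
})

test_that("default parameters recover the event count on rhythmic traces", {
  # 1 Hz at the default window; 2 Hz needs the window lowered to match the
  # anticipated beat rate, as interactive practice prescribes
  sim1 <- simulate_traces(rate_hz = 1)
  tr1 <- normalize_to_background(sim1$table)
  expect_length(detect_peaks(tr1$dff), 15)
  sim2 <- simulate_traces(rate_hz = 2, decay_tau_s = 0.2)
  tr2 <- normalize_to_background(sim2$table)
  # noiseless trace: the difference-based noise gate has nothing to
  # estimate from (every sample moves with the signal), so disable it
  expect_length(
    detect_peaks(tr2$dff, detection_params(window_size = 4, prominence_k = 0)),
    30
  )
})

test_that("plateau ties resolve to the earliest index", {
  d <- c(0, 0, 2, 2, 0, 0, 0)
  pk <- detect_peaks(d, detection_params(window_size = 2, prominence_k = 0))
  expect_equal(pk, 3)
})

test_that("detected peaks honour the minimum separation", {
  set.seed(21)
  d <- as.numeric(arima.sim(list(ar = 0.7), 300))
  for (w in c(3, 8, 15)) {
    pk <- detect_peaks(d, detection_params(window_size = w, prominence_k = 0))
    if (length(pk) > 1) expect_gte(min(diff(pk)), w)
  }
})

test_that("triangular pulse bounds sit at the feet under zero/full tolerance", {
  tt <- seq(0.01, 2, by = 0.01)
  d <- triangle_dff(tt, centre = 1, rise = 0.5)
  ev <- locate_bounds(d, which.max(d),
                      detection_params(tol_peakstart = 0, tol_peakend = 1))
  expect_equal(ev$start_idx, 50) # t = 0.50, last zero sample before rise
  expect_equal(ev$peak_idx, 100)
  expect_equal(ev$end_idx, 150)  # t = 1.50, first zero sample after fall
  expect_equal(ev$baseline, 0)
  expect_true(ev$complete)
})

test_that("unrecovered tails are marked incomplete and excluded from means", {
  tt <- seq(0.01, 2, by = 0.01)
  d <- triangle_dff(tt, centre = 1.8, rise = 0.5) # falls off the trace end
  ev <- locate_bounds(d, which.max(d), detection_params())
  expect_false(ev$complete)
  tr <- make_traces(d, duration_s = 2)
  tf <- transient_features(tr, dplyr::mutate(ev, cell_id = "Cell1"))
  cs <- summarize_cells(tf, duration_s = 2)
  expect_equal(cs$n_transients, 0)
  expect_equal(cs$n_incomplete, 1)
  expect_true(is.na(cs$amplitude))
})

test_that("peak count is monotone in window size and prominence gate", {
  for (seed in 1:30) {
    sim <- simulate_traces(rate_hz = sample(c(0.5, 1, 1.5), 1),
                           decay_tau_s = runif(1, 0.2, 0.5),
                           noise_sigma = runif(1, 0, 2), seed = seed)
    d <- normalize_to_background(sim$table)$dff
    n_by_w <- vapply(c(2, 5, 10, 20), function(w) {
      length(detect_peaks(d, detection_params(window_size = w)))
    }, 1L)
    expect_true(all(diff(n_by_w) <= 0))
    n_by_k <- vapply(c(0, 2, 4, 8), function(k) {
      length(detect_peaks(d, detection_params(prominence_k = k)))
    }, 1L)
    expect_true(all(diff(n_by_k) <= 0))
  }
})

test_that("raising tolerances shifts starts and ends right, never left", {
  for (seed in 31:60) {
    sim <- simulate_traces(rate_hz = sample(c(0.5, 1), 1),
                           noise_sigma = runif(1, 0, 2), seed = seed)
    d <- normalize_to_background(sim$table)$dff
    pk <- detect_peaks(d, detection_params(window_size = 6))
    if (length(pk) == 0) next
    s1 <- locate_bounds(d, pk, detection_params(tol_peakstart = 0.05))
    s2 <- locate_bounds(d, pk, detection_params(tol_peakstart = 0.20))
    expect_true(all(s2$start_idx >= s1$start_idx))
    e1 <- locate_bounds(d, pk, detection_params(tol_peakend = 0.80))
    e2 <- locate_bounds(d, pk, detection_params(tol_peakend = 0.95))
    end1 <- ifelse(e1$complete, e1$end_idx, .Machine$integer.max)
    end2 <- ifelse(e2$complete, e2$end_idx, .Machine$integer.max)
    expect_true(all(end2 >= end1))
  }
})

test_that("manual adjustment respects ordering and updates the baseline", {
  sim <- simulate_traces(rate_hz = 1 / 3, noise_sigma = 1, seed = 13)
  tr <- normalize_to_background(sim$table)
  ev <- detect_transients(tr)
  first <- ev[ev$event == 1, ]
  # moving the end later on the decaying tail lengthens the transient
  moved <- adjust_event(ev, tr, "Cell1", 1, "end", first$end_idx + 3)
  f0 <- transient_features(tr, ev)
  f1 <- transient_features(tr, moved)
  expect_gt(f1$duration_s[1], f0$duration_s[1])
  expect_true(moved$manually_adjusted[1])
  # moving the start changes the recorded baseline to the trace value there
  moved2 <- adjust_event(ev, tr, "Cell1", 1, "start", first$start_idx - 2)
  d <- tr$dff[tr$cell_id == "Cell1"]
  expect_equal(moved2$baseline[1], d[first$start_idx - 2])
  # illegal move is rejected and leaves events unchanged
  expect_error(adjust_event(ev, tr, "Cell1", 1, "start", first$peak_idx),
               "before peak")
  expect_identical(ev, detect_transients(tr))
})

test_that("adjusting a noisy peak to the true argmax matches noiseless detection", {
  clean <- simulate_traces(rate_hz = 1 / 3, seed = 17)
  noisy <- simulate_traces(rate_hz = 1 / 3, noise_sigma = 2, seed = 17)
  tr_c <- normalize_to_background(clean$table)
  tr_n <- normalize_to_background(noisy$table)
  ev_c <- detect_transients(tr_c)
  ev_n <- detect_transients(tr_n)
  # force every noisy peak onto the noiseless argmax position
  for (i in seq_len(nrow(ev_n))) {
    if (ev_n$peak_idx[i] != ev_c$peak_idx[i]) {
      ev_n <- adjust_event(ev_n, tr_n, "Cell1", ev_n$event[i], "peak",
                           ev_c$peak_idx[i])
    }
  }
  expect_equal(ev_n$peak_idx, ev_c$peak_idx)
})

test_that("edits files apply through the scriptable interface", {
  sim <- simulate_traces(rate_hz = 1 / 3, seed = 19)
  tr <- normalize_to_background(sim$table)
  ev <- detect_transients(tr)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(
    data.frame(cell_id = "Cell1", event = 2, which = "end",
               new_index = ev$end_idx[2] + 2),
    path
  )
  out <- apply_edits(ev, tr, path)
  expect_equal(out$end_idx[2], ev$end_idx[2] + 2)
  expect_true(out$manually_adjusted[2])
})
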