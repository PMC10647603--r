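triangle_analysis <- function(dt = 0.01) {
  tt <- seq(dt, 2, by = dt)
  tr <- make_traces(triangle_dff(tt, centre = 1, rise = 0.5), duration_s = 2)
  ev <- locate_bounds(tr$dff, which.max(tr$dff),
                      detection_params(tol_peakstart = 0, tol_peakend = 1))
  ev$cell_id <- "Cell1"
  transient_features(tr, ev)
}

test_that("triangular pulse features match closed-form geometry", {
  f <- triangle_analysis()
  dt <- 0.01
  expect_equal(f$amplitude, 1.0)
  expect_equal(f$duration_s, 1.0)
  expect_equal(f$time_to_peak_s, 0.5)
  expect_equal(f$auc, 0.5, tolerance = 1e-12) # trapezoid exact on lines
  expect_equal(f$t50_s, 0.25, tolerance = dt)
  expect_equal(f$t90_s, 0.45, tolerance = dt)
  expect_equal(f$upstroke_velocity, 2.0, tolerance = 1e-9)
})

test_that("amplitude and auc are invariant to a constant trace offset", {
  tt <- seq(0.01, 2, by = 0.01)
  base <- triangle_dff(tt, centre = 1, rise = 0.5)
  for (off in c(0, 0.8)) {
    tr <- make_traces(base + off, duration_s = 2)
    ev <- locate_bounds(tr$dff, which.max(tr$dff),
                        detection_params(tol_peakstart = 0, tol_peakend = 1))
    ev$cell_id <- "Cell1"
    f <- transient_features(tr, ev)
    expect_equal(f$amplitude, 1.0, tolerance = 1e-12)
    expect_equal(f$auc, 0.5, tolerance = 1e-12)
  }
})

test_that("recovery times come from the decay side and t50 <= t90 always", {
  sim <- simulate_traces(rate_hz = 1 / 3, rise_time_s = 0.1,
                         decay_tau_s = 0.4, seed = 23)
  res <- analyze_traces(normalize_to_background(sim$table))
  comp <- res$transients[res$transients$complete, ]
  dt <- 15 / 156
  # exponential decay: half-recovery at tau*ln(2) after the peak
  expect_true(all(abs(comp$t50_s - 0.4 * log(2)) <= dt))
  expect_true(all(comp$t50_s <= comp$t90_s, na.rm = TRUE))
})

test_that("decay tau fit recovers a pure exponential to 1e-6 relative", {
  t <- seq(0.096, 1.5, by = 0.096)
  tau <- fit_decay_tau(t, exp(-t / 0.4), 1, length(t), baseline = 0)
  expect_lt(abs(tau - 0.4) / 0.4, 1e-6)
  # offset and scaled variant
  tau2 <- fit_decay_tau(t, 2.5 * exp(-t / 0.4) + 0.3, 1, length(t),
                        baseline = 0.3)
  expect_lt(abs(tau2 - 0.4) / 0.4, 1e-6)
})

test_that("degenerate decay fits are reported missing, not as errors", {
  t <- seq(0.1, 1.5, by = 0.1)
  expect_true(is.na(fit_decay_tau(t, rep(0.2, 15), 1, 15, baseline = 0.2)))
  expect_true(is.na(fit_decay_tau(t, exp(-t / 0.4), 1, 3, baseline = 0)))
  # tail too slow to identify from the window
  expect_true(is.na(fit_decay_tau(t, exp(-t / 50), 1, 15, baseline = 0)))
})

test_that("the per-cell summary carries exactly the eleven features", {
  sim <- simulate_traces(n_cells = 2, seed = 3)
  res <- analyze_traces(normalize_to_background(sim$table))
  expect_length(ca_feature_names(), 11)
  expect_true(all(ca_feature_names() %in% names(res$cells)))
  other <- setdiff(names(res$cells),
                   c("cell_id", "n_transients", "n_incomplete", "n_tau_missing"))
  expect_setequal(other, ca_feature_names())
})

test_that("single-event cells report frequency but no interval features", {
  tt <- seq(0.096, 15, length.out = 156)
  d <- transient_waveform(tt - 5, 0.1, 0.4)
  tr <- make_traces(d, duration_s = 15)
  res <- analyze_traces(tr)
  expect_equal(res$cells$n_transients, 1)
  expect_equal(res$cells$frequency_hz, 1 / 15)
  expect_true(is.na(res$cells$time_between_max_s))
  expect_true(is.na(res$cells$inter_event_interval_s))
})

test_that("rhythmic cells recover frequency and peak spacing", {
  sim <- simulate_traces(rate_hz = 1, seed = 29)
  res <- analyze_traces(normalize_to_background(sim$table),
                        detection_params(window_size = 6))
  truth_complete <- sum(sim$truth$recovery_complete)
  expect_equal(res$cells$frequency_hz, truth_complete / 15)
  expect_equal(res$cells$time_between_max_s, 1.0, tolerance = 0.02)
  expect_gt(res$cells$inter_event_interval_s, 0)
})

test_that("identical traces give identical summaries", {
  sim <- simulate_traces(noise_sigma = 2, seed = 37)
  two <- sim$table
  two$Cell2 <- two$Cell1
  tbl <- intensity_table(as.data.frame(two)[-1], duration_s = 15,
                         background = "Background")
  res <- analyze_traces(normalize_to_background(tbl))
  a <- res$cells[res$cells$cell_id == "Cell1", -1]
  b <- res$cells[res$cells$cell_id == "Cell2", -1]
  expect_equal(as.data.frame(a), as.data.frame(b))
})
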