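# catransient

Quantitative analysis of single-cell calcium transients from fluorescence
imaging of cardiomyocyte monolayers — for example hiPSC-derived
cardiomyocytes expressing a genetically encoded calcium indicator, where
per-cell kinetics (beat rate, amplitude, decay time constant) separate
patient-derived lines from controls.

The package takes either a per-frame mean-intensity table (the shape
ImageJ's ROI manager *Multi Measure* exports, one column per traced cell
plus a final cell-free background column) or a TIFF stack with an integer
label mask, and runs:

1. **frame → time**: `t_j = j · duration / frame_count` (1-based,
   end-inclusive);
2. **background normalization**:
   `ΔF/F = (F_cell − F_background) / F_background`, optional smoothing;
3. **transient detection** under three tunable parameters — minimum peak
   separation (`window_size`), a start threshold at
   `baseline + tol_peakstart · amplitude`, and an end at
   `tol_peakend · amplitude` recovery from the peak — plus a robust
   prominence gate; incomplete final transients are excluded from
   averages, and manual corrections apply through a scriptable edits
   table;
4. **eleven features** per transient/cell: amplitude, time to peak,
   duration, area under the curve, time to 50% and 90% recovery,
   upstroke velocity, mono-exponential decay tau
   (`y = A·e^{−(t−t_peak)/τ} + C`, constrained Levenberg–Marquardt),
   time between maxima, inter-event interval, transient frequency;
5. **group statistics**: per feature, one-way ANOVA and
   Bonferroni-corrected pooled-variance pairwise t tests across groups of
   cells, starred `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.

A seeded synthetic-trace generator (`simulate_traces()`,
`simulate_stack()`) emits recordings with known ground truth so every
stage is testable without microscope data.

## Worked example

```r
library(catransient)
library(dplyr)

# simulate a 15 s / 156-frame recording: 3 cells at 1 Hz, tau 0.4 s,
# noise 2% of baseline
sim <- simulate_traces(n_cells = 3, rate_hz = 1, decay_tau_s = 0.4,
                       noise_sigma = 2, seed = 7)
traces <- normalize_to_background(sim$table)
res <- analyze_traces(traces, detection_params(window_size = 6))
res$cells %>% select(cell_id, n_transients, frequency_hz, amplitude,
                     decay_tau_s) 
#> # A tibble: 3 × 5
#>   cell_id n_transients frequency_hz amplitude decay_tau_s
#>   <chr>          <int>        <dbl>     <dbl>       <dbl>
#> 1 Cell1             13        0.867     0.883       0.371
#> 2 Cell2             13        0.867     0.885       0.446
#> 3 Cell3             13        0.867     0.879       0.375
```

Each cell shows 13 complete transients: the simulation contains 15
events, but the first of a sustained 1 Hz train cannot recover 90% of its
amplitude before the next beat (its baseline has no residue elevation)
and the last is truncated by the recording end, so both are excluded from
averages — `frequency_hz = 13/15`. Amplitudes near 0.88 reflect the
sampled peak of a sharp 0.1 s rise at 10.4 frames/s (the vertex falls
between frames); the decay tau estimates scatter around the simulated
0.4 s. `plot_cell_trace(traces, res$events)` draws the traces with
detected starts (green), peaks (orange) and ends (blue ×) for review,
and `compare_features(cells, group)` + `tidy()` / `glance()` /
`autoplot()` handle multi-group statistics.

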