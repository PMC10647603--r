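---
title: "Quantifying single-cell calcium transients: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-cell calcium transients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(catransient)
library(dplyr)
```

## The measurement problem

Spontaneously beating cardiomyocyte monolayers expressing a genetically
encoded calcium indicator produce, for every cell, a fluorescence time
series: a baseline interrupted by rapid rises (calcium release during
systole) followed by roughly mono-exponential decays (reuptake and
extrusion). Recordings are short — typically 15 s at around 10 frames per
second — and each field of view yields tens of manually outlined cell
ROIs plus one cell-free background region. The scientific questions live
in per-cell kinetic features (beat rate, amplitude, decay time constant,
recovery times, and so on) compared across cell lines or treatments.

`catransient` covers the full path: per-frame ROI mean intensities (from
an exported table or a TIFF stack with an integer label mask),
background normalization, transient detection with tunable
window/tolerance parameters and scriptable manual overrides, eleven
per-transient/per-cell features, and one-way ANOVA with
Bonferroni-corrected pairwise comparisons across groups of cells.

## From frames to normalized traces

Exported intensity tables carry no time metadata, so the recording
duration is a required input. Frames are 1-based and end-inclusive:
`t_j = j * duration_s / frame_count`, so frame 156 of a 15 s / 156-frame
recording maps to 15 s and the first frame to one sampling interval
(~0.096 s).

Each cell is normalized to the cell-free background ROI:

$$\Delta F/F(t_j) \;=\; \frac{F_\text{cell}(t_j) - F_\text{bg}(t_j)}{F_\text{bg}(t_j)}.$$

By protocol the background region is traced last, so the reader takes
the final ROI column as background unless told otherwise. Because the
background shares the illumination and bleaching trend of the cells,
multiplicative drifts largely cancel; the package applies no separate
photobleach correction (the simulator's `bleach_fraction` exists to
verify this cancellation, not to be corrected for).

Smoothing is off by default and intended only for recordings with poor
signal: a hard spectral low-pass (`fft_lowpass`) that zeroes all
components above the cutoff, with the trace mean-padded to twice its
length to soften wrap-around ringing, and a centred moving average with
reflection padding. The hard cutoff is the plain reading of an "FFT
filter" smoothing step; no taper is applied. Edge effects mean the
truncated output's mean can drift by order 10^-3 on noisy traces — exact
DC preservation holds on the padded extension, not the truncated half —
which is why tests of attenuation evaluate the interior of the trace.

## Transient detection

Three user-facing parameters control detection, with defaults
`window_size = 10` samples, `tol_peakstart = 0.05`, `tol_peakend = 0.90`,
plus a robustness gate `prominence_k = 4`:

* **window_size** — the minimum separation between detected peaks. A
  sample is a peak when it strictly dominates every earlier sample and
  weakly dominates every later one within `window_size` samples (ties on
  a plateau therefore resolve to the earliest index, and endpoints are
  never peaks), and when its topographic prominence exceeds
  `prominence_k` robust noise standard deviations. Raising the window or
  the gate can only reduce the peak count. The noise scale is the median
  absolute deviation of the first differences of the trace divided by
  (sqrt(2) * 0.6745); on noiseless synthetic traces every difference is
  signal, the estimate is inflated, and the gate should be disabled
  (`prominence_k = 0`). **Choose the window for the anticipated beat
  rate**: at 10.4 samples per beat (1 Hz at 156 frames / 15 s) the
  default window of 10 leaves no margin — one sample of peak jitter under
  noise puts true peaks 9 samples apart and one of them is suppressed —
  so rhythmic 1 Hz recordings are analyzed with `window_size = 6`, and
  2 Hz recordings need it lowered further (tests use 4). This mirrors
  interactive practice, where the window is lowered proactively when a
  higher transient frequency is anticipated.
* **tol_peakstart** — the transient start is the last pre-peak sample at
  or below `pre-peak baseline + tol_peakstart * amplitude`, where the
  pre-peak baseline is the trace minimum since the previous peak and the
  amplitude estimate is peak minus that baseline. Raising it moves starts
  later, never earlier.
* **tol_peakend** — the end is the first post-peak sample that has
  recovered at least `tol_peakend * amplitude` from the peak, searching
  no further than the next transient's start (transients never overlap).
  Raising it moves ends later. If the threshold is never reached —
  typically the final transient of a recording — the event is marked
  incomplete: it stays in the per-transient output but is excluded from
  every per-cell average, the tabular equivalent of deleting the final
  unfinished transient before summarizing.

The fractional-amplitude semantics of the two tolerances are the
simplest convention under which both "raise to shift right" behaviours
hold; interactive tools that expose similarly named dials may differ
numerically.

Automatic detection is reviewed per cell (`plot_cell_trace()` draws
starts green, ends as blue crosses, peaks as orange triangles, hollow
for incomplete events), and corrections are supplied as a scriptable
edits table (`adjust_event()`, `apply_edits()`): ordering
`start < peak < end` is enforced, the baseline is recomputed when a
start moves, and detection is not re-run afterwards — re-running would
reset the corrected points.

## The eleven features

Per complete transient, all baseline-relative (baseline = trace value at
the transient start):

| feature | definition |
|---|---|
| `amplitude` | ΔF/F at the peak minus baseline |
| `time_to_peak_s` | start to peak, seconds |
| `duration_s` | start to end, seconds |
| `auc` | trapezoidal integral of (ΔF/F − baseline) over the event, negative excursions clipped to zero so noise cannot produce negative area |
| `t50_s`, `t90_s` | time from the **peak** until the trace first recovers 50% / 90% of the amplitude toward baseline, linearly interpolated between samples; missing (with a QC count) if never reached before the event end |
| `upstroke_velocity` | maximum discrete first derivative on the rising limb (the mean rise rate amplitude/time-to-peak is also reported per transient as `mean_upstroke_velocity`, but the maximum is the feature: "velocity" reads as a rate, not an average) |
| `decay_tau_s` | mono-exponential decay constant, below |
| `time_between_max_s` | mean successive peak-to-peak interval (needs ≥ 2 transients) |
| `inter_event_interval_s` | mean end-to-next-start gap, floored at 0 (needs ≥ 2 transients) — deliberately distinct from time between maxima |
| `frequency_hz` | complete transients per second of the whole recording, well-defined even for a single event |

Recovery times are measured from the peak because they describe the
decaying limb; an alternative convention measures from the transient
start, which would simply add `time_to_peak_s`.

Per cell, features are averaged arithmetically over complete transients
only; missing decay-tau or recovery-time values drop out of their own
mean pairwise. A cell with no complete transient keeps its summary row
with `n_transients = 0` and missing features.

### The decay-tau fit

`y(t) = A exp(-(t - t_peak)/tau) + C` is fitted by constrained
Levenberg–Marquardt least squares (`A > 0`, `tau > 0`), initialized at
`A = amplitude`, `C = baseline`, `tau = t50 / ln 2` (fallback: a third
of the fit span). Numerical choices that matter:

* **Window**: the fit spans from one sample after the peak to the last
  sample before the next transient starts (trace end for the last
  event). Skipping the peak sample avoids the vertex kink — the sampled
  maximum can land just before the true vertex, on the rising limb,
  which flattens the apparent decay start and inflates tau even without
  noise. Extending beyond the 90%-recovery sample to the full available
  decay limb stabilizes the three-parameter fit under noise.
* **Identifiability**: a fit is reported missing (never an error) when
  fewer than 4 samples are available, the optimizer fails, the fitted
  amplitude collapses to zero (flat tail), or the fitted tau is at least
  as long as the fitted window — over such a window the curve is
  indistinguishable from a line, and without this rule a few runaway
  fits under noise put a heavy right tail on the per-cell mean.

## The synthetic-trace generator

Every stage is validated against `simulate_traces()` /
`simulate_stack()`, which emulate the study conditions end to end: a 15 s
recording at 156 frames, cells beating regularly at 1 Hz (events at
0.5, 1.5, ..., 14.5 s), waveform = linear rise (0.1 s) then
mono-exponential decay (tau 0.4 s), amplitude 1.0 ΔF/F, equal cell and
background baselines of 100 arbitrary units, and optional i.i.d.
Gaussian noise (2% of baseline in the validation runs — at the ROI-mean
level the central limit theorem makes Gaussian noise an adequate model
of photon shot noise), linear photobleaching, and lognormal
cell-to-cell variability (`cell_cv`, mean-one, default 0). The rendered
stack places each cell as a disc of pixels carrying exactly the cell's
trace value, so ROI extraction must reproduce the table to double
precision.

Ground truth is emitted in the same run (never regenerated from the
seed) and includes two deliberately distinct amplitude columns and a
completeness flag:

* `amplitude_dff` — the model amplitude;
* `sampled_amplitude_dff` — the amplitude realized on the discrete
  sampling grid (noiseless sampled maximum minus pre-onset minimum). At
  10.4 frames/s a 0.1 s-rise vertex falls between frames, attenuating
  the sampled peak by ~9% on average. That loss happens in acquisition,
  before any analysis, so analyzer accuracy is judged against the
  sampled truth. The attenuation depends on the decay rate (slower decay
  holds the near-vertex sample higher), which also means sampled-peak
  amplitudes carry a small tau-dependent bias — a few percent between
  tau 0.3 s and 0.6 s groups — that can reach statistical significance
  when between-cell variability is small. This is a property of
  peak-sampling at this frame rate, not of the analysis.
* `recovery_complete` — whether, in closed form on the noiseless model,
  the event recovers 90% of its amplitude above its own pre-onset
  residue baseline before the next event and before the recording ends.
  Under a sustained 1 Hz rhythm with tau 0.4 s, recovery from a clean
  baseline needs `tau ln 10 = 0.92` s but only 0.9 s separates onset
  from the next event: the first transient of each train (whose baseline
  carries no residue elevation) and the truncated final one are
  therefore structurally unrecoverable, and the recoverable truth
  frequency is 13/15 Hz·s, the correct estimand for a frequency defined
  as complete transients per recording duration.

What the generator does **not** emulate: motion artifacts, focus drift,
overlapping or moving cells, arrhythmic waveform shapes (double peaks,
plateaus) beyond irregular event spacing, and Poisson pixel statistics.
Passing the validation suite therefore demonstrates correct recovery of
well-formed rhythmic transients under realistic noise, not robustness to
every pathology of real recordings — which is precisely why the per-cell
review plots and the manual-edit pathway exist.

## Group comparison

Cells — not transients — are the unit of analysis; each of the eleven
features is tested independently with a classical fixed-effects one-way
ANOVA (F on k−1, N−k degrees of freedom) and all k(k−1)/2 pairwise
two-sample t tests pooling the ANOVA within-group variance, each raw p
multiplied by the number of comparisons and capped at 1 (the textbook
Bonferroni post-hoc). Stars on adjusted p: `*` < 0.05, `**` < 0.01,
`***` < 0.001. Welch per-pair tests are available behind
`pool_sd = FALSE` for clearly heteroscedastic data. No normality
gatekeeping or nonparametric fallback is applied, and replicate
plates/differentiations are not modelled as blocking factors — with
cells pooled across replicates the comparisons inherit any
replicate-level confounding; treat them accordingly.

```{r example}
gen <- function(tau, seed) {
  sim <- simulate_traces(n_cells = 12, rate_hz = 0.5, decay_tau_s = tau,
                         noise_sigma = 2, cell_cv = 0.1, seed = seed)
  analyze_traces(normalize_to_background(sim$table))$cells
}
cells <- bind_rows(
  mutate(gen(0.30, 101), line = "ctrl"),
  mutate(gen(0.55, 202), line = "dcm")
)
cmp <- compare_features(cells, line,
                        features = c("decay_tau_s", "frequency_hz"))
glance(cmp)
tidy(cmp)
```

## Problem sizes and validation scope

The validation suite exercises: 30-cell recordings at the study
conditions above for parameter recovery (beat rate and amplitude
recovered within 5%, decay tau within 10%, transient counts exact per
cell); 100 randomized traces for the monotonicity properties of the
window and tolerance parameters; brute-force ROI-mean references on
8×8×5 stacks; a hand-derived ANOVA (F = 13.5 for groups 1,2,3 vs 4,5,6),
a 10^4-shuffle permutation oracle for the pairwise tests at n = 6 per
group, and 200 null replicates bounding the familywise false-star rate
at 0.08; and byte-identical reruns of the full pipeline from a resolved
configuration file. These sizes keep the whole suite under a minute on a
laptop while leaving each check statistically meaningful.
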