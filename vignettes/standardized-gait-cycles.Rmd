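---
title: "Standardized gait cycles for segmental spinal rotation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized gait cycles for segmental spinal rotation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinegait)
```

## The measurement problem

Dynamic surface topography estimates the transverse-plane (axial) rotation of
each spinal segment — pelvis, L4 up to T1, and C7; L5 is not estimated because
surface shape correlates poorly with vertebral position in the lower back —
from the shape of the walking subject's back, at 60 Hz. A pressure plate in
the treadmill records per-foot vertical ground reaction force at 120 Hz. Both
devices start simultaneously, but raw exports from different measurements
differ in length and cadence, so per-segment curves are not directly
comparable between measurements or subjects.

`spinegait` implements the processing chain that makes them comparable:

1. **Event detection** (`detect_events()`): Initial Contact (IC, foot strikes
   the ground) and Initial Swing (IS, toe-off) per foot from the force trace.
2. **Phase encoding and synchronization** (`encode_phases()`,
   `synchronize()`): stance/swing codes on the 60 Hz frame grid.
3. **Cycle segmentation** (`segment_cycles()`): a gait cycle runs from one
   right-foot IC to (excluding) the next, so `n` right ICs delimit `n - 1`
   complete cycles.
4. **Standardization** (`normalize_cycles()`, `fit_sgc()`): each cycle's
   frames are mapped to percent-of-cycle, the pooled points of three or more
   cycles are fit by one cubic smoothing spline per segment, and the result
   is evaluated on the 101-point grid 0, 1, ..., 100 % — the Standardized
   Gait Cycle (SGC).
5. **Descriptors** (`spine_features()`): symmetry line, level shift,
   amplitude, maxima timing relative to stance, pairwise phase shifts on the
   antagonism percentage scale, and the point of intersection.

A synthetic-data generator (`simulate_recording()`) stands in for the
proprietary measurement device so that every stage can be validated against
known ground truth.

## Event detection and phase encoding

A foot is in contact when its force exceeds a *relative* threshold: 5 % (by
default) of that foot's 95th force percentile. A relative rule is robust to
the absolute force scale, which varies with body weight and with simulator
settings; the 95th percentile rather than the maximum makes the reference
robust to single spiky samples. Contact runs are debounced with a minimum
credible phase duration (default 0.1 s): shorter sub-threshold gaps are
merged into the surrounding contact, shorter contact runs are discarded.
Increasing the debounce window can therefore only reduce the event count,
never increase it.

IC is the first sample of a contact run and IS the first sample after it.
Because the true transition occurred somewhere between the last sample of the
old phase and the first sample of the new one, events are *timestamped at the
midpoint* of that 1/120 s interval (clamped at the recording start). This
convention is unbiased at sub-sample resolution and is what lets a simulated
60 % stance fraction come back as exactly 60 % after frame rounding; anchoring
the timestamp on the first new-phase sample instead would bias every IS late
by half a force sample and push the recovered stance share of a 72-frame
cycle from 43 to 44 frames.

Synchronization with the spine stream is nearest-sample pairing (frame `k` at
`k/60` s pairs with force sample `2k`), not interpolation: phase codes are
categorical, so interpolating force values would add nothing. Rounding of
event times onto the frame grid is round-half-up, documented and used
consistently. Frames before a foot's first detected event are left
unannotated and excluded from cycles rather than extrapolated.

## The standardized gait cycle

All samples of all complete cycles are pooled as (percent-of-cycle, degrees)
points per segment and fit with one cubic smoothing spline
(`stats::smooth.spline`), with the penalty chosen per segment by generalized
cross-validation when `smoothing = "auto"`. Pooling-then-fitting (rather than
resampling each cycle to a grid and averaging) uses every observed point at
its exact cycle position and needs no intermediate grid. The 101-point
output grid (0–100 inclusive, step 1) is the conventional resolution for
gait curves; the endpoint is duplicated (0 % and 100 % describe the same
cycle instant), which matters for the period statistics below.

Numerical choices:

* `smoothing` is the spline penalty λ; as λ → 0 the fit approaches the
  interpolant of the pooled points (a floor of 1e-10 keeps the solver away
  from the exactly-singular limit).
* `periodic = TRUE` switches to a cyclic cubic basis (`mgcv::gam`,
  `bs = "cc"`, GCV), which closes the curve exactly,
  `curve(0 %) == curve(100 %)`. The default is non-periodic because measured
  cycles genuinely end slightly away from where they started; forcing
  closure would hide that.
* Constant segments short-circuit to a constant curve — a smoothing spline
  reproduces constants anyway, but zero-variance input can upset GCV.
* `NA` samples are excluded from the fit, never imputed; an all-`NA` segment
  is omitted from the SGC with a warning.
* At least 3 distinct cycles and 10 samples per segment are required; fewer
  cycles is an error, because a single- or two-cycle "standardized" curve
  would misrepresent what the standardization claims.

The suite verifies the two properties that justify the construction: the SGC
of three noisy cycles is closer (RMSE) to the true curve than any single raw
cycle, and recordings of the same true curve at different cadences (60 vs 84
frames per cycle) yield near-identical SGCs. It also verifies that a
superimposed higher-frequency rhythm — an individual characteristic, not an
artifact — survives standardization with more than half of its spectral
power.

## Motion descriptors

* **Symmetry line (SL)** — the level a segment oscillates around: the mean of
  the curve over one period (grid points 0–99, so the duplicated endpoint is
  counted once). The midrange `(max + min)/2` is a defensible alternative
  reading and is reported alongside (`symmetry_line_midrange`); the time-mean
  is the primary definition because it is stable under asymmetric waveforms.
* **Level shift (LS)** — SL minus zero; positive values are shifts toward
  left rotation.
* **Amplitude** — the total excursion `max − min`; the `< 5°` low-movement
  flag is applied to this total excursion, and half-amplitude is reported
  separately.
* **Phase shift** — between two curves on the shared grid: mean-center both,
  circularly cross-correlate over the 100-point period, take the
  best-aligning lag `L` (ties resolved toward the smaller folded lag), fold
  `d = min(L, 100 − L)` and report `2d`, so antiphase ↦ 100 %, quadrature ↦
  50 %, in-phase ↦ 0 % (equivalently 3.6°·d of phase angle). Cross-correlation
  uses the whole waveform and therefore tolerates non-sinusoidal periodic
  shapes with steep rises; the peak-timing estimate (`method = "peak"`) is
  available for comparison. A constant curve has no phase: that is an error,
  not a zero.
* **Point of intersection (PoI)** — scanning caudally-to-cranially, the first
  segment whose phase shift versus the pelvis exceeds 50 % (more than a
  quarter cycle). Low-movement segments are skipped: they sit near the zero
  line where the directional exchange happens and their phase estimate is
  noise-dominated. If no segment crosses — an amble-like, whole-spine-in-phase
  pattern — there is no PoI. The first-crossing and skip rules are this
  package's conventions; the construct itself is defined only verbally in the
  gait-analysis literature.
* **Maxima vs gait phase** — each segment's leftward maximum is classified
  into `[0, stance/2)`, `[stance/2, stance)`, `[stance, 100)` with half-open
  bounds, using the measurement's mean right-stance percentage.

## What the generator emulates — and what it does not

`simulate_recording()` produces, per segment,
`level + A·sin(2π(t/T − lag))`, optionally plus a higher-harmonic rhythm
term, plus Gaussian noise; forces follow a double-bump stance profile
(raised-cosine peaks at 25 % and 75 % of stance for weight acceptance and
push-off), exactly zero in swing, with noise clipped at zero. Defaults are
chosen once as the canonical study conditions:

* stride 1.2 s at 5 km/h-like cadence, 4 strides (hence 4 right ICs and the
  3 complete cycles an SGC needs), stance fraction 0.60;
* amplitudes: pelvis and T7/T8 largest (6°), T12 smallest (1.5°, total
  excursion 3° — deliberately under the 5° low-movement flag), the rest
  graded smoothly between. Published descriptions of these curves are
  qualitative apart from the `< 5°` low-movement bound, so the magnitudes
  are illustrative, not reference values;
* phase lags: 0 for pelvis and L4, ramping linearly to antiphase (0.5) at T8
  and constant above — the ramp crosses the quarter-cycle mark between T12
  and T11, so the typical preset's PoI is T11;
* presets: `superimposed` adds a third-harmonic rhythm (1.5°), `amble` zeroes
  all lags, `shifted` moves the thoracic symmetry lines 4° to the right;
* noise: 0.5° on rotation and 5 force units on force (about 0.7 % of the
  700-unit stance peak), sensor-scale rather than stride-to-stride scale.

The generator is deliberately *not* a biomechanical model: it has no
stride-to-stride timing variability, no asymmetric gait (the left foot is
exactly half a stride behind the right), no soft-tissue artifacts, and one
rotation oscillation per stride by construction. Passing tests therefore
show that the pipeline recovers what it claims from signals with the stated
structure — periodicity, phase gradients, level shifts, double-bump stance
loading — not that it is robust to every pathology of real exports.
Conversely the detection tolerance test (20 seeded noisy recordings, maximum
IC error ≤ 3 frames at 60 Hz) mirrors the face-validation practice of
checking automated detection against video frames.

## Export dialect

Vendor export layouts are proprietary and depend on the parameter choices
made in the acquisition software, so the package freezes one documented
dialect instead of guessing at an unpublished format: comma-separated UTF-8
with a dot decimal (comma accepted on read), headers
`frame,time_s,PELVIS,...,C7` and `sample,time_s,force_left,force_right`,
0-based gapless indices, time = index/rate, all intervals half-open
`[start, end)`. Reading is strict — a missing or unexpected segment column
and any non-numeric cell are hard errors naming the culprit — because a
silently mis-mapped column is the worst failure mode of an assembly step.
Subject code and speed travel in the filename
(`<code>_<speed>kmh*.csv`), merging preserves row counts
(files × frames × 18 segments) independently of input order, and duplicate
(subject, speed, frame) keys abort the merge as ambiguous.

## Problem sizes

The test suite and the acceptance script run on 4–6-stride recordings
(289–433 frames at 60 Hz, 577–865 force samples), 20-recording batches for
the detection-tolerance checks, and 10–25-case parameter sweeps for the
property tests; these sizes give sub-sample-accurate checks for every
deterministic contract and comfortable margins for the stochastic ones while
keeping the whole suite interactive.

## Known limitations

* Only transverse-plane rotation is modelled and analyzed; sagittal and
  frontal planes are out of scope.
* Only IC/IS and the stance/swing dichotomy are encoded, not the full
  eight-phase gait model.
* The event detector's threshold rule is a documented stand-in validated
  against the package's own simulator; vendor detection logic is unpublished.
* Whether pooling more than three cycles changes downstream descriptors is
  an open scientific question; `fit_sgc()` accepts any number ≥ 3 and makes
  no claim.
* A local Fourier representation could serve the same standardization goal;
  it is deliberately not implemented here.
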