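---
title: "Oculomotor event detection and parameter extraction with gazemetrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor event detection and parameter extraction with gazemetrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazemetrics)
```

gazemetrics analyses eye-tracking recordings end to end: it converts
vendor text exports (EyeLink-, SMI- and Tobii-style dialects) to a common
trial table, detects blinks, fixations, saccades and microsaccades,
extracts 21 per-trial eye-movement parameters, compares subject and
stimulus groups with a small matrix of classical tests, and renders the
standard plots of the field. This vignette explains the models and the
numerical choices; the README shows the happy path.

## The trial table

Every recording is reduced to one flat table per (subject, stimulus)
trial with the frozen column set of `base_format_columns()`: timestamps
in ms, binocular gaze in screen pixels (origin top-left, y downward),
binocular pupil size in vendor arbitrary units, an optional vendor event
flag, a free-text message column, and the sampling rate. Lost samples are
`NA` in the pupil columns; by invariant, gaze may be missing only where
the same eye's pupil is missing. Timestamps must increase strictly — a
violation is an error, never a silent reorder, because resorting would
silently repair corrupted exports.

Detection runs on a monocular trace. By default the two eyes are
averaged where both are valid and the valid eye is used where only one
is; `detection_config(eye =)` selects a single eye instead. Averaging
halves independent sensor noise and is the common practice when no eye
dominance is recorded.

## Blink detection and refinement

Blinks appear as runs of lost pupil samples, but the eyelid already
distorts the signal before the dropout: the apparent pupil shrinks over
the closing flank and recovers over the opening flank. The detector
therefore refines the raw gap boundaries: the pupil series is smoothed
with a centred moving average (window `blink_smooth_window_ms`, default
10 ms — at 1000 Hz an impulse has exactly 10 samples of support), and
the initial onset (last valid sample before the gap) is walked backward
while the smoothed series rises going backward, i.e. while the pupil was
still falling into the blink; the offset is walked forward
symmetrically. Walks use strict monotonicity, so plateaus stop them —
this keeps two nearby blinks from bleeding into each other across a flat
recovery. Smoothing windows never cross a gap, and where a window would
cross the segment edge it shrinks symmetrically, which preserves the
local monotone structure that the walk needs on short flanks.
Refinement can only widen the raw missing run; refined windows that
overlap are merged.

## Fixations: dispersion thresholding (I-DT)

Gaze dwells are found with the dispersion-threshold loop. The dispersion
of a window is

$$D = \sqrt{[\max(G_x) - \min(G_x)]^2 + [\max(G_y) - \min(G_y)]^2},$$

the same quantity that later serves as the amplitude of saccadic events
(one shared implementation, `compute_dispersion()`). A candidate window
of the minimum fixation length `w_thresh_ms` (default 50 ms) grows one
sample at a time while `D <= d_thresh_px`; when it first exceeds the
threshold, the window minus its last point is emitted as a fixation and
the next candidate starts after it; if the initial window already
exceeds the threshold its start slides by one sample. Ties grow — a
window exactly at threshold is still a dwell. A window still within
threshold at the end of the trace is emitted, since the dwell was merely
truncated by the recording.

Two numerical choices deserve a note:

* The minimum window is `round(w_thresh_ms * S_freq / 1000) + 1`
  samples. With 50 samples at 1000 Hz a "50 ms" fixation would span only
  49 ms from onset to offset; the extra sample makes the shortest
  reportable fixation actually span 50 ms, which is what a duration
  threshold means.
* `d_thresh_px` defaults to 25 px. Dispersion thresholds are screen- and
  viewing-distance-dependent and the I-DT literature leaves them to the
  analyst; 25 px is roughly 0.5–1° on a typical desktop setup and is a
  package default, configurable per run.

Samples inside refined blink windows are masked to `NA` before any gaze
detection: a half-closed eyelid drags the reported gaze and would
corrupt both dispersion and velocity. Missing samples split the trace,
and each valid segment is processed independently — velocities are never
taken across a gap.

One interaction is worth knowing: I-DT absorbs the slow tail of a
preceding saccade into the fixation window (the tail's residual movement
fits inside the dispersion budget). A small displacement later in the
fixation — a microsaccade — can then overflow the budget and split the
fixation at that point. This is faithful I-DT behaviour, not a defect,
but it means fixation counts on data with large planted microsaccades
can exceed the nominal count by one per split.

## Saccades: velocity thresholding (I-VT)

The pointwise velocity is the sample-to-sample difference
$V_t = G_t - G_{t-1}$ per axis. The classification threshold is quoted
in pixels per second (default 40 px/s), so the per-sample difference is
multiplied by the sampling rate before comparison — otherwise the same
threshold would mean different things at 250 and 1000 Hz. Samples whose
speed strictly exceeds the threshold are saccadic; consecutive saccadic
samples merge into one saccade, whose peak velocity is the maximum speed
over the run and whose amplitude is the dispersion of the run's gaze
points including the pre-movement sample (so a one-step jump of 100 px
has amplitude 100 px).

A 40 px/s pointwise threshold is *very* sensitive at high sampling
rates: at 1000 Hz it corresponds to 0.04 px per sample, far below the
jitter of video-based eye trackers. On noisy traces I-VT saturates —
nearly every sample classifies as saccadic and runs merge into long
pseudo-saccades. This is a property of the printed threshold, and the
package reproduces it rather than papering over it. The synthetic
generator's default gaze jitter (below) is chosen to sit inside the
regime where the threshold is operable.

## Microsaccades: the median-based adaptive threshold

Within each fixation, a smoother velocity is computed with the five-tap
moving-average stencil

$$V_t = (G_{t+2} + G_{t+1} - G_{t-1} - G_{t-2}) / (6 \times S_\mathrm{freq}),$$

with the first and last two samples set to zero. The divisor is applied
exactly in this form. Readers familiar with the microsaccade literature
will note that the original convention *multiplies* by the sampling rate
instead; the `engbert_units` switch restores that scale (a factor
$S_\mathrm{freq}^2$). Detection is entirely unaffected by the choice
because the threshold is estimated from the same velocities and the
classification criterion is scale-free per axis — only reported peak
velocities change. The default follows the formula as stated above and
the switch is documented, so either convention is one flag away.

The per-axis threshold is $V_\mathrm{thresh} = V_\mathrm{fac} \times
\sqrt{\mathrm{median}[(V - \mathrm{median}(V))^2]}$ with
$V_\mathrm{fac} = 5$: a robust spread estimate of the velocity noise
inside the fixation, times a safety factor. Samples with
$k = (V_x/V_{x,\mathrm{thresh}})^2 + (V_y/V_{y,\mathrm{thresh}})^2 > 1$
— an elliptic criterion — are candidates, and maximal candidate runs of
at least six samples become microsaccades, with peak velocity
$\max\sqrt{V_x^2+V_y^2}$ and amplitude again the dispersion of the run's
gaze points.

Because the threshold is *adaptive*, a noise-free segment has zero
spread and no meaningful threshold: `compute_ms_threshold()` raises a
typed condition and the caller skips that fixation with a warning. This
is inherent to the method — it detects excursions *relative to ambient
drift*, and with no drift there is no reference. Consequently the
zero-noise recovery suite exercises fixations, saccades and blinks
(whose detectors are well defined without noise), while microsaccade
recovery is exercised at small non-zero jitter.

## The 21 parameters

Per trial, after interpolating the pupil linearly across refined blink
windows (leading/trailing gaps take the nearest valid value):

* pupillometry — mean, peak, time-to-peak (ms) and trapezoidal area
  under the curve of the interpolated pupil, over the window from the
  stimulus-onset message (any message containing "onset"; else the first
  sample) to the end of the trial. No baseline subtraction is applied to
  the AUC: comparability across conditions is the job of
  control-stimulus normalization, and stacking two baseline corrections
  would obscure what was subtracted when.
* blinks — count, peak duration, mean duration.
* fixations — count, maximum and mean duration; restricted to an AOI
  (by centroid membership) when one is given.
* saccades and microsaccades — count, mean duration, mean peak
  velocity, mean amplitude. Aggregation across events is the arithmetic
  mean; empty families report zero.
* reading behaviour — a *reading* is a maximal run of consecutive
  fixations whose centroids fall inside the AOI; reported are the number
  of readings and the summed durations of the first and second runs
  (first/second pass). Without an AOI the three reading parameters are
  zero.

Exactly 21 scalars, in the frozen order of `eye_parameter_names()`.
Control normalization (`normalize_with_controls()`) subtracts, per
subject and parameter, the mean over that subject's control trials from
every non-control trial; a ratio mode is available behind
`method = "ratio"` but subtraction is the default because several
parameters (counts, normalized durations) can legitimately be zero in
controls.

## Areas of interest

Rectangles (two corners), ellipses (centre and semi-axes) and polygons
(vertex list) are supported, with boundary points counted inside for
every shape and polygon membership decided by ray-casting parity with an
on-edge short-circuit. Polygon self-intersection is not checked. A
per-stimulus CSV (`stimulus, shape, coordinates`, the coordinate field a
space-separated flat list) assigns one AOI per stimulus per run; a later
duplicate row overrides with a warning.

## Statistics

The statistical machinery is deliberately delegated to base R: mixed
ANOVA as `aov` with an `Error(subject/within)` stratum, repeated-measures
ANOVA with up to two within factors, factorial between-subjects ANOVA,
paired Student's t tests across within-level pairs, and Welch's t test —
this package's own contribution is the table shaping, the arity policing
per test, per-parameter iteration, and CSV reporting. Replicate trials
within a (subject × cell) are averaged before repeated-measures fits so
the error strata stay balanced. On balanced designs the `aov` strata
reproduce the classical Type-I mixed/RM ANOVA tables; no sphericity
correction is applied (with two within levels there is nothing to
correct; with three, interpret accordingly). No multiple-testing
correction is applied across the 21 parameters by default; `p_adjust`
accepts any `p.adjust` method. Zero-variance cells skip the parameter
with a warning rather than reporting a degenerate statistic.

## Visualization

The gaze heat map is a 2D histogram with `floor(n_rows/4)` by
`floor(n_cols/4)` bins over the image extent — a quarter of the pixel
resolution per axis — smoothed with a separable Gaussian (default sigma
2 bins, truncated at 3 sigma). Kernel mass that would spill past the
grid edge is folded back by reflection, so the smoothed grid sums
exactly to the kept sample count and the mass-conservation property is
testable to machine precision. Off-screen samples are dropped and
counted. Aggregate heat maps sum the per-subject *count* grids before
smoothing (so the aggregate of one subject equals that subject's map),
and saving one writes a sidecar text file listing the included subjects.
Fixation plots number the fixations in temporal order with marker area
proportional to duration; the main-sequence plot scatters peak velocity
against amplitude on log axes; the microsaccade position–velocity plot
stacks the four traces with detected runs shaded. The "dynamic" gaze and
pupil view is exported as a PNG frame sequence at a configurable
decimation; there is no animation or video encoding. Plot tests assert
on the built scene model (marker counts and coordinates), never on
raster pixels, and all renderers are pure functions of their inputs.

## The synthetic generator

`event_plan()` plus `generate_trial()` realize planted fixations,
saccades, microsaccades and blinks into base-format trials with a
recorded ground truth (realized sample indices per event), and
`make_synthetic_experiment()` lays a whole subject × stimulus grid on
disk with a Listing-style JSON config. Design choices:

* Saccades and microsaccades move along a raised-cosine displacement
  profile, so velocity peaks mid-movement and planted amplitude/velocity
  pairs trace a main sequence.
* Blinks are a missing run (exactly `duration * S_freq / 1000` samples)
  flanked by a 20 ms monotone pupil descent and ascent — the structure
  the refinement walks exploit. Ground truth spans flank to flank.
* Gaze noise is isotropic Gaussian with default SD 0.005 px, pupil
  noise SD 2 units on a baseline of 1000. The gaze default is chosen so
  that per-sample velocity noise (≈7 px/s SD at 1000 Hz) stays well
  below the 40 px/s I-VT threshold, i.e. inside the regime where a
  pointwise velocity classifier is meaningful. Video-based trackers are
  an order of magnitude noisier: passing recovery tests therefore show
  algorithmic correctness in the detectors' operating regime, not
  robustness to video-tracker jitter. That robustness question belongs
  to threshold selection on real data, which the configuration exposes
  but the tests do not claim to settle.
* Group effects are injected as a pupil-baseline shift for groups after
  the first and recorded in the ground-truth JSON, giving the
  statistics layer a known between-group signal (or, at zero, a true
  null).

The default experiment (two groups of three subjects, two stimulus
types of three stimuli, 3 s trials at 1000 Hz) keeps the full test suite
in the low minutes on one CPU; the acceptance sweeps are desk-scale by
construction (constant-speed traces, single-segment plants).

One sizing note: the I-VT boundary sweep uses a dyadic sampling rate
(1024 Hz) so that every integer speed's per-sample step is exactly
representable in binary floating point; at 1000 Hz the knife-edge case
"speed exactly at threshold" would be decided by rounding noise rather
than by the comparison rule.

## Store and formats

Converted trials can be kept as per-trial CSVs or aggregated into a
single-file SQLite database (one `samples` table indexed on subject and
stimulus) — the two backings answer every query identically, and the
suite fuzzes that equivalence. Vendor dialect grammars are documented in
`?convert_vendor_export`; all three round-trip losslessly through
`write_vendor_export()`, including messages containing separators. The
SMI dialect encodes lost samples as pupil 0 (the vendor convention), so
SMI round-trips are lossless whenever true pupil values are positive —
true of all generated data and of real recordings in vendor units.

## Known limitations

* No binary vendor formats (EDF/IDF), live recording, or GUI; the CLI
  script and the R API replace the windowed workflow.
* One AOI per stimulus per run; multiple or time-varying AOIs require
  re-running.
* I-VT with the default threshold is not usable on noisy video-tracker
  data at high sampling rates (see above); raise `ivt_vel_thresh`
  accordingly.
* The microsaccade detector is monocular (no binocular-conjugacy
  criterion) and undefined on noise-free segments by construction.
* Smooth pursuit is neither generated nor modelled; pursuit segments
  will be classified as fixation or saccade depending on speed.
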