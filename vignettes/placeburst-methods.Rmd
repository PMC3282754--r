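---
title: "Methods: place-field and burst-pattern analysis in placeburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place-field and burst-pattern analysis in placeburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`placeburst` analyses single-unit recordings of hippocampal CA1 place cells
from animals foraging in a cylindrical arena, together with a synthetic-data
generator that emulates such recordings so the whole pipeline can be
exercised and validated without any recorded data. This vignette documents
the models, the tunable parameters, the numerical choices, and the design
decisions that were genuinely open.

## Rate maps and place fields

Position samples (nominally 60 Hz) and spike times are binned onto an
axis-aligned, arena-centred grid of 1 x 1 cm pixels. Each spike is assigned
to the pixel of the temporally nearest track sample; occupancy accrues one
inter-sample interval (the median timestamp difference) per sample; the
pixel rate is spike count over dwell time. Pixels wholly outside the arena
circle are permanently invalid; for a 30-cm arena this leaves roughly 700
candidate pixels.

Three decisions here are ours, with the recording literature silent or
split:

* **Occupancy threshold.** Pixels with less than `min_occupancy = 0.1` s of
  dwell are invalid. A single 16.7-ms visit coinciding with one spike would
  otherwise produce a 60-Hz pixel; 0.1 s (six samples) suppresses these
  slivers while discarding almost no interior pixels of a 25-min session.
* **No smoothing.** Rate maps are never smoothed before a statistic is
  computed. Smoothing would inflate spatial coherence (which measures
  exactly the local smoothness we would be manufacturing) and bias the
  regression span selection.
* **No running-speed filter.** All samples and spikes are used.

The **place field** is, by default, the set of valid pixels whose rate
strictly exceeds the cell's overall firing rate (total spikes over total
dwell, i.e. the occupancy-weighted map mean); its pixel count is the field
size. The alternative `top_quartile` definition takes the ceiling of 25% of
valid pixels by rate, ties broken by pixel index order.

## Spatial statistics

* **Selectivity** = log10(in-field mean rate / out-field mean rate),
  unweighted pixel means, all valid non-field pixels forming the out-field.
  A silent out-field yields `Inf`, which is flagged and excluded from
  group averages.
* **Coherence** = Pearson r between each valid pixel's rate and the mean
  rate of its up-to-8 valid neighbours (pixels without a valid neighbour
  are skipped), reported with its Fisher Z transform `atanh(r)` (r clipped
  to 1 - 1e-7). A constant map has undefined coherence and raises a typed
  error.
* **Information rate** (bits/s) = sum over valid pixels of
  `p(x) lambda(x) log2(lambda(x) / lambda_bar)`, with `p(x)` the occupancy
  share renormalised over valid pixels and `lambda_bar = sum p(x) lambda(x)`.
  Using the occupancy-weighted map mean for `lambda_bar` (rather than the
  raw session spike count over duration) keeps the formula internally
  consistent with its own `p(x)` when pixels have been discarded; the two
  agree exactly when nothing is discarded. Zero-rate pixels contribute
  zero; the sum is nonnegative up to rounding (Jensen).

Note one asymmetry worth knowing when interpreting simulations: coherence
decreases under iid pixel noise but is invariant to affine rescaling,
whereas the information rate is convex in the rate and therefore
*increases* under iid pixel noise; what dilutes information is spatially
uniform (untuned) firing. The test suite checks each statistic against the
perturbation that actually degrades it.

## Stability, rotation search, cue classification

Cross-session stability is the Pearson correlation over jointly valid
pixels of the two session maps (error below 10 joint pixels), Fisher-Z
transformed. The rotation search rotates one map about the arena centre in
1-degree steps, resampling by nearest neighbour, and reports the angle of
maximum correlation. Nearest-neighbour (not bilinear) resampling is
deliberate: interpolation would smooth the rotated map and inflate its
correlation. Pixels whose rotation source lies outside the grid or on an
invalid pixel drop out; ties in the correlation go to the smallest angle.

For cue classification the earlier session's map is rotated to match the
later one, so the best angle reads directly as the field's displacement. A
field within a 90-degree arc (i.e. +/-45 degrees, half-open: the exact
boundary is not counted) of its original position followed the unmoved
distal light ("distal"); within +/-45 degrees of the card displacement it
followed the local cue ("local"); anything else remapped. With the
standard 90-degree card rotation these three windows exactly partition the
circle. The distal window is tested first, which matters only for card
rotations below 90 degrees where the windows could overlap.

The random-pair baseline -- similarities of maps from different cells --
estimates the chance level against which within-cell stability is judged.

## Burst detection and temporal statistics

A complex-spike burst is two or more spikes, each within 15 ms of its
predecessor, with progressively decreasing amplitudes. "Progressively
decreasing" is read strictly: an amplitude tie terminates the burst (a
toggle disables the amplitude criterion entirely). Because the rule
constrains only consecutive spike pairs, the greedy left-to-right scan is
equivalent to taking maximal runs of qualifying pairs; the implementation
exploits this (vectorised run-length encoding) and the test suite proves
the equivalence against an explicit greedy-loop oracle on 1,000 random
trains. When a middle spike violates the amplitude ordering, the scan
restarts a new candidate at that spike.

Burst statistics: burst frequency (bursts/s), intra-burst spike rate
(burst spikes over total time), mean spikes per burst, percentage of
spikes inside bursts, and the mean inter-burst interval measured from each
burst's end to the next burst's start (not onset-to-onset; switchable in
principle but end-to-start is what "interval between bursts" means).
Burst reliability is the fraction of bursts whose onset pixel (position at
the first spike) lies inside the place field, computed for both field
definitions; the burst place map bins burst onsets exactly like spikes and
its coherence quantifies the spatial regularity of bursting.

ISI histograms need bin choices the recording literature rarely states:

* intra-burst ISIs (ISI-1 = first-to-second spike, ISI-2, ISI-3): 0.5-ms
  bins on (0, 15] ms -- fine enough to separate peak times of 2.5 vs 3.9 ms;
* whole-session ISIs: 1-ms bins on (0, 500] ms with the modal bin searched
  on [1, 50] ms, so the peak reflects the burst/theta time scale rather
  than the long foraging tail.

Entropy is Shannon entropy over non-empty bins (bits); CV and SD are
computed from the raw intervals. Modal ties resolve to the smallest bin.

## Spatial regression and the logistic remapping model

The regression of firing rate on position is a locally weighted
least-squares fit: for each valid pixel, a degree-1 plane in (x, y) over
its `span * N` nearest valid pixels (minimum 3) with tri-cube distance
weights, evaluated at the pixel. This is the classical locally-weighted
construction; the span -- the neighbourhood fraction -- is the smoothing
parameter. It is selected per cell by 10-fold cross-validation over the
grid {0.05, 0.1, 0.2, 0.3, 0.5, 0.75, 1}, which spans near-local to
fully global fits; folds partition pixels (the regression's sampling
unit), ties go to the smaller span. Fit quality is the percent of
firing-rate variance explained, `100 (1 - sd(resid)^2 / sd(rate)^2)` --
the conventional variance-ratio form. Degenerate (collinear)
neighbourhoods fall back to the weighted neighbourhood mean. At full span
the local fit reduces to a per-pixel global weighted plane, which the test
suite checks against a direct normal-equation solution to 1e-8 Hz.

The remapping model is a logistic regression of a remap indicator on the
session ISI peak time, group, and session indicators, fitted by
iteratively reweighted least squares with step-halving, so the deviance is
non-increasing by construction; convergence is declared when the largest
coefficient change falls below 1e-8 (at most 100 iterations). Perfect
separation is detected (divergent linear predictor without convergence)
and flagged rather than silently reported. The reduced model drops the
ISI-peak column. The IRLS fitter agrees with `stats::glm` to 1e-8 on
well-posed problems; `glm` is used only as a cross-check.

Group contrasts use Welch's two-tailed unequal-variance t-test with
Welch-Satterthwaite degrees of freedom, one metric at a time, missing
values excluded pairwise. Per-metric p-values are reported unadjusted, as
is conventional for these recording studies; a Benjamini-Hochberg column
is emitted alongside for transparency but drives no decision.

## The synthetic generator: what it emulates, and what it does not

The generator produces the three ingredients the analyses consume:

**Trajectory.** Heading performs a random walk with increment sd
`sqrt(2 dt / heading_persistence)` (default persistence 1 s); speed is a
mean-reverting AR(1) around `mean_speed` (default 6.2 cm/s, the observed
foraging speed; relaxation 2 s, sd 25% of the mean, floored at zero); the
wall reflects the velocity specularly, and the head centre is kept 0.5 cm
off the wall. Sessions default to 1500 s at 60 Hz in a 15-cm-radius arena.
Realised mean speed lands within a few percent of the target.

**Spiking.** Generation is doubly stochastic -- an event process, then a
burst per event -- precisely because the statistics under test are
burst-level and must be directly controllable. Events are an inhomogeneous
Poisson process (thinning) with Gaussian spatial tuning
(`baseline_event_rate + peak_event_rate * exp(-d^2 / 2 width^2)`; defaults
0.1 Hz, 6 Hz, width 4 cm). An event is a lone spike with probability
`p_single = 0.82`; otherwise a burst with `2 + Geometric(0.18)` spikes
(capped at 10) whose ISIs are gamma with mean `intra_isi_mean` and shape
`intra_isi_shape`, rejection-truncated to (0, 15) ms so that generated
bursts are detectable by the 15-ms criterion. Amplitudes start at `amp0`
and fall by a fixed factor (default 0.8) per spike. The burst-structure
defaults are back-computed from the recorded control cohort's summary
statistics: an intra-burst spike ratio near 32% with 2.2 spikes per burst
forces `p_single ~ 0.82` and `burst_continue ~ 0.18`; with these, a
simulated default cell lands at ~1.3 Hz overall rate, ~0.17 Hz burst
frequency, ~30% intra-burst ratio and in-field rates of 3-4 Hz --
the observed regime. Control-like cells use ISI mean 2.5 ms, shape 4;
mutant-like cells 3.9 ms, shape 3, with between-cell sds of 0.6 and 1.2 ms
(back-computed from the reported group SEMs); the shapes place discretised
ISI-1 entropies near 3.2 and 3.7 bits, reproducing the direction and
rough size of the recorded entropy contrast.

**Cue protocol.** Three sessions with the cue card at 0, +90 (CCW), 0
degrees. A `distal` cell keeps its field; a `local` cell's field rotates
with the card; a `remap` cell's field is redrawn each non-reference
session. The redraw keeps the field's eccentricity (scaled by a factor in
[0.8, 1.25], clamped away from the centre and wall) and moves its azimuth
at least 60 degrees away from both the original and the card-following
position. This is the generator's *definition* of remapping: a remap
whose field happened to land back inside a +/-45-degree cue window would
be indistinguishable from a cue-following cell by any angle-based
classifier, so the generator only produces identifiable remaps. A
consequence worth stating: classification accuracy measured on this
generator speaks to the estimator (rotation search plus windows), not to
the base rate of ambiguous remaps in real recordings, where a remapped
field can land anywhere.

Field centres are drawn at eccentricities of 4-10 cm: fields at the very
centre make rotation angles meaningless, fields at the wall are badly
undersampled.

Not emulated, by design: theta modulation and phase precession, spike
sorting artefacts, multi-unit contamination, electrode drift, head
direction, and any within-session nonstationarity. Passing tests
therefore demonstrate that the estimators recover what the generative
model puts in, at realistic sampling densities -- not that real recordings
satisfy the generative assumptions.

## Problem sizes and numerical conventions

The validation suite uses: 1,000 random trains for the burst-detector
oracle; 60-cell cohorts (20 per cue class, 1500-s sessions) for
classification; a 4500-s session per ISI calibration point (>= 500
detected bursts, recovery within 0.3 ms); 25 replicates of the 28-vs-32
cell group contrast at 600 s per cell plus 25 null replicates; 100
replicates of n = 1000 logistic recovery; and 5 constructed maps for the
full-span regression oracle. The acceptance script re-runs the two-group
study at 900-s sessions with the full metric battery.

Conventions collected in one place: times in seconds, ISIs in
milliseconds, coordinates in cm in the arena-centred frame, angles in
degrees CCW; pixel (i, j) is 0-based and covers the half-open square
`[x0+i, x0+i+1) x [y0+j, y0+j+1)`; correlations are clipped to
`1 - 1e-7` before `atanh`; rate-map ties in the top-quartile field and
angle ties in the rotation search resolve to the smallest index/angle;
all stochastic steps are seeded, and every cohort is byte-reproducible
from its master seed.

## Known limitations

* The rotation search resolves angles only up to the pixel quantisation
  (1-2 degrees for smooth fields at mid-eccentricity; worse for small or
  central fields).
* Burst reliability on clean synthetic cells (low untuned baseline) is
  higher than in recordings; the generator does not model the out-of-field
  spiking that real cells exhibit beyond a constant baseline rate.
* The spatial regression treats pixels as independent observations during
  cross-validation; spatially structured noise would make the selected
  span optimistic.
* `analyze_cell` computes pooled ("all sessions combined") firing
  properties by concatenating sessions on a shifted time axis; the
  inter-session gaps of the real protocol are not represented (one
  inter-spike interval per boundary spans the gap and lands in the
  histogram tail).
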