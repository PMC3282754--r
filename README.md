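# placeburst

Analysis of hippocampal CA1 place-cell recordings from freely foraging
animals in a cylindrical arena — and of what the *temporal structure* of
their spiking (complex-spike bursts) says about how position is encoded.
The package is aimed at in-vivo electrophysiologists comparing groups of
recorded cells (e.g. mutant vs wild-type cohorts) on spatial-firing and
burst-pattern statistics, and at methodologists who need a fully
synthetic, seeded test bed for such analyses.

## What it computes

For each cell-session (spike times + amplitudes, 60-Hz tracking, session
descriptor):

* **Rate maps** on a 1×1 cm arena-centred grid: rate = spikes / dwell per
  pixel, with an occupancy validity mask; **place field** = pixels above
  the cell's overall rate λ̄ (or the top quartile by rate).
* **Spatial battery**: selectivity `log10(in/out field rate)`; coherence
  (Pearson r between each pixel's rate and its 8-neighbour mean, Fisher-Z
  transformed); information rate `I = Σ p(x) λ(x) log₂(λ(x)/λ̄)` bits/s;
  field size.
* **Stability**: pixel-by-pixel cross-session correlation; a 1°-step
  rotation search for the angle of maximal correlation; classification of
  each session pair as **distal-cue**, **local-cue** or **remap** by
  whether the field stayed within a 90° arc of its original or of the
  card-following position; a random-cell-pair chance baseline.
* **Burst battery**: bursts = runs of ≥2 spikes with ISIs ≤ 15 ms and
  progressively decreasing amplitudes; burst frequency, intra-burst spike
  rate, spikes/burst, % spikes in bursts, inter-burst intervals; ISI-k
  (first-to-second spike, etc.) means, SD, CV, histogram peak time and
  Shannon entropy; burst-in-field reliability and burst place-map
  coherence.
* **Models**: locally weighted (tri-cube, degree-1) regression of pixel
  firing rate on position with 10-fold cross-validated span selection and
  percent variance explained `100(1 − σ²_resid/σ²)`; logistic regression
  (hand-rolled IRLS with monotone deviance) of remapping on ISI peak time,
  group and session.
* **Group comparison**: Welch unequal-variance t-tests per metric with
  SEMs, plus a BH-adjusted column.

A calibrated synthetic generator (`simulate_trajectory`,
`simulate_place_cell`, `generate_cohort`) produces random-foraging
trajectories and bursty place-tuned spike trains under three-session
cue-rotation protocols, with distal-following, local-following and
remapping cell types. See `vignettes/placeburst-methods.Rmd` for the
models, calibration and design decisions.

## Worked example

```r
library(placeburst)

co  <- generate_cohort(1, group_params(), cohort_protocol(), master_seed = 42)
res <- analyze_cell(co[[1]]$sessions, cell_id = "cell_01", config = pf_config())
s   <- res$sessions[res$sessions$session_id == 1, ]
```

Session-1 metrics for this simulated control-like cell print as:

```
rate 1.37 Hz | in-field 3.72 Hz | selectivity 1.18 | field 183 px
coherence z 1.31 | information 1.77 bits/s | span 0.05 | pve 80.4%
bursts 326 | freq 0.22 Hz | 35.7% of spikes | ISI-1 2.60 ms | entropy 3.28 bits
```

— a ~1.4-Hz pyramidal-like cell whose in-field rate is ~15× its out-field
rate (selectivity 1.18 log₁₀ units), with about a third of its spikes in
bursts at a 2.6-ms intra-burst interval, and whose position explains 80%
of the pixel-rate variance at the smallest smoothing span. The pairwise
stability table shows why it classifies as distal-cue throughout — the
rotation search finds its field essentially unmoved in all three session
pairs even though the card moved in session 2:

```
 pair         r         z best_angle abs_rotation     max_r cue_class
  1v2 0.7620557 1.0011000         12           12 0.7917570    distal
  1v3 0.7816087 1.0494917          3            3 0.7838517    distal
  2v3 0.7506201 0.9743739          3            3 0.7616258    distal
```

`analyze_cohort()` + `compare_groups()` run the same battery over whole
cohorts; `include_cell()` applies the place-cell inclusion rule
(mean rate > 0.2 Hz and selectivity > 0.5). Thin CLI wrappers live in
`inst/cli/`: `synthgen.R` writes a cohort to disk in the canonical CSV/YAML
layout, `analyze.R` analyses such a directory.

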