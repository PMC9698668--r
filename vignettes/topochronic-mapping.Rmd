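---
title: "Topochronic mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topochronic mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(topochron)
```

This vignette documents the estimation model implemented by `topochron`,
the parameters that matter, the design decisions taken where the
procedure admitted more than one reading, and what the built-in
synthetic cohorts do and do not establish about real data.

## The estimation model

### From time series to avalanches

A subject's input is a regions × samples matrix of source-reconstructed
activity with its sampling rate (Hz). Each regional series is z-scored
over the full recording with the population (n) denominator; a
sub-window normalisation would be equally defensible, but whole-segment
normalisation is the simplest reproducible choice and is what
`zscore_timeseries()` implements. Regions with zero variance are
rejected rather than silently propagated, since a flat channel upstream
is always a data problem.

Activity is discretized at a threshold θ on |z| (default 3, alternates
2.5/3.5 reachable by configuration). The inequality is **strict**
(|z| > θ): both an excursion above +θ and below −θ count. An *event* is
by default the **onset** of an excursion — the first suprathreshold
sample of a contiguous run — so a sustained excursion contributes one
event rather than inflating per-bin event counts; the alternative
occupancy semantics (every suprathreshold bin counts) is available via
`events = "occupancy"` and is the more natural choice for
branching-parameter work, where a bin with ongoing but no new activity
would otherwise have zero events and leave the geometric-mean ratio
undefined.

The sample-resolution raster is binned (default width 3 samples,
widths 1–5 supported; a trailing partial bin is dropped) and a
*neuronal avalanche* is a maximal run of bins with at least one active
region, bounded by empty bins. Runs touching the first or last bin of
the recording are discarded: their start or end is unobservable, so
both their duration and their recruitment delays would be censored.

### Branching parameter and bin-width selection

For an avalanche with event counts `n(1..N)` per bin, the branching
parameter is the geometric mean of successive descendant/ancestor
ratios, and the cohort value is the geometric mean over avalanches.
Single-bin avalanches are excluded (the product is empty), as are
avalanches with a zero-event bin under onset semantics; the number of
avalanches actually used is reported. `select_bin_width()` scans a
candidate set (default 1–5) and returns the width whose cohort σ is
closest to 1 — the critical branching value — breaking ties toward the
smaller (finer) width.

### Delays, velocities, aggregation

Within an avalanche each region is recruited at most once, at its first
activation; for every ordered pair with t_j > t_i a delay
(t_j − t_i)·w/fs seconds is recorded. Simultaneous recruitments yield
no entry: a zero delay is indistinguishable from "both recruited by a
common ancestor" and the averaging rule discards zero entries anyway.
Delays are recorded for **all** recruited pairs, not only structurally
connected ones; the structural mask enters only at the velocity stage,
where v = (L/1000)/delay is computed solely on edges with a direct
tract. Two resolutions are available: recruitment at the bin index
(default; avalanches are defined on the binned raster) or at the raw
first suprathreshold sample within the avalanche window
(`delay_resolution = "sample"`).

Subject matrices average entrywise over the avalanches in which the
pair was observed; group matrices average over the subjects with an
estimate; missingness propagates (an entry absent everywhere stays
absent, never zero). Because tract lengths are undirected, the directed
delay matrix is symmetrised — count-weighted mean of the two
directions — before velocities, correlations or percentile profiles are
computed; `directed = TRUE` disables this. Whether the underlying
published matrices were directed is not determinable from their
description; the count-weighted symmetrisation is the choice that
preserves the per-avalanche sample sizes.

Units are fixed throughout: lengths mm, delays s, velocities m/s, with
the single conversion constant centralised in the package.

### Inference

*Surrogates.* Time-shuffled surrogates permute the frame order within
each avalanche independently, leaving each frame's recruited set — and
hence avalanche size, duration and spatial structure — intact. Pooling
frames across avalanches would destroy exactly the quantities the
surrogate is supposed to preserve. Per-permutation RNG streams are
derived from the root seed by a counter, so ensembles are reproducible
bit-for-bit. The default number of permutations is 1000.

*Empirical p-values* use the add-one estimator
p = (1 + #extreme)/(1 + n_perm), which cannot return 0 and is the
standard conservative convention.

*Lesion test.* The observed statistic is the mean patient-minus-control
delay difference over lesioned records (restricted to complete-coverage
edges — edges with an estimate in every control). The null draws random
subsets of the same size from **all** records by default (the
"ignore the structural information" null); `null_pool = "nonlesioned"`
gives the stricter variant. The alternative is one-sided (lesioned
edges slowed more), with a two-sided option.

*KS comparison.* Two-sample Kolmogorov–Smirnov on per-edge group-mean
delays over the coverage edges by default; percentile-profile
aggregation is available for display-matched comparisons.

*Convergence.* For random subject orderings, the mean absolute change
of the group matrix when the x-th subject is added, over the edges
present in both cumulative aggregates, summarised by the median across
orderings. The testable footprint of "convergence" is a strongly
monotone decreasing trend (rank correlation with x near −1) with a
final value a small fraction of the initial one; per-step strict
monotonicity is not a meaningful criterion because late increments are
O(1/x²) and fall below Monte-Carlo noise.

## The synthetic cohort generator

The generator exists so that every stage — detection, delay extraction,
velocity estimation, inference — can be validated against known ground
truth. Its defaults are fixed study conditions, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `n_regions` | 60 | cortical parcellation size class |
| `edge_density` | 0.1 | probability of a direct tract per pair |
| `meanlog`, `sdlog` | log 70, 0.55 | log-normal tract lengths (mm): fat-tailed, median 70 mm |
| `a`, `b` | 0.18, 0.8 | velocity law v = a·L^b (m/s) |
| `p_t` | 0.12 | per-edge transmission probability |
| `n_avalanches` | 500 | cascades per subject |
| `fs`, `bin_width` | 1024 Hz, 1 | native sampling rate and scheduling bin |
| `noise_sd` | 1 | background noise SD |
| cohort | 20 controls, 18 patients | study design |

Choices that deserve justification:

* **Velocity law.** b interpolates between the constant-velocity null
  (b = 0) and the homogeneous-delay regime (b = 1); b = 0.8 encodes
  "longer tracts conduct faster". With a = 0.18 the ground-truth delays
  span roughly 10–18 samples at 1024 Hz, so they are resolvable at
  sample/bin quantisation — a generator whose delays all round to one
  bin could not validate anything.
* **Transmission probability.** With mean degree ≈ 6, p_t = 0.12 gives
  a subcritical cascade (mean offspring ≈ 0.7): recruitment is
  predominantly first-neighbour, so direct-edge delay estimates are
  minimally confounded by network first-arrival shortcuts, while
  cascades remain large enough that the complete-coverage edge set over
  20 controls is non-empty and group matrices converge. Explosive
  regimes (offspring well above 1) make every measured delay a
  shortest-path difference: the length–delay signal washes out and the
  fitted exponent drifts toward 1.
* **Cascade model.** A cascade starts at a uniformly random seed
  region; an activation at bin t attempts each structural neighbour
  independently with probability p_t, scheduling recruitment after the
  edge's rounded bin delay; a region is recruited once, by the earliest
  arrival. This first-arrival/single-recruitment semantics mirrors the
  single-onset delay definition of the estimator. Edges whose delay
  rounds to zero bins are refused (they would create instantaneous
  loops); cascades outlasting the horizon are discarded.
* **Lesions** multiply the *delay* (not the length) of a random edge
  fraction, consistent with analysing delays rather than patient length
  estimates, and ground-truth velocities are updated so
  delay·velocity = length/1000 always holds.
* **Continuous series.** Each recruited region holds a suprathreshold
  excursion from its recruitment bin to the cascade's last bin, with
  random sign, on Gaussian background noise. Single-sample pulses at
  each recruitment would leave empty bins inside a cascade and the
  segmentation (maximal non-empty run) would split it, so sustained
  excursions are required for the detection round trip to be exact;
  they contribute exactly one onset each, so delay extraction is
  unaffected. Inter-cascade gaps (≥ 4 empty bins, also padding the
  recording ends so no cascade is boundary-discarded) are stretched so
  no region's duty cycle exceeds 1/(1 + (θ + 2.5)²), and excursion
  amplitudes are scaled per region so that after z-scoring pulses sit
  comfortably above θ while background noise sits an order of magnitude
  below it.

**False-positive budget.** After z-scoring, background noise in a
region *with* pulses has standard deviation ≈ 0.1 in z units, so
spurious threshold crossings are practically impossible. A region with
*no* pulses at all, however, is renormalised to unit variance and
crosses |z| > 3 at ≈ 2.7 × 10⁻³ per sample regardless of the generator's
noise amplitude — an unavoidable property of z-scoring, not of the
generator. Such regions produce single-region excursions that
contribute no delays but can appear as (small) avalanches; realistic
configurations recruit every region somewhere, making this a corner
case.

**What the generator does not emulate:** volume conduction and source
leakage, oscillatory background structure (the noise is white),
neural-mass dynamics, distance-dependent connection probability, or
measurement-referenced tract-length error. Passing tests on synthetic
cohorts therefore demonstrates correctness of the estimator and its
inference under the stated generative assumptions — not that real MEG
avalanches satisfy those assumptions.

## Numerical choices and degenerate inputs

* Strict threshold inequality; exact boundary values are not events.
* Decimation is integer-only (keep every k-th sample) and assumes
  anti-alias filtering happened upstream in the acquisition pipeline;
  non-integer ratios are refused with advice to resample upstream.
* Equal-count percentile bins are formed by sorting edge lengths and
  chunking (bin of rank r is ⌈r·n_bins/n⌉); ties in length follow sort
  order. Default 100 bins; profiles refuse inputs with fewer edges than
  bins.
* Degenerate correlations (zero variance on either margin) return
  r = 0, p = 1 rather than NA: no detectable association.
* Avalanche-size filters are interpreted in **bins** (the published
  descriptions mix "samples" and "bins"; the unit is exposed in the
  configuration so either reading is reachable).
* Subject failures inside `run_pipeline()` are isolated and logged, not
  fatal; cohort statistics require at least one surviving subject per
  group compared.

## Problem sizes used by the test suite

The suite validates oracle equivalence on 100 random small rasters
(≤ 10 regions, ≤ 50 bins), ground-truth recovery on 20 deterministic
20-region connectomes, exponent recovery and the surrogate null on a
60-region cohort with 4 × 500 cascades and 199 permutations, lesion
power and calibration on a 20 + 18 cohort with 200 cascades per subject
and 500 calibration replicates, and convergence on 40 subjects with 500
cascades each — sizes chosen so each property is tested at meaningful
scale while the whole suite runs in well under a minute of simulation
time per block.

## Known limitations

* Delay estimates conflate direct and indirect propagation; in densely
  recruiting regimes the measured delay is a first-arrival (network)
  quantity, not a single-tract conduction time. This is inherent to the
  estimator, and the reason the synthetic default regime is subcritical.
* Bin-resolution delays quantise at w/fs seconds; sample resolution
  mitigates but cannot remove discretisation.
* The branching parameter under onset semantics is undefined for
  avalanches containing a zero-event bin; occupancy semantics avoids
  this at the cost of duration-weighting sustained excursions.
* No per-edge multiple-testing machinery is provided: the inferential
  targets are pooled statistics (correlation, distribution shift, mean
  lesioned-edge difference), not edge-wise significance maps.
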