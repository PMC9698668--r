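# topochron

Topochronic mapping of functional transmission delays in brain networks.

Large-scale brain activity propagates along white-matter tracts with
finite conduction delays. `topochron` estimates those delays *per edge*
from the spontaneous, intermittent bursts of activity known as **neuronal
avalanches** in source-reconstructed MEG/EEG time series, and combines
them with tractography-derived tract lengths to obtain per-edge
**conduction velocities** — a joint spatial/temporal ("topochronic") map
of signal propagation. It is aimed at researchers in electrophysiology
and connectomics who have regional time series and a structural
connectome for the same subjects, including clinical comparisons where
demyelination (e.g. multiple sclerosis) is expected to slow conduction
along lesioned tracts.

## The method

1. **Avalanche detection.** Each regional series is z-scored and
   discretized: a region is active when |z| > θ (default θ = 3; 2.5 and
   3.5 as alternates), with both polarities counting. The raster is
   binned (default 3 samples; widths 1–5 supported) and a neuronal
   avalanche is a maximal run of bins in which at least one region is
   active, bounded by empty bins.

2. **Branching parameter.** For avalanche *i* with event counts
   n(j) per bin,

       σᵢ = ∏ⱼ₌₁^{N−1} ( n(j+1) / n(j) )^{1/(N−1)},     σ = ( ∏ᵢ σᵢ )^{1/N_aval}

   σ ≈ 1 indicates near-critical dynamics; `select_bin_width()` picks the
   bin width whose σ is closest to 1.

3. **Delays and velocities.** Within an avalanche, the delay from region
   i to region j is the time from i's first activation to j's first
   activation. Entries are averaged over the avalanches in which each
   ordered pair was observed (missing entries are discarded, never
   treated as zero), over subjects for group matrices, and divided into
   the tract lengths — v = (L/1000)/delay, in m/s — only where a direct
   structural connection exists.

4. **Inference.** Time-shuffled surrogates (frame order permuted within
   each avalanche, recruited sets preserved) give the null for the
   length–delay correlation; a two-sample KS test compares patient and
   control delay distributions; a permutation test asks whether delays on
   structurally lesioned edges slowed more than a random subset of edges
   would; a convergence analysis tracks the stability of the group matrix
   as subjects accumulate.

5. **Synthetic ground truth.** A built-in generator draws connectomes
   with fat-tailed (log-normal) tract lengths, assigns velocities by a
   power law v = a·L^b, simulates cascades that spread along structural
   edges with per-edge delays (first arrival wins), embeds them in noise
   as continuous time series, and can slow a random fraction of edges in
   "patients" — so every stage of the pipeline is testable against known
   ground truth.

## Worked example

```r
library(topochron)

# ground-truthed synthetic subject: 20 regions, 100 cascades on a delayed connectome
p  <- cascade_params(n_regions = 20, edge_density = 0.25, n_avalanches = 100,
                     seed = 42)
gt <- assign_velocities(synth_connectome(p), a = p$a, b = p$b)
ts <- synthesize_timeseries(simulate_cascades(gt, p), p)

fit <- topochron(ts, lengths = gt$lengths, bin_width = 1, events = "occupancy")
summary(fit)
```

```
Avalanches: 100 (boundary-discarded 0, single-bin 60)
Branching parameter sigma: 1.052
Delay quantiles (s):
    5%    50%    95%
0.0107 0.0178 0.0391
Velocity quantiles (m/s):
  5%  50%  95%
2.27 3.77 9.25
Length-delay Spearman r = 0.492 (p = 0.00145, n = 39 edges)
```

All 100 simulated cascades are re-detected from the continuous series; σ
near 1 reflects near-critical spreading; delays are tens of ms and
velocities a few m/s on this small connectome, and longer tracts carry
longer delays (positive Spearman r) though far less than proportionally —
the signature of faster conduction on longer tracts. `coef(fit)` returns
the per-edge table (delay, count, length, velocity), `plot(fit)` the
length–delay scatter with percentile trend and constant-velocity
reference curves, and `simulate(fit)` time-shuffled surrogate delay
matrices.

Cohort-level analysis runs from an on-disk bundle (or
`inst/scripts/topochron.R simulate | run` from a shell):

```r
co  <- make_cohort(cascade_params(seed = 1), n_controls = 20, n_patients = 18,
                   lesion = list(fraction = 0.2, slowdown = 1.5),
                   timeseries = TRUE, dir = "cohort")
res <- run_pipeline("cohort", run_config(fs = 1024, bin_width = 1, n_perm = 1000))
report(res, "results")
```

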