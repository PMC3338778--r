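---
title: "Motility, adhesion and expression analytics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motility, adhesion and expression analytics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motanlage)
```

This vignette documents the models behind the package, the parameters
that matter, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The biological setting

Limb muscles form from migratory muscle progenitors (MMPs) that
delaminate from the dermomyotome and travel into the limb bud. In
Pitx2-mutant embryos these cells migrate poorly: they cover roughly half
the wild-type distance in a 2-hour recording, pause about half the time,
carry fewer but larger focal adhesions, and mis-express a panel of
actin-, microtubule- and adhesion-related genes. The package implements
the quantitative assays behind those statements as reusable, tested
components, and replaces the unavailable raw data (microscopy stacks,
flow cytometry files, array CEL files) with simulators whose ground
truth is known.

## Track simulator

A cell is a two-state Markov chain over 5-minute intervals: *moving*
with per-interval escape probability `p_move_to_pause`, *paused* with
escape probability `p_pause_to_move`. The initial state is drawn from
the chain's stationary distribution, so short recordings are not biased
toward either state. While moving, the cell steps a distance
`speed * dt` (speed truncated-normal, `speed_mean`, `speed_sd`) along a
heading that deviates from the previous moving heading by a von Mises
angle with concentration `turn_kappa`; `turn_kappa = 0` is an
uncorrelated walk and large values are near-ballistic. The heading is
frozen across pauses. Paused intervals receive isotropic Gaussian jitter
(default SD 0.1 µm per axis) emulating centroid noise, so the
moving/paused classifier is exercised against a realistic floor rather
than exact zeros.

Defaults mirror the recorded world: 25 samples at `dt = 5` min (2 h).
The printed time budgets of the source assay sum to 124–125 min although
25 samples span 120; the package enforces exact `(n−1)·dt` budgets and
treats the printed values as having an unknowable inclusive-counting
convention.

**Presets.** `preset_params()` returns per-genotype constants frozen by
`scripts/calibrate_presets.R`. Switching probabilities are set
analytically from the published moving fraction (e.g. WT 92/124 of time
moving); the moving speed is then tuned by fixed-point iteration on
large simulated cohorts so that the realised mean total distance —
including the small path-length contribution of pause jitter and speed
truncation — matches the published mean (WT 53, HET 74, MUT 23 µm).
`turn_kappa` (WT/MUT 0.8, HET 1.6) encodes the qualitative observation
that heterozygote cells turn less; no printed number constrains it. The
acceptance suite verifies that 500 five-cell cohorts per genotype give
median cohort means within ±2 printed SEM of distance, velocity and both
time budgets. Cells within a genotype are i.i.d. draws from one
parameter set: the source data report no cell-level parameter
heterogeneity, so none is modelled.

## Track metrics

* Total path `T`, net displacement `D`, and `D/T`; `D/T` is undefined
  (excluded from group means, with the exclusion counted) when `T = 0`.
* Pause criterion: interval displacement < 1.0 µm per 5-min interval
  (0.2 µm/min). The source assay never states its criterion; this value
  sits at the mutant mean speed and above the jitter floor, and is
  configurable.
* Velocity defaults to `T / total observation time`: WT 53 µm / 120 min
  ≈ 0.44 µm/min is consistent with the printed 0.5 ± 0.1. Per-moving-
  time is available (53/92 ≈ 0.58 also fits within SEM); the printed
  convention is ambiguous and both are kept.
* Direction changes: heading changes above 45° between consecutive
  moving steps, reported descriptively only.

## MSD analysis

`displacement_msd()` is the standard time-averaged ensemble MSD;
`path_squared_curve()` is the literal squared-cumulative-path variant
(`T²`) that the source assay's wording describes. The wording conflicts
with the displacement-based method it cites, so both are implemented and
neither is privileged: displacement is the default, the path variant
sits behind the CLI's `--msd-mode path`.

The x-intercept of the ordinary least-squares line through the curve at
lags 20, 40, …, 120 min (matching the "measured every 20 min" design) is
the randomness diagnostic: `|x-intercept| ≤ tol` (default 10 min) is
consistent with an uncorrelated walk. The diagnostic's null calibration
is checked on cohorts of 100 isotropic-walk tracks: with 5-track
cohorts the intercept estimate is dominated by regression noise (six lag
points, the longest estimated from one window per track), so a failed
5-cell diagnostic reflects sampling noise, not directional motion — a
real limitation of the assay at the published cohort size, and the
reason the calibration is stated at a size where the curve itself is
estimable. For the closed-form comparison (`MSD = 2σ²k` for an
isotropic walk with per-axis step variance σ²), 49-point tracks are
used so every default lag is averaged over multiple windows.

The Fürth persistent-random-walk model
`MSD(τ) = 2S²P[τ − P(1 − e^{−τ/P})]` is fitted by least squares on
`log(S), log(P)` from 8 deterministic multi-starts (Nelder-Mead, then a
quasi-Newton polish; ties broken by lowest residual then lowest `P`).
A fit with `P ≥ max(τ)` is flagged ballistic — the lag window cannot
resolve the crossover. For simulator tracks the mapping between the
discrete correlated walk and the continuous model is
`S = speed_mean`, `P = dt(1 + ρ)/(2(1 − ρ))` with
`ρ = I₁(κ)/I₀(κ)` (`vm_mean_resultant()`); the acceptance suite recovers
`S` within 10% and `P` within 25% at κ = 4 (ρ ≈ 0.86, P ≈ 34 min),
a regime where the track span (120 min) still resolves the crossover.

## Group statistics

`t_test()` is the classical pooled-variance two-tailed Student test
(Welch behind a flag), with the convention p = 1 for identical
zero-variance samples. `t_test_from_summary()` computes the same
statistic from printed `(n, mean, SEM)` triples and is algebraically
identical to the raw-data test — this is how published p-values from
mean ± SEM figures are checked (e.g. the distance contrast
53 ± 4 vs 23 ± 1 at n = 5 gives t ≈ 7.28, p ≈ 9 × 10⁻⁵, consistent with
a printed "p = 0.0001" read as floor-rounded display, not an exact
value).

`dunnett()` performs many-to-one comparisons with a pooled variance
across all groups. Rather than interpolating classical tables, adjusted
p-values and critical values are obtained by seeded Monte Carlo of the
joint null of the correlated t statistics (default 10⁵ draws), which
covers unbalanced designs uniformly; a guard enforces
adjusted ≥ unadjusted per contrast against Monte-Carlo noise in the
degenerate single-contrast case. Familywise error control is verified by
simulation in the acceptance suite (3 groups of 5, 2,000 null
replicates, target window 0.035–0.065 at α = 0.05).

## Focal-adhesion quantification

The source counts were manual; the package substitutes a reproducible
pipeline. `render_puncta_image()` draws each punctum as an isotropic
Gaussian of SD `psf_sigma_um` with integrated intensity proportional to
area; `detect_puncta()` applies an absolute threshold (adaptive
thresholding deliberately avoided for reproducibility), 8-connected
component labelling, and a minimum-area filter, returning
intensity-weighted centroids and pixel areas. Detection is exact on
noiseless scenes when spots are separated by more than ~4 PSF sigmas and
above threshold — the regime the round-trip tests use.

Leading/trailing assignment is projection onto an explicit polarity
axis: strictly positive → leading, with exact zeros assigned trailing as
a deterministic tie rule. How the source study delineated the edges
operationally is unstated, so the axis is an input, not an inference.
"Size" is reported as equivalent diameter `√(4·area/π)` — the published
2.14–3.15 µm values are lengths, not areas — with nascent (< 1 µm) and
mature (2–10 µm) classes. Display rounding is half-away-from-zero,
matching the published per-cell means (475 puncta over 18 cells → 26.4 →
"26").

## Expression fold table

The signed fold convention (`MUT/WT` for increases, `−WT/MUT` for
decreases) is inferred: it reproduces the printed column (256/44 → 5.8;
632/293 → −2.2). The HET column is carried but unused by the fold. The
two-of-three replicate filter is a reconstruction of a footnote that
gives no criterion: replicate *i* is flagged when
`|vᵢ − median| > f_max · max(median, ε)` with `f_max = 0.5` exposed in
the interface; at most one replicate is dropped. Reconstructed folds
from the printed means match the printed column for 34 of 38 genes; the
four mismatches (including two the source likely recomputed on two
arrays after filtering) are reported by the tests as observations, not
corrected.

## Cell populations

`percent_positive()` is exact arithmetic on gated counts (no FCS
parsing, no compensation — out of scope). DNA-content histograms are a
three-component mixture: Gaussian G1 at the 2N position, Gaussian G2
constrained to 1.9–2.1 × the G1 mean with the same coefficient of
variation, and an S-phase plateau of cells replicating between the
peaks, broadened by the same CV — the simplest shape consistent with
such histograms. `estimate_phase_fractions()` fits this model to the
binned counts by least squares (Nelder-Mead on log/logit-transformed
parameters; mixture weights through a softmax so estimates always lie in
the simplex; G1 mean initialised at the dominant mode; the S component
integrated by 32-point midpoint quadrature). Because the fitted model is
the generating model, recovery within ±0.03 at 50,000 cells validates
the estimator's implementation, not its robustness to real-world
artefacts (debris, doublets, non-Gaussian peaks), which are out of
scope. The published SEMs of the phase fractions mix units ("±0.007%"
against a 69% mean); the package reports SEM in percentage points and
does not attempt to match them.

## What a green test establishes — and what it does not

The generators reproduce the *stated* world: published group means,
sample sizes, and printed tables. They do not emulate photobleaching,
illumination drift, 3-D motion, track splitting at division, adhesion
turnover, array normalisation, or flow-cytometry artefacts. Green
acceptance therefore establishes that the pipeline's arithmetic,
statistics and estimators are correct and calibrated on data matching
the published summaries — not that the source study's biological
conclusions re-derive from raw data, which were never deposited for the
motility assays.

## Numerical conventions

* Every generator is a pure function of (specification, seed); RNG state
  is restored after each call.
* Display rounding is half-away-from-zero (`round_half_away()`), the
  convention of the published tables; internal values are never rounded.
* Undefined quantities (`D/T` at `T = 0`, per-moving-time velocity with
  no moving interval, x-intercept at zero slope, SEM at n = 1) are `NA`
  with documented exclusion or warning, never imputed.
* Degenerate inputs fail fast with messages naming the offending field.
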