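---
title: "Detecting circadian oscillations in qPCR time courses: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian oscillations in qPCR time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(antclock)
library(dplyr)
```

`antclock` turns raw qPCR threshold-cycle (Ct) measurements from a
light:dark time course into per-gene oscillation calls, the analysis used to
characterize the molecular circadian clock of the fire ant brain. This
vignette explains the models the package implements, the tunable parameters
and their defaults, and the design choices made where the procedure was
genuinely open.

## From Ct to relative expression

A qPCR reaction reports the cycle number at which fluorescence crosses a
threshold; each earlier cycle means roughly twice as much starting template.
Quantification therefore works on differences of Ct values:

* **ΔCt** — for each (colony, timepoint) cell, the mean Ct of the target
  gene across technical replicates minus the mean Ct of the reference
  gene (EF1α, a housekeeping gene assumed temporally flat) in the same
  cell. Replicates are averaged, never dropped: the triplicate design has
  no stated outlier-rejection rule, and silently discarding reactions
  would bias low-replicate cells.
* **ΔΔCt** — ΔCt minus a calibrator. The default calibrator is each
  series' own across-time mean (`mean_over_time`), so expression is
  measured as deviation around the gene's daily average — the natural
  choice when the quantity of interest is the *shape* of the daily
  profile rather than fold change relative to a specific hour. The
  alternative `first_timepoint` calibrator is available for designs with
  a meaningful baseline sample.
* **Fold change** — 2^(−ΔΔCt). With the mean calibrator, the geometric
  mean of the folds in a series is exactly 1.
* **z-scores** — each (gene, colony) series is standardized to mean 0 and
  unit *sample* standard deviation (n − 1 denominator throughout the
  package). Standardization is applied to −ΔΔCt, i.e. to log2 relative
  expression, not to the fold change itself: an oscillation that is
  sinusoidal on the Ct scale (the scale on which PCR physics is additive)
  stays exactly sinusoidal on the log scale, whereas exponentiation would
  distort it. Z-scoring per colony removes colony baseline differences
  before cross-colony averaging, so the aggregate reflects shared
  temporal structure rather than between-colony level differences.

Missing (colony, timepoint) cells are an error, never imputed: with only
seven timepoints per day a silently imputed cell would contribute a seventh
of the rhythm evidence.

## The cosinor model

Rhythmicity is assessed against the single-component cosinor

$$ y(t) = M + A\,\cos\!\big(2\pi (t - \varphi)/\tau\big), $$

with mesor $M$, amplitude $A \ge 0$, acrophase $\varphi \in [0, 24)$ (the
hour of peak), and the period fixed at $\tau = 24$ h — the appropriate
constraint for animals entrained to a 12:12 light:dark cycle, where the
question is *whether* expression tracks the 24-h day, not what the
free-running period is. Free-period fits, multi-component cosinors and
nonparametric rhythm statistics are out of scope.

Two fitting routes are provided and deliberately kept independent:

* **`cosinor_ls()`** — the closed-form optimum. Because the period is
  fixed, the model is linear in $(M, A\cos\hat\varphi, A\sin\hat\varphi)$
  and ordinary least squares on $\{1, \cos\omega t, \sin\omega t\}$ gives
  the exact solution: $A = \sqrt{\beta_c^2 + \beta_s^2}$,
  $\varphi = \operatorname{atan2}(\beta_s, \beta_c)/\omega$.
* **`cosinor_mc()`** — Monte-Carlo random search: `n_sims` parameter
  triples drawn uniformly from a data-driven box ($M$ within the data
  range, $A$ up to the data span, $\varphi$ over the full day — a box
  guaranteed to contain the least-squares optimum), each candidate scored
  by its R² against the series, and the `top_k` best aggregated.
  Deterministic given its seed. Defaults are desk-scale `n_sims = 1e5`,
  `top_k = 400`; the historical 1e7-simulation effort is a parameter away.

### Why the top-k aggregation refits

The top-k candidates are averaged with arithmetic means for $M$ and $A$ and
a circular mean for $\varphi$ (phases live on a circle; averaging 23 h and
1 h must give 0 h, not 12 h). For the *reported R²*, two conventions are
plausible, and they differ materially at desk scale. Averaging the top-400
candidate R² values directly describes a neighbourhood of the optimum, not
the optimum: the best 0.4 % of a three-dimensional uniform box is still a
sizeable ellipsoid, and the resulting R² sits ~0.05 below the least-squares
value at `n_sims = 1e5` (the gap only closes, to a few thousandths, at 1e7
draws). The default therefore evaluates the R² of the curve built from the
averaged parameters (`r2_aggregation = "refit"`), which is centred on the
optimum and converges quickly; the literal mean of candidate R² values
remains available as `r2_aggregation = "mean"` for comparability with the
large-`n_sims` convention.

### Adjusted R², peaks and amplitudes

`adjusted_r2()` applies $1 - (1 - R^2)(n-1)/(n-k-1)$ with $k = 2$ — the
cosine and sine regressors, intercept excluded. With $n = 7$ timepoints
this choice reproduces every cleanly printed R² → adjusted-R² pair in the
published per-gene table (0.86 → 0.79, 0.66 → 0.49, 0.46 → 0.19), which is
how the convention was pinned down. Adjusted R² is negative whenever
$R^2 < k/(n-1)$, i.e. below ≈ 0.33 at this design size.

The reported peak-to-trough amplitude is $2A$ (exact for the fixed-period
cosine). Peak time is reported both continuously ($\varphi$ mod 24) and
snapped to the nearest sampled ZT in circular distance, ties resolved
toward the earlier hour; a flat fit ($A = 0$) has no peak and is flagged
missing rather than defaulted.

### Significance of the fit

The original analysis computed cosine-fit p-values in unspecified software,
so the package defines its own test and states it: a permutation test that
shuffles the series over its own timepoints `n_perm` times, refits by least
squares, and reports $p = (1 + \#\{R^2_{perm} \ge R^2_{obs}\})/(n_{perm}+1)$.
The +1 convention keeps the test valid (p can never be 0) and the
comparison includes ties, so the test is exact-conservative; its measured
type-I error at α = 0.05 over 1000 flat-noise series sits at the nominal
level (see the acceptance script). With 7 points there are only 5040
distinct arrangements, so the resolution floor of the p-value is about
2 × 10⁻⁴ regardless of `n_perm`.

## ANOVA and the oscillation call

Independently of the cosinor, each gene is tested with an additive two-way
ANOVA, `value ~ timepoint + colony`, on the per-colony z-scores (one value
per cell; with no within-cell replication the interaction is not estimable
and the residual has $(T-1)(C-1)$ df). The timepoint effect asks whether
expression differs over the day at all, without assuming a sinusoidal
shape.

A gene is called rhythmic by the compound rule in `classify_oscillation()`:

* `p_only` (default): ANOVA timepoint p ≤ 0.05 **and** cosine-fit
  p ≤ 0.05.
* `strict`: additionally adjusted R² ≥ 0.5.

Both rules ship because the published record is internally inconsistent:
the stated criterion includes the variance-explained cutoff, yet the
gene list actually presented as significant includes a gene with adjusted
R² = 0.49. `p_only` reproduces that four-gene list; `strict` yields three.
The package exposes the choice instead of resolving the contradiction. No
multiple-testing correction is applied across genes, matching the original
analysis of eight candidate genes.

`summarize_rhythms()` additionally flags genes whose per-colony fits
disagree in peak phase by more than 6 h (circular distance) as not
consistent across colonies. The 6-h threshold — a quarter cycle — is this
package's operationalization of a qualitative footnote; it is a parameter
(`phase_tol`).

## The synthetic-data generator

No raw Ct measurements were deposited for the original time courses, so
`simulate_qpcr()` generates datasets with the study's structure and known
ground truth:

$$ Ct = \text{baseline} + \text{colony offset} - A_{ct}\cos\!\big(2\pi(t-\varphi)/24\big) + \varepsilon $$

The cosine enters with a minus sign (lower Ct = more template), so
expression 2^(−ΔΔCt) oscillates with the specified acrophase; one Ct unit
of amplitude is a two-fold peak-to-trough expression change. Defaults
encode the study geometry: 3 colonies, 7 timepoints every 4 h
(ZT 2–26), triplicate reactions, a flat EF1α reference. Where the original
study reports no value the generator fixes a realistic one: Gaussian
replicate noise of 0.25 Ct (typical TaqMan technical-replicate scatter),
per-(gene, colony) baseline offsets of 0.5 Ct, oscillator amplitudes of
1–1.2 Ct (matching the 2–3-fold peak-to-trough changes reported), and a
panel of four true oscillators (per/cry-m peaking at ZT 18, cwo/cyc
anti-phase at ZT 6) plus four arrhythmic genes. The ZT grid
{2, 6, …, 26} follows from "7 timepoints every 4 hours" with reported
peaks on even hours 6 and 18; note its first and last points duplicate a
phase (ZT 2 ≡ 26), which the fitting code tolerates.

What the simulator does **not** model: amplification failure/dropout, PCR
efficiency differences between genes (no Pfaffl correction is implemented,
so the generator assumes perfect doubling), pooling variance across the 12
individuals per sample, or non-sinusoidal waveforms. Passing tests on this
synthetic ground truth therefore demonstrate that the statistical pipeline
recovers what it assumes — sinusoidal signal in Gaussian noise — not that
real brains behave this way.

## Protein-domain conservation

The gene-model side of the analysis is a pairwise comparison:
`global_align()` computes a Needleman–Wunsch global alignment with affine
gap penalties (BLOSUM62, gap open 10, extend 0.5 — the defaults of the
standard global-alignment web tool, since no parameters were recorded; a
gap of length L costs open + extend·L). Identity is the percentage of
alignment columns with identical residues and similarity the percentage
with a positive substitution score, both over the full alignment length
*including* gap columns — conventions that are tool-specific and therefore
stated. `domain_conserved()` applies the ≥ 40 % identity rule (inclusive at
the boundary), and `window_conservation()` counts identical sites in an
aligned window for "similar at x/n sites" statements, with gap columns
counting toward the window length but never toward identity. Domain
coordinates are 1-based inclusive. Multiple alignment, domain-database
searches and tree building are out of scope.

## Numerical choices and degenerate inputs

* Constant series: standardization returns zeros with a warning; the
  cosinor returns A = 0, R² = 0, undefined acrophase, with a warning;
  the permutation p is 1.
* A cosinor fit requires ≥ 4 points and ≥ 3 distinct timepoints mod 24;
  collinear designs are an error.
* All randomness (simulation, Monte-Carlo search, permutations) flows
  from explicit integer seeds; `fit_rhythms()` derives a deterministic
  sub-seed per series from the master seed and the series' rank in sorted
  order, so results are invariant to row order.
* ZT values ≥ 24 are allowed (multi-day designs) and reduced mod 24 only
  for phase arithmetic.
* Permutation and classification thresholds compare inclusively
  (p ≤ 0.05, identity ≥ 40 %), matching the stated rules.

## Problem sizes used in the shipped checks

The package's own verification runs at sizes a laptop handles in about a
minute: Monte-Carlo/least-squares agreement on 50 seeded series at
`n_sims = 1e5`, `top_k = 400`; oscillation-recovery operating
characteristics on 200 simulated study-geometry datasets with 199
permutations per gene; permutation-test calibration on 1000 flat-noise
series; alignment checks against a dynamic-programming oracle on 200 random
short sequence pairs. `scripts/acceptance.R` re-runs all of these from
scratch at a user-chosen seed.

## Known limitations

* The ΔΔCt model assumes equal amplification efficiency for target and
  reference; no standard-curve or multi-reference normalization.
* With 7 timepoints the cosinor has 4 residual df: adjusted R² is a
  coarse instrument, and the permutation p-value has a hard resolution
  floor.
* The LD design cannot separate endogenous rhythmicity from light-driven
  expression; the statistics here detect 24-h structure, not its cause.
* The consistency flag compares per-colony least-squares acrophases only;
  a colony with a flat (peakless) fit is ignored by the flag.
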