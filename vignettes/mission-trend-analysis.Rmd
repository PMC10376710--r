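---
title: "Spectral trend classification of mission biomarker panels: models and design choices"
author: "missionTrends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral trend classification of mission biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missionTrends)
```

# The problem and the data model

Long-duration mission monitoring produces, per subject, a few hundred
biomarker series (blood and urine chemistry, immune cell fractions,
physiological measurements) sampled at heterogeneous, subject-specific
times. Deidentification and cross-subject comparability both argue for a
common grid, so every series is collapsed to at most eight bins: two
pre-flight (−180, −45 d), three in-flight (33, 82, 132 d), return (165 d)
and two post-return (195, 225 d). Each bin value is the arithmetic mean of
the raw records falling in the bin's half-open day interval; repeated
assays within a bin are averaged. The bin boundaries are the midpoints
between adjacent bin labels, extended to −200 and +240 d at the ends — the
grid only fixes the labels, so the boundary placement is a package choice,
and it is configurable in `missionGrid()`.

The working object is a `MissionExperiment` (a `SummarizedExperiment` with
one row per subject × measurement series and one column per bin), which
accumulates assays and per-series metadata as the stages run.

Two preprocessing rules matter downstream:

* **Filtering.** A series is kept only if its −45 d baseline bin is present
  and at least 5 of 8 bins are present (`minBins`, configurable). No
  imputation is performed anywhere; the spectral machinery tolerates
  missing bins natively. The threshold is a documented default — the
  appropriate value depends on how sparse real panels are.
* **Normalization.** Kept series are differenced against the baseline bin
  and scaled to unit Euclidean norm over their present bins. A series equal
  to its baseline everywhere has zero norm; it is flagged *degenerate* and
  excluded from classification and the network rather than divided by zero.
  Degenerate series are reported in the drop log, since in noise-free
  simulated data they are the rule, not the exception.

# Spectral classification

## The estimator

For each kept series the classical Lomb–Scargle periodogram is evaluated
over the observed bins: at each frequency the power equals half the
residual-sum-of-squares reduction of a least-squares sinusoid fit to the
mean-centered values, computed in closed form via the phase-shift (τ)
formulation. Autocorrelations are the normalized inverse Fourier transform
of the power,

$$\rho_l \;=\; \frac{\sum_k P_k \cos(2\pi f_k\, l\, d)}{\sum_k P_k},$$

with lag unit $d$ = one grid step and $l = 0,\dots,\lfloor N/2\rfloor$.
This estimator has three properties the tests rely on: $\rho_0 = 1$
exactly; $|\rho_l| \le 1$ whenever the power is nonnegative; and on a
complete, evenly sampled window evaluated at the *natural* frequencies
$f_k = k/(Nd)$ it reproduces the circular lagged-product autocorrelation of
the centered series to machine precision (the discrete Wiener–Khinchin
pairing). The oracle tests exercise exactly that configuration.

## Two deliberate grid choices

**Grid-step time.** Spectra are computed with bins at index positions
0…N−1, not at their day labels. Lags are defined in grid steps, and the
mission grid's day spacing is strongly uneven (a 135 d pre-flight gap
against ~30 d flight gaps); evaluated in day time, that unevenness
scatters the power of a smooth monotone trend into mid frequencies whose
lag-1 cosine weights are negative, and the lag-1 autocorrelation of a clean
in-flight rise drops from +0.51 to −0.11 — destroying the class structure
the analysis is built on. Lomb–Scargle still earns its keep: series with
missing bins are uneven subsets of the index grid.

**Frequency range.** The run-level grid is $f_k = k/(2\,\mathrm{span})$ for
$k = 1,\dots,4\lfloor N/2\rfloor$: it starts at half a cycle per window,
where the power of slow monotone trends lives, and is oversampled fourfold.
The natural grid (`oversampling = NULL`) is retained for verification, but
it resolves trend classes poorly on 8-point windows because it cannot see
below one cycle per window.

## The bootstrap null and what "significant" means

The null model resamples, with replacement, the pooled present normalized
values of one subject (across that subject's measurements and bins) onto
the full grid — 10⁵ series by default. Per-lag 0.95 quantiles of the null
autocorrelations give the lag thresholds; the 0.95 quantile of null maxima
and the 0.05 quantile of null minima give the spike thresholds (the minima
test must be lower-tailed for a low extremum to be a rare event). A series
is assigned Lag *M* at the smallest lag whose autocorrelation meets or
exceeds its threshold (ties count as exceedance); only lag failures are
spike-tested, so every series gets exactly one label.

Class assignment itself is the method's definition of a statistically
significant trend, and the `significant` flag reflects it. An empirical
p-value (upper-tail rank of the max-over-lags autocorrelation, or of the
spike extremum, within the corresponding null distribution, with an
add-one correction) is also computed, and a per-subject Benjamini–Hochberg
gate on those p-values is reported as `bhSignificant`. The two flags are
kept separate for a structural reason: with eight bins, the resampling
null produces series as smooth as a noiseless monotone step a few percent
of the time, so the empirical p-value of even an infinite-SNR trend
bottoms out around 0.02–0.04. Composing the class rule with BH at 0.05
would therefore report essentially no lag trends at any effect size —
the gate is a stricter, adaptive filter appropriate for ranking, not the
primary detection criterion. The spike branch of the pooled null is also
mildly anticalibrated when the pool mixes series of very different shapes
(a pool rich in spike values inflates the null maxima quantile); the
synthetic studies below quantify both effects.

# Two-level trend clustering

Within each subject and class, series are clustered agglomeratively with
average linkage at two levels: groups on autocorrelation profiles with
correlation dissimilarity $1 - r$, and subgroups on the normalized series
with Euclidean dissimilarity. Both counts are chosen by maximizing the
mean silhouette over $k = 2,\dots,\min(n-1, 8)$, ties to the smallest k;
fewer than three members, or members at zero mutual dissimilarity, bypass
the silhouette and form one cluster. Average linkage and the Euclidean
second-level metric are package choices (both configurable in spirit —
the dissimilarities are isolated in one helper each); zero-variance
profiles are handled by defining their correlation with an identical
profile as 1 and with anything else as 0.

# Visibility-graph summaries

Each group/subgroup median signal (per-bin, missing-aware) is summarised
as a natural visibility graph: vertices are present timepoints, and two
points are joined when the straight line between them passes strictly
above every intermediate point. Strictness is a convention: it makes a
constant series a path graph rather than a complete one, and it is
isolated in a single predicate. Adjacent points are always joined, so the
graph is connected.

Temporal communities are delimited by the endpoint shortest path (fewest
hops; ties resolved toward the lexicographically smallest vertex
sequence). A path edge that skips over intermediate timepoints marks a
regime change, so communities are the contiguous runs between the
endpoints of multi-step jumps; stretches where the path advances one bin
at a time stay within one community. Each delimiting vertex joins the
adjacent community with which it shares more visibility edges, ties to the
earlier one. All tie rules are fixed so outputs are deterministic; the
cost is that exact time-reversal symmetry can be broken by one vertex at a
community boundary, which the property test accounts for.

# The cross-subject network

Per measurement, Euclidean distances between subjects' periodograms are
binarized strictly below a radius $d_q$ and summed into an integer
weighted adjacency. $d_q$ is the 0.99 quantile of distances between
bootstrap-series periodograms drawn from the cohort-wide pooled values —
a deliberately permissive radius that excludes only the most dissimilar
1% of null pairs, implemented exactly as stated (the level is a
parameter). With 50,000 bootstrap signals the full set of pairwise
distances is enormous and statistically redundant; the implementation
pairs consecutive signals into 25,000 disjoint pairs, which leaves the
quantile estimator unbiased and the draw seeded and reproducible.
Measurements missing for either subject are skipped for that pair;
subjects sharing no measurement stay in the roster as isolated nodes.

Communities are found by embedding the adjacency in two dimensions via a
regularized spectral decomposition — a uniform shift of
$0.01\,\bar A + 10^{-8}$ is added, the matrix is symmetrically
degree-normalized, and the top singular vectors are scaled by their
singular values — followed by k-means, repeated 1,000 times with varied
random initializations. k is chosen by silhouette on the embedding
(`kMode = "auto"`) or fixed (`kMode = "fixed"`, e.g. k = 5); both modes
exist because the selection rule and the reported count answer different
questions and need not agree. Runs are combined through a co-association
matrix (fraction of runs co-clustering each pair); the consensus partition
cuts an average-linkage tree of 1 − co-association at k, each run is
aligned to it by greedy contingency matching, and each subject takes its
highest-frequency membership, with the full frequency row retained.

# Cohort reporting

Per measurement, the summary counts subjects with a significant trend and
codes the majority direction of three phases of the normalized series
versus the (zero) baseline: flight F (mean over 33/82/132 d), return R
(165 d) and post-return PR (mean over 195/225 d). The coding deadband
ε = 0.1 on the normalized scale is a package default: normalized series
have unit norm, so a fixed deadband is comparable across measurements; it
is configurable. Per-phase ties code as "−". A secondary triple is listed
when at least 25% of the counted subjects share a common triple different
from the primary (the fraction is configurable, the convention mirrors
parenthetical secondary trends in cohort tables). Rows sort by count,
ties by measurement id. Negating all series flips ↑ and ↓ and fixes "−"
(the antisymmetry property test).

# The synthetic cohort generator

The generator emulates the structure of the motivating cohort — by
default 27 subjects × 264 measurement annotations — with raw observations
every ~15 d plus Gaussian jitter, 10% dropout, and additive i.i.d.
Gaussian noise per raw record (the simplest model consistent with the
analysis assumptions; no distribution is published for the real panels).
Planted archetypes span the reported trend families: in-flight rise
persisting post-flight, in-flight rise reverting at return, landing
spike/dip, and flat. Blocks of subjects share archetype-measurement
assignments so the cross-subject network has a recoverable block
structure. Ground truth stores the intended class at bin resolution,
because classification operates on binned series.

Effect sizes are free parameters: no per-measurement variances are
published for the restricted real data, so amplitudes are set in units of
the raw noise SD. The recovery studies freeze amplitude 15 (raw
SNR 15, i.e. bin-level SNR 25–40 after within-bin averaging) for the
high-SNR sensitivity checks; sensitivity at raw SNR 5 is ~0.6–0.7 for the
step archetype, rising through ~0.93 at SNR 12 to a plateau near 0.975 —
the residual misses trace to the planted series' own values contaminating
the subject's bootstrap pool. For the same reason spike archetypes are
planted sparsely in the spike recovery study (2 of 100 measurements):
each planted spike contributes its extreme value to the pool, and once
spike series exceed ~5% of a panel the null maxima quantile absorbs them.

What the generator does **not** emulate: assay-specific error structures,
between-measurement correlation, non-Gaussian heavy tails, and
measurement-specific sampling schedules. Passing recovery tests therefore
demonstrate that the pipeline's logic is correct and calibrated under its
own assumptions, not that real panels reach any particular sensitivity.

# Numerical conventions and degenerate inputs

* Degenerate Lomb–Scargle basis components (a cosine or sine that vanishes
  at every sample point, e.g. the sine at an exact Nyquist frequency of an
  integer grid) are zeroed and contribute no power, the convention under
  which the natural-grid inversion identity holds exactly through Nyquist.
* All-zero-power series are rejected by `autocorrelations()`; upstream
  flagging makes this unreachable in the pipeline.
* Every stochastic operation takes an explicit seed; cohort-level
  functions derive per-subject and per-run child seeds deterministically,
  and `runPipeline()` is byte-reproducible for a fixed seed.
* Empirical p-values use the add-one correction $(1 + \#\{\text{null} \ge
  \text{obs}\})/(n_{\text{boot}} + 1)$, so they are never exactly zero.

# Problem sizes used by the test suite

The suite runs the calibration checks at 10⁵ bootstrap series with 10⁴
held-out draws (lag-1 threshold) and 5×10⁴ signals with 10⁴ fresh pairs
(similarity radius); recovery studies use 20-subject cohorts with 40–100
measurements and 10⁴-series nulls; unit tests use smaller cohorts. The
acceptance script reproduces both calibrations on a 27 × 264 cohort. These
sizes were chosen so each quantity's sampling error is well inside its
stated tolerance.

# Known limitations

* Eight bins bound the resolvable lag range (L ≤ 4) and the power of any
  trend statistic; the empirical p-value floor discussed above is a
  consequence, not an implementation artifact.
* The pooled-value null assumes exchangeability of a subject's normalized
  values across measurements and bins; strong pool heterogeneity biases
  the spike thresholds upward.
* The permissive 0.99 similarity radius makes dense networks whose
  community structure rests on edge weights rather than topology;
  interpretation should lean on the weights and membership frequencies.
* Visibility-community boundaries depend on deterministic tie rules and
  can shift by one vertex under time reversal.
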