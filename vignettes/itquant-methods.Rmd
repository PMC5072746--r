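---
title: "Ordinal information quantifiers for environmental time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal information quantifiers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itquant)
```

## The problem

Conventional model benchmarking metrics for environmental fields (bias,
RMSE, correlation) compare values but are largely blind to *dynamics*: a
simulation can match a monthly productivity climatology closely while
producing time series whose temporal structure — how regular, how noisy,
how predictable — is wrong. `itquant` implements a family of time-causal
information-theory quantifiers built on ordinal pattern statistics that
target exactly this structural aspect, together with the machinery to apply
them to site records and gridded space–time fields and to compare model
runs against observations.

## Ordinal symbolization

A regularly sampled series $x_t$ is embedded in windows
$(x_j, x_{j+\tau}, \dots, x_{j+(D-1)\tau})$ of dimension $D$ and delay
$\tau$. Each window is symbolized by the permutation of its time offsets
sorted by ascending value, and the permutation is indexed by its Lehmer
rank (its position in the lexicographic listing of all $D!$
permutations). The relative frequencies of the $D!$ patterns over all
complete windows form the ordinal-pattern probability distribution $P$ —
a "causal" PDF in the sense that it encodes temporal order, unlike a value
histogram. Patterns are invariant under strictly increasing transformations
of the data, which makes the quantifiers immune to sensor calibration
drift, unit changes, and monotone bias.

Choices the user controls, and the defaults:

* **Embedding dimension** `D = 4` by default (24 patterns). Reliable
  estimation needs far more windows than patterns; the package enforces a
  hard floor of $D!$ windows and warns below $5 \cdot D!$. For
  multi-decadal monthly records (a few hundred steps), $D = 4$ is the
  largest dimension that respects these floors; $D = 6$ is used for the
  long synthetic benchmark series where $10^4$–$10^5$ samples are
  available.
* **Delay** `tau = 1`: consecutive values. Larger delays probe longer
  lags; the variance weights are then computed over the same lagged
  (embedded) points the symbolization sees, so weighting and symbolization
  always refer to the same vectors.
* **Ties**: real-valued geophysical data rarely tie, but quantized or
  truncated data do. The default resolves ties deterministically in favour
  of the earlier time offset (so results are reproducible and a constant
  window maps to the identity pattern); `tie_rule = "reject"` drops tied
  windows instead. `validate_series()` always reports the tied fraction so
  the user can judge whether ties are material.
* **Missing data**: any window touching a missing value is skipped and the
  skipped fraction reported. No imputation is attempted.
* **Pattern ordering**: the Lehmer rank is the canonical ordering. The
  Fisher information (below) depends on the ordering, so the configuration
  carries it explicitly and a user-supplied ordering table is accepted for
  alternative schemes.

Weak stationarity — that the probability of $x_t < x_{t+k}$ does not
depend on $t$ — is an assumption of the approach; it is documented, not
tested.

## The quantifiers

With $N = D!$ and $P = \{p_i\}$:

* **Normalized permutation entropy**
  $H[P] = -\sum_i p_i \ln p_i / \ln N \in [0, 1]$ measures how evenly the
  dynamics populate the patterns: 1 for uncorrelated noise, 0 for a series
  with a single pattern (e.g. a monotone trend).
* **Statistical complexity** $C[P] = Q_J[P, P_e] \cdot H[P]$, where $Q_J$
  is the Jensen–Shannon divergence between $P$ and the uniform
  distribution $P_e$, normalized by the constant
  $Q_0 = -2\{\frac{N+1}{N}\ln(N+1) - 2\ln(2N) + \ln N\}^{-1}$ so that a
  point-mass distribution scores exactly 1. $C$ vanishes both for perfect
  order and for pure randomness and is large for structured dynamics in
  between. The normalization constant follows from evaluating the
  divergence of a point mass against $P_e$ in closed form; the package's
  tests assert $Q_J(\text{delta}) = 1$ to $10^{-12}$ for several $N$.
* **Discrete Fisher information**
  $F[P] = F_0 \sum_{i=1}^{N-1} (\sqrt{p_{i+1}} - \sqrt{p_i})^2$, built
  from probability *amplitudes*, with $F_0 = 1$ for a point mass at either
  end state and $1/2$ otherwise. $F$ is a local quantity — it compares
  adjacent pattern probabilities in the configured ordering — and behaves
  opposite to $H$ at the extremes: 0 for the uniform distribution, 1 for
  an end-state point mass. Because it is ordering-dependent, periodic
  signals whose mass splits between the all-ascending and all-descending
  patterns (which sit at opposite ends of the Lehmer ordering) attain
  $F \approx 1/2$ rather than 1; the monotone ramp attains exactly 1.
* **Rényi entropy** $H_q = \log_2(\sum_i p_i^q)/(1-q)$ (bits) is provided
  as the single-exponent analogue of pattern weighting; $q > 1$ suppresses
  rare patterns. The $q \to 1$ limit is the Shannon entropy; tests verify
  the two-sided limit with the symmetric mean at $q = 1 \pm 10^{-4}$,
  which cancels the first-order term in $q - 1$.

### Variance weighting

Environmental series have strongly seasonal signal-to-noise ratios:
dormant-season windows are low-amplitude and noise-dominated. The weighted
pattern distribution multiplies each window's contribution by its variance
$w_j = \frac{1}{D}\sum_k (x_{j+k\tau} - \bar{X}_j)^2$, so
low-variance, noise-dominated patterns are down-weighted. The weighted
variants $H_w, C_w, F_w$ result from applying the same functionals to the
weighted distribution, and are the package default (`weighted = TRUE`).
Two consequences worth remembering:

* weighting is invariant under *affine* transforms of the data but not
  under general monotone transforms (the weights are amplitude-dependent
  by design); exact monotone-transform invariance is a property of the
  unweighted counts;
* a constant series has zero total weight and is rejected as degenerate.

### Limit curves of the entropy–complexity plane

For fixed $N$, the attainable $(H, C)$ pairs lie between two curves. The
package traces the lower curve with the one-parameter family
$(p, \frac{1-p}{N-1}, \dots)$ and the upper curve as the envelope of the
families having $m = 0, \dots, N-2$ components exactly zero and the
remaining mass split as one free component plus equal shares. Each family
is evaluated in closed form on a 2000-point parameter grid, the envelope
is taken as per-bin maxima on the requested entropy grid (500 points by
default), and both curves are returned via linear interpolation, anchored
at $C = 0$ for $H \in \{0, 1\}$. Containment is fuzz-tested with $10^4$
flat-Dirichlet random distributions at $N = 24$ against a $10^{-6}$
tolerance.

## Causal information planes and the plane geography

The pair $(H, C)$ — and the complementary pair $(H, F)$ — locate a series
in a plane in which canonical process classes occupy distinct regions:
periodic signals at low $H$, low $C$; uncorrelated noise in the corner
$(1, 0)$; $1/f^k$ noise at intermediate positions ordered by $k$; and
deterministic chaos at intermediate $H$ with $C$ close to the upper limit
curve. The package's synthetic generators (`white_noise()`, `k_noise()`,
`logistic_map()`, `harmonic()`) reproduce this geography, and the test
suite asserts it quantitatively: e.g. the fully chaotic logistic map at
$r = 4$ lies nearer the upper than the lower complexity bound, and its
shuffled surrogate (same values, destroyed order) moves to the noise
corner.

## Model benchmarking with the Jensen–Shannon divergence

Mismatch between an observed and a simulated series is quantified as the
Jensen–Shannon divergence
$J = S[(P_{obs}+P_{mod})/2] - S[P_{obs}]/2 - S[P_{mod}]/2$ between their
ordinal distributions: symmetric, bounded by $\ln 2$, zero exactly when
the distributions coincide. Because it is computed on ordinal patterns it
is blind to bias and monotone rescaling — the complementary failure mode
to RMSE. `rmse_map()`/`jsd_map()` compute both per grid cell;
`metric_correlation()` quantifies their (non-)redundancy. A deliberate
non-goal: quantifiers are never applied to model *residuals*, whose
noise-like ordinal statistics would reward bad noisy models.

## Temporal resolution

`ts_aggregate()` (block means; gap-conservative: any missing member makes
the block missing; trailing partial blocks dropped to keep block
statistics unbiased) and `ts_decimate()` (thinning) move a series through
the planes in opposite directions: aggregation builds serial correlation
and lowers entropy of correlated series, decimation destroys it.
`resolution_sweep()` traces the quantifiers along an aggregation ladder.
For a half-hourly series with a daily cycle and $D = 4$, a window spans
exactly one day at 6-hour resolution, the pattern distribution collapses
onto the few phases of the cycle, and the entropy dips — the package
reproduces this detection effect with the pure diurnal-cycle generator
`diurnal_cycle()`, whose flat night and asymmetric daylight bump mimic a
productivity record. For a *pure sinusoid* the dip relative to 1-hour
resolution does not occur (its long monotone runs already concentrate the
distribution at fine resolution); the asymmetric profile is the honest
minimal model of the phenomenon.

## Gridded products

`itq_map()` applies the suite cell-wise to a `time × lat × lon` field,
masking cells with less than `min_valid_fraction = 0.9` valid time steps
(a conservative default for gap-prone satellite products).
`rgb_composite()` encodes $(H, C, F)$ in the red/green/blue channels,
scaled linearly over the *theoretical* $[0, 1]$ range (not per-map
min–max) so composites are comparable across datasets. No regridding is
performed anywhere: fields must be pre-aligned, and coordinate equality is
enforced.

## Model-structure diagnostics

To compare many model runs, each run's cell-wise $(H_w, C_w)$ point cloud
is rasterized on a fixed $25 \times 25$ grid over $[0,1]^2$ (half-open
pixels, top edge closed) and normalized to unit mass, so runs with
different numbers of grid cells are comparable. The fixed raster bounds —
rather than data-driven bounds — keep pixels identified across runs.
Long simulations are sliced into windows (`windowed_runs()`, e.g.
30-year windows every 10 years of a monthly run) so each run contributes a
trajectory of fingerprints. Pixels empty across *all* runs are dropped
(above the upper limit curve they are empty by necessity), and a PCA
(column centering only — the entries already share the normalized-count
scale; no variance scaling) separates the fingerprints. The package's
synthetic experiment builds two "model families" (noise colour $k = 1$
vs $k = 3$) under two "scenarios" (linear trends of different slope) and
verifies that the leading component separates families with cluster purity
1 across 20 seeds while scenarios interleave — structure, not forcing, is
what the fingerprints see.

## Synthetic generators: what they do and do not emulate

All generators are seed-deterministic and restore the caller's RNG state.
`gpp_site()` and `gpp_grid()` emulate the first-order features of
productivity records: a seasonal cycle (optionally with a mid-summer
depression that creates the two-peaked season of water-limited sites), a
diurnal daylight bump at sub-daily resolution, AR(1) noise, truncation at
zero, and latitude-banded regimes for spatial gradients. They do **not**
emulate weather-driven synoptic variability, realistic gap structure,
sensor artifacts, or spatial autocorrelation of the noise. Passing tests
therefore demonstrate the correctness and the qualitative behaviour of the
quantifiers, not that any particular real-world product will occupy a
particular plane position.

`k_noise()` synthesizes $1/f^k$ noise spectrally (unit-amplitude spectrum
scaled by $f^{-k/2}$, uniform phases, zero DC, standardized to unit
variance); periodogram regression in the tests confirms the slope.
`logistic_map()` discards a 1000-step transient by default; the degenerate
orbit from $x_0 = 0.5$ at $r = 4$ (which hits the fixed point) is
documented and tested.

## Numerical conventions and problem sizes

Natural logarithms throughout for $S$, $H$, $C$, $J$ (the normalized
quantities are base-invariant); Rényi entropy in bits. $0 \ln 0 := 0$.
Probability vectors are validated to sum to 1 within $10^{-8}$; computed
divergences are clamped at 0 to absorb rounding. CSV output uses 12
significant digits so round-trips are stable. The test and acceptance
computations use $n = 10^5$ (white noise), $n = 10^4$ (chaos, coloured
noise; 50 replicates per noise colour), 360 monthly steps for gridded
fixtures, and 20 seeds for the structure-separation experiment — sizes at
which every asserted effect is far larger than its sampling noise.

## Known limitations

* Univariate, regularly sampled series only; no formal stationarity test.
* The Fisher information is meaningful only relative to a pattern
  ordering; comparisons across orderings are not.
* Weighted quantifiers lose exact monotone-transform invariance (by
  design).
* Calendar-aware aggregation (true month boundaries) is out of scope; the
  sweep uses fixed integer factors.
* The limit curves are interpolated from finite parameter grids; the
  $10^{-6}$ containment tolerance reflects that.
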