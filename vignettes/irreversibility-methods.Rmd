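---
title: "Testing time irreversibility: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing time irreversibility: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irrev)
```

## The problem

A stationary series `x = (x_1, ..., x_N)` is time-reversible when
`(x_1, ..., x_k)` and `(x_k, ..., x_1)` have the same joint distribution for
every `k`; irreversibility is any departure from that symmetry. Linear
Gaussian processes — and static transformations of them — are reversible, so
evidence of irreversibility is evidence of nonlinearity, non-Gaussianity or
non-equilibrium dynamics. The definition is agnostic about *which* joint
property breaks the symmetry, which is why this package carries 18 tests with
very different sensitivities, all returning the same `(p-value, statistic)`
pair and registered in `all_tests()`.

Throughout, "the reversed series" means `rev(x)`; every signed statistic in
the package changes sign under reversal (checked by the test suite), and
every p-value is invariant or near-invariant under it.

## Surrogate significance

Measures without a native p-value (Casali, Costa, Pomeau, Gaspard, discrete
Costa) are wrapped by `surrogate_test()`: the measure is recomputed on `S`
uniformly random permutations of the values. A permutation preserves the
marginal distribution exactly and destroys all temporal structure, so it is a
sample from the "no temporal structure at all" null.

* **Proportional** (`surrogate_plan("proportional")`, default `S = 100`):
  the p-value is `max(c, 1)/S`, `c` the number of surrogates whose statistic
  reaches the observed one. It is a true (conservative) p-value with floor
  exactly `1/S` — 0.01 at the default ensemble size. The clamp `max(c, 1)`
  was chosen over the `(c+1)/(S+1)` estimator precisely so the floor is
  `1/S`.
* **Z-score** (`surrogate_plan("zscore")`, default `S = 20`): the observed
  statistic is standardised against the surrogate ensemble and mapped through
  the standard-normal tail. Cheap and able to resolve arbitrarily small
  values, but *not* a true p-value: the surrogate null need not be Gaussian.

Wrapped measures are oriented "larger = more irreversible" by taking absolute
values of signed statistics, so "equal to or higher" is well defined; the
reported statistic keeps its sign.

Two caveats the user should know. First, a surrogate scheme tests
*exchangeability*, not reversibility: on serially dependent but reversible
input (an AR(1)/Ornstein–Uhlenbeck series) the shuffled null is too narrow
and the wrapped measures over-reject. The dependence-robust native tests are
the right tools for dependent data; the surrogate route is appropriate when
the null of interest is "no temporal structure". Second, with a surrogate
measure that can degenerate on shuffled data (e.g. entropy production with an
unmatched reverse transition), the failed surrogate is counted as exceeding
the observed statistic — conservative by construction.

## The sixteen continuous tests

**BDS** (`bds_test`, native). Correlation integrals `C_m(eps)` (fraction of
pairs of `m`-dimensional delay vectors within sup-norm radius `eps`) are
compared through the classical standardised difference
`sqrt(M) (C_m - C_1^m) / sigma`, with the standard variance built from `C`
and the triple-count `K`. Defaults `m = 2`, `eps = 0.5 sd(x)`; minimum
`N = 200`. BDS is an iid test: it rejects for *any* serial dependence, which
is why it is kept out of reversibility-specific calibration claims.

**Casali** (`casali_test`, surrogate). Sample skewness of the lag-`m`
increments `x[i+m] - x[i]`; `m = 1` by default. Skewed increments mean rises
and falls are shaped differently — a direct arrow-of-time signature.

**COP** (`cop_test`, native). `nPatterns = 100` random reference patterns of
length `pSize = 3` are drawn (standard normal values, normalised to zero mean
and unit maximum absolute deviation — the same normalisation applied to every
sliding window; constant windows are skipped with a warning). For each
pattern the series is transcribed into distances (mean absolute difference)
between the pattern and each normalised window, for the series and its
reversal; the two distance samples are compared by a two-sample KS test. The
reported p-value is the smallest per-pattern p times `nPatterns`
(Bonferroni); the statistic is the largest KS distance. Two inference
corrections are built in: the KS comparison uses only non-overlapping windows
(stride-1 windows are serially dependent, which would inflate the effective
sample), taken from *interleaved* disjoint window sets for the forward and
backward samples (forward and backward distances of the same window are
mutually dependent, and interleaving — rather than a first-half/second-half
split — prevents slow nonstationarity from masquerading as irreversibility).
Bonferroni over correlated patterns makes the test conservative under the
null; a minP-style resampling correction would be exact but multiplies the
cost by the resampling factor, a poor trade for a test that is run inside
optimisation and manipulation loops.

**Costa index** (`costa_test`, surrogate). `(N_up - N_down)/(N_up + N_down)`
— amplitude-blind by design in the continuous version.

**DFK** (`dfk_test`, native). The series is symbolised (equal-probability
bins by default; equal-width available), symbols are merged into overlapping
words of `wordLength = 3`, and each word's count is compared with its
reversed word's count through the HAC-studentised chi-square described below.
The default alphabet is binary (`nSymbols = 2`), the original construction's
partition — and a deliberately conservative default: in *any* binary
sequence the counts of a word and of its reversal are nearly balanced (each
maximal run of a symbol contributes one boundary occurrence of each), so
detection power effectively requires `nSymbols >= 3`. This mirrors the known
behaviour of the test: weak at default parameters, much stronger after
parameter optimisation. One concrete consequence, computed in the test
suite: the binary default does not flag a fully chaotic logistic orbit —
the median partition is that map's generating partition, making the symbol
stream iid — while `nSymbols = 3` detects it overwhelmingly. Because the
binary default's p-value is close to 1 for essentially any input, its null
rejection rate sits *below* any two-sided calibration envelope; calibration
is therefore asserted at `nSymbols = 3`, and the default is only required
not to exceed the envelope.

**Diks** (`diks_test`, native). Non-overlapping `m`-dimensional delay
vectors of the series form one cloud; their element-reversed copies form the
other. The clouds are compared by a Gaussian-kernel two-sample U-statistic
(unbiased MMD form; because reversal preserves pairwise distances the
statistic reduces to within-cloud minus cross-cloud kernel means). Under the
null the delay-vector law is reversal-symmetric, which makes the U-statistic
*degenerate* — the usual normal approximation is invalid — so significance
comes from an exact sign-flip randomisation: each (vector, reversed vector)
pair is exchangeable under reversibility, and the null is sampled with
`B = 200` independent fair-coin swap patterns (smallest attainable p:
`1/(B+1)`). Bandwidth default is Silverman-type,
`sd(x) * (4/(m+2))^(1/(m+4)) * M^(-1/(m+4))`; at most `max_vectors = 1000`
evenly spaced vectors are used, which keeps the cost quadratic in a bounded
number.

**Local clustering** (`local_clustering_test`, native). The directed
horizontal visibility graph (dHVG: arc `i -> j`, `i < j`, when every
intermediate value lies strictly below `min(x_i, x_j)`; equal values block
visibility) is built with the standard monotone-stack sweep. For each node
the triangle density among its past neighbours (retarded coefficient) and
among its future neighbours (advanced) are computed; the two samples are
compared with the Epps–Singleton test (heavy ties make a CDF-based test
inappropriate). A graph with no triangles on either side (e.g. a monotone
series) returns `p = 1`.

**MSTrends** (`mstrends_test`, native). Least-squares polynomial fits
(`degree = 1`) on sub-windows; the distribution of leading coefficients of
the series is compared with that of its reversal by a two-sample KS test.
The compared samples come from alternating disjoint blocks (forward fits on
odd blocks, reversed fits on even blocks) so the KS independence assumption
approximately holds. Default `window = 3` — the shortest window with a
redundant observation per linear fit — both maximises the number of blocks
and keeps the test sensitive to short-memory dynamics, whose slope asymmetry
washes out in long windows.

**Permutation patterns** (`perm_patterns_test`, native). The ordinal pattern
(rank sequence; ties broken stably, earlier index first) of every stride-1
window of length `pSize = 3` is counted, and each pattern's count is compared
with its time-reversed partner's through the HAC-studentised chi-square:
for each non-palindromic pattern pair the indicator difference stream
`d_t = 1{pattern} - 1{reversed pattern}` is formed, `(sum d_t)^2` is divided
by a Bartlett long-run variance estimate of `sum d_t` (bandwidth `pSize`,
accounting for window overlap), and the per-pair terms are summed into an
approximately chi-square statistic with one degree of freedom per
contributing pair. A plain multinomial chi-square would ignore the overlap
dependence and miscalibrate.

**Pomeau** (`pomeau_test`, surrogate). The canonical third-order
time-asymmetric polynomial `mean(x_t x_{t+1}^2 - x_t^2 x_{t+1})` — the
lowest-order polynomial that changes sign under reversal and vanishes for
exchangeable series.

**Ramsey** (`ramsey_test`, native). The lag-`k` sample bicovariances
`mean(x_i^2 x_{i-k})` and `mean(x_i x_{i-k}^2)` are compared on the raw
(uncentered) series; for iid input the per-term difference has exactly zero
mean without centering. The mean difference is studentised with a Bartlett
HAC variance (bandwidth `max(k, 1.5 n^(1/3))`, covering the lag-`k` term
overlap and weak dependence) and referred to the standard normal, two-sided.

**Skewness index** (`skewness_index_test`, native). The reported statistic
is the ratio `skew(diff(x)) / skew(x)` (unstable when the series itself is
nearly symmetric — it is a descriptive index, not the inferential quantity);
the p-value comes from the D'Agostino zero-skewness transformation applied to
the differenced series, with one correction: differencing makes the input
serially dependent (MA(1) for iid data), which scales the sampling variance
of the skewness by `sum_j rho_j^3`; the z-score is rescaled by the empirical
value of that factor (lags up to 20, clamped to [0.2, 3]).

**Ternary coding** (`ternary_test`, native). Increments are mapped to
strongly increasing / strongly decreasing / maintaining using a threshold on
`|diff(x)|`, by default its `q = 0.33` quantile so the coding adapts to
scale (an absolute threshold is available). Words of length `wordLength = 1`
are compared with their reversal image (reverse and negate) through the same
pair chi-square; here the long-run variance uses the flat-top (truncated,
unweighted) estimator, because differencing plus thresholding leaves strong
*negative* autocovariances that the Bartlett kernel's downweighting cannot
represent (it falls back to Bartlett in the rare case of a non-positive
flat-top estimate).

**TPLength** (`tplength_test`, native). Maximal increasing and decreasing
run lengths (zero increments break runs) are compared by Epps–Singleton;
reversal swaps the two length distributions. All-length-one runs (a strictly
alternating series) return `p = 1`.

**Visibility graph** (`visibility_test`, native). In- versus out-degree
samples of the dHVG, compared by Epps–Singleton — the natural choice for
small-integer degree samples. The first and last nodes are dropped by
default (`drop_boundary`): their degrees are truncated by the series edges.

**Zumbach** (`zumbach_test`, native). Returns are simple differences by
default; log-returns are available for strictly positive multiplicative
data (log-transforming bounded positive data that merely visits small values
produces heavy-tailed spikes that wreck the moment estimates, so "positive"
alone is not a reason to take logs). At evaluation points spaced
`2*window + 2` apart — so the return stretches feeding different points are
disjoint, and under an iid null the contributions are exactly independent —
the squared return is correlated with the realised (future) and historical
(past) RMS volatility over `window` samples; the statistic is
`cor(r_t^2, realised) - cor(r_t^2, historical)`, which reversal negates, and
the p-value is a one-sample t-test on the per-point contributions. Default
`window = 2`: volatility asymmetry is only visible at scales where the
process has memory, and the asymmetry of short-memory processes decays
quickly with window length; 2 is the shortest window giving a proper
multi-sample RMS. Users analysing daily financial data will want larger
windows (the grid exposes 1–20).

## The two discrete tests

**Gaspard** (`gaspard_test`, surrogate). The symbol stream is modelled as a
Markov chain; entropy production per step is
`sum_ij pi_i P_ij log(P_ij / P_ji)` with `pi_i P_ij` estimated by bigram
frequencies (so the estimate inherits stationarity up to edge effects and is
non-negative up to estimation noise; zero exactly under estimated detailed
balance). An observed transition whose reverse is never observed makes the
statistic infinite; with the default `pseudocount = 0` this is an *error* —
silently regularising would bias the statistic — and the user opts into
regularisation by setting a positive pseudocount. Orders above 1 recode the
stream into overlapping k-grams and run the same estimator. Minimum length
`10 |A|^2` so the transition matrix is populated.

**Discrete Costa index** (`costa_discrete_test`, surrogate). For rankable
symbols with numeric differences, the statistic is the excess share of the
total squared increment carried by rises:
`(sum_{d>0} d^2 - sum_{d<0} d^2) / sum d^2` in [-1, 1] — amplitude-aware,
antisymmetric under reversal, and equal to the continuous count asymmetry
when all increment magnitudes coincide. The exact amplitude weighting of the
original heartbeat-dynamics index is not in the literature available here;
this variance-share form is the package's documented choice.

## Dependence-aware inference: a summary

Most classical two-sample machinery assumes independent observations, but
sliding windows, overlapping words, differenced streams and volatility
windows are all serially dependent, and forward/backward samples extracted
from the *same* data are mutually dependent. The package uses four devices,
each where it is the right tool:

1. **Bartlett HAC long-run variance** for count-difference streams with
   mild positive dependence (permutation patterns, DFK, Ramsey);
2. **flat-top (truncated) long-run variance** where negative
   autocovariances dominate (ternary coding);
3. **subsampling to disjoint supports** where exact independence is
   achievable by design (Zumbach's spaced evaluation points, MSTrends'
   alternating blocks, COP's interleaved non-overlapping windows, Diks'
   non-overlapping delay vectors);
4. **randomisation nulls** where the asymptotic distribution degenerates
   (Diks' sign-flip swaps; the surrogate layer itself).

The test suite verifies the resulting calibration: on iid Gaussian series
every native test's rejection rate at the 5% level sits inside the 99%
binomial envelope, except the two that are conservative by construction
(Bonferroni-corrected COP and binary-default DFK), which are checked against
the upper bound only.

## Toolkit

**Downsampling** (`downsample`). `skip` keeps the first observation of each
block of `tau`; `average` replaces each block by its mean; `decimate`
applies an order-8 Butterworth low-pass at `0.8/tau` of Nyquist with
zero-phase (`filtfilt`) application before taking every `tau`-th sample.
All three return `floor(N/tau)` values; `tau = 1` is the identity.

A note on multiscale logic, computed in the test suite: average-downsampling
a *deterministic chaotic map* does not erase its irreversibility — the
`tau = 2` average of a logistic orbit is a static transform of the
twice-iterated map's orbit, itself fully chaotic — so at `N = 10^4` the COP
test still detects the averaged series; at `N = 10^3` the asymmetry falls
below detectability and the test reads non-significant. Multiscale analysis
separates *scales of irreversibility* only for processes with genuinely
scale-localised structure, like the `generate_multiscale_irrev()` model,
where averaging at the model's own scale exposes the asymmetry and far
coarser averaging destroys it.

**Parameter optimisation** (`optimise_parameters`). For every combination in
the declared grid the test runs on every series of the ensemble; per-series
p-values are combined by Fisher's method on the log scale (so astronomically
small values stay comparable; a median-p combiner is available as a robust
alternative) and the arg-min combination is returned. Combinations that fail
on any series are skipped, never imputed. The default COP grid is pattern
sizes 3–6. To avoid overfitting, tune on one subset of the data and evaluate
on another; the optimiser deliberately takes whatever ensemble it is given.

**Manipulation** (`manipulate`). Candidate transforms are COP distance
profiles: a random pattern of length `pSize = 4` turns the series into the
sequence of distances to its normalised windows (length `N - pSize + 1`,
aligned to window starts; the correlation with the original is computed on
that support). Among `numIterations = 1000` candidates, increase mode keeps
those whose p-value (COP test with default parameters) is at or below
`pvThreshold = 0.01` and returns the one with the highest Pearson
correlation with the original; decrease mode mirrors this with `p >=`
threshold. Candidates are examined in decreasing order of correlation, so
evaluation stops at the first that satisfies the threshold — an exact
shortcut, not an approximation. If no candidate qualifies, the result is an
explicit failure record carrying the best candidate found, not an exception.

## Generators

Each generator emulates one regime of known (ir)reversibility; all are
seedable and none touches the caller's RNG state.

* `generate_logistic` (`r = 4`): fully chaotic, strongly irreversible; the
  canonical positive control. `x0 = 0.5` is rejected (degenerate orbit).
* `generate_henon`, `generate_lcg`, `generate_lorenz` (RK4, `dt = 0.02`,
  first coordinate): further deterministic chaotic references.
* `generate_ou` (Euler–Maruyama, `theta = 1`, `sigma = 1`, `dt = 0.1`):
  stationary linear Gaussian, the canonical *negative* control.
* `generate_srgbm` (`mu = 0.1`, `sigma = 0.2`, reset rate 0.05): geometric
  Brownian motion with Poissonian resetting. The defaults sit in the
  drift-dominated regime — slow multiplicative growth punctuated by abrupt
  resets — which is the regime in which resetting produces a genuinely
  irreversible non-equilibrium steady state; with volatility dominating the
  drift the sample path is statistically near-reversible and the generator
  would not serve its purpose as a positive control.
* `generate_weierstrass_asym`: a Weierstrass-style sum of `nterms = 8`
  self-similar harmonics (`a = 0.6`, `b = 3`) of an asymmetric
  piecewise-linear wave with rise fraction `gamma = 0.25` — time-asymmetric
  at every scale. This construction is the package's own documented variant.
* `generate_multiscale_irrev` (`tau_star = 5`, component amplitude equal to
  the noise sd): a logistic-map component held constant over blocks of
  `tau_star` samples plus dominant iid Gaussian noise; irreversibility is
  hidden at native resolution, exposed by averaging at `tau_star`, and
  destroyed far above it. Also the package's own construction.
* `generate_symbolic_walk` (`p_up = 0.7`, alphabet size 4): a biased walk on
  a cyclic alphabet; any bias breaks detailed balance on the cycle, giving a
  known-irreversible symbol stream with positive entropy production.

What the generators do *not* emulate: measurement noise with structure
(colored noise), nonstationarity (trends, regime switches), missing data,
and multivariate coupling. Tests passing on these generators therefore
demonstrate correctness of the statistics and calibration under clean
stationary conditions, not robustness to the artefacts of real recordings —
for real data the usual preprocessing (detrending, stationarity checks)
remains the user's responsibility.

## Numerical and policy choices

* **Missing values**: rejected everywhere, never imputed — imputation would
  corrupt ordinal structure silently.
* **Ties**: rank-based machinery breaks ties stably (earlier index first);
  equal values block horizontal visibility; zero increments break trend runs
  and belong to neither sign; symbolisation bins with duplicated quantile
  breaks collapse (an error if fewer than two distinct bins survive).
* **Per-test minimum lengths**: window/pattern tests require `N >= 50`,
  BDS and Diks `N >= 200`; calling below the minimum is an error, because
  the statistics are meaningless on tiny samples.
* **Degenerate inputs** return the null answer where the degeneracy *is*
  the answer (no triangles, all runs length one, constant volatility,
  palindromic clouds: `p = 1`, statistic 0) and an error where the statistic
  is undefined (constant series, zero-variance increments, exactly zero
  series skewness in the skewness index).
* **Sidedness**: difference-of-distribution tests are two-sided; the Diks
  U-statistic and the surrogate schemes are upper-tailed (larger = more
  irreversible); the registry records each test's convention.
* **Reproducibility**: every stochastic component (surrogates, COP patterns,
  Diks swaps, generators, manipulation) takes a `seed` and restores the
  caller's RNG state; a battery run inherits its seed from the surrogate
  plan, making the full output byte-reproducible.
* **Epps–Singleton**: implemented from the original construction
  (characteristic function at `t = (0.4, 0.8)` scaled by the pooled
  semi-interquartile range, chi-square with rank degrees of freedom,
  small-sample correction below 25 observations); when heavy ties collapse
  the IQR to zero the pooled standard deviation is used as the scale.

## Known limitations

* The shuffled-surrogate route over-rejects on serially dependent reversible
  series (it tests exchangeability); use the native tests there.
* BDS rejects for any dependence, not specifically irreversibility.
* COP's Bonferroni correction across correlated patterns is conservative;
  its p-values are valid but not tight.
* The Z-score scheme's output is an approximation, not a true p-value.
* The skewness index statistic (a ratio of skewnesses) is numerically
  unstable for nearly symmetric series; rely on its p-value, which depends
  only on the differenced series.
* All tests assume stationarity; the interleaved/alternating designs reduce
  but do not eliminate sensitivity to slow drifts.
* Problem sizes in the shipped test suite (series of 10^3–10^4 points,
  ensembles of 50–100 series, 200-replicate calibration runs) were chosen so
  the full suite completes in minutes while keeping binomial envelopes
  meaningful; all scale up by changing the corresponding arguments.
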