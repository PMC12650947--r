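# irrev: time-irreversibility tests for time series

A time series is **time-irreversible** when its statistical properties change
under the transformation *t → −t*: the series and its time-reversed copy are
distinguishable. Irreversibility is a fingerprint of non-equilibrium,
nonlinear or non-Gaussian dynamics — linear Gaussian processes (and static
transformations of them) are reversible — and it has become a working tool in
physiology (heartbeat dynamics, brain activity), finance and nonlinear
dynamics. Because "irreversible" does not say *how* the arrow of time shows
up, many tests exist, each sensitive to a different signature: ordinal
structure, visibility-graph topology, correlation integrals, symbol
statistics, trends, volatility asymmetry. A system can look reversible to one
test and glaringly irreversible to another, so serious analyses run several
tests in parallel.

`irrev` bundles **18 tests behind one uniform interface** — every test maps a
series to exactly a `(p-value, statistic)` pair:

* **16 tests for real-valued series**: BDS, Casali (increment skewness),
  Continuous Ordinal Patterns (COP), Costa index, Daw–Finney–Kennel (DFK),
  Diks, horizontal-visibility local clustering, MSTrends, Permutation
  Patterns, Pomeau, Ramsey (bicovariances), skewness index, ternary coding,
  trend-pattern lengths (TPLength), visibility-graph degrees, Zumbach
  (volatility asymmetry).
* **2 tests for symbolic series**: Gaspard entropy production
  `sum_ij pi_i P_ij log(P_ij / P_ji)` of the fitted Markov chain, and the
  amplitude-aware discrete Costa index.

Measures that do not come with a natural p-value (Casali, Costa, Pomeau,
Gaspard, discrete Costa) are wrapped in **shuffled-surrogate significance**:
the statistic is recomputed on randomly permuted copies of the series —
shuffling destroys all temporal structure, hence all irreversibility — and
compared to that null ensemble either by proportion (a true p-value with
floor `1/S`) or through a Z-score (cheap, approximate).

On top of the tests, the package provides the surrounding workflow:
multiscale **downsampling** (`skip`, block `average`, anti-aliased
`decimate`), per-test **parameter optimisation** over ensembles
(Fisher-combined p-values), an ordinal-pattern-based **irreversibility
manipulator** (transform a series to make it more or less irreversible while
staying correlated with the original), **generators** of series with known
irreversibility (logistic/Hénon/LCG maps, Lorenz, Ornstein–Uhlenbeck, srGBM,
asymmetric Weierstrass-type, a scale-specific irreversibility model, a
symbolic walk), and a command-line tool.

## Worked example

```r
library(irrev)

x <- generate_logistic(10000, seed = 42)   # fully chaotic, irreversible
cop_test(x, seed = 1)
#> Time-irreversibility test: COP
#>   statistic = 0.371135
#>   p-value   = 4.08189e-98
#>   params    = pSize=3, nPatterns=100, seed=1
```

The COP statistic 0.37 is the largest Kolmogorov–Smirnov distance between the
pattern-distance distributions of the series and its reversal over 100 random
patterns; the Bonferroni-corrected p-value ~1e-98 says the arrow of time in
this orbit is unmistakable. Every test is interchangeable:

```r
bds_test(x)
#> Time-irreversibility test: BDS
#>   statistic = 1576.63
#>   p-value   = 0
#>   params    = m=2, epsilon=0.177099

b <- run_battery(x, plan = surrogate_plan("zscore", seed = 7))
b[, 1:3]
#>                    test    pvalue statistic
#> 1                   BDS  0.00e+00  1.58e+03
#> 3                   COP  4.08e-98  3.71e-01
#> 5                   DFK  9.99e-01  1.07e-03
#> 6                  Diks  4.98e-03  1.88e+02
#> 16              Zumbach  1.20e-04 -1.23e-01
#> ...
```

Every test flags the series except DFK, whose default binary symbolisation is
the logistic map's generating partition (the symbol stream is iid coin
flips); optimising its parameters (`optimise_parameters("DFK", ...)`) finds
an informative alphabet. Manipulation in the other direction — injecting
irreversibility into white noise while staying close to it:

```r
set.seed(8)
u <- runif(10000)                          # iid: reversible by construction
m <- manipulate(u, increase = TRUE, numIterations = 1000,
                pSize = 4, pvThreshold = 0.01, seed = 9)
sprintf("p = %.4g, correlation = %.3f", m$pvalue, m$correlation)
#> "p = 0.001555, correlation = 0.699"
```

The returned series is strongly irreversible (p ≈ 0.0016) yet keeps a Pearson
correlation of ~0.70 with the original noise.

A shell interface wraps the same functions
(`inst/cli/irrev`; installed under `system.file("cli", "irrev")`):

```sh
irrev generate --model logistic --n 10000 --seed 1 > x.txt
irrev test --test COP --input x.txt --seed 7
irrev battery --input x.txt --surrogates 100 --method proportional
irrev downsample --method average --tau 2 --input x.txt
```

## Further reading

The methods vignette (`vignettes/irreversibility-methods.Rmd`) documents the
statistical construction of each test, the surrogate machinery, the
dependence-aware inference corrections, every tunable parameter with its
default and rationale, what the generators emulate, and known limitations.
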