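# Worked micro-examples (hand-derived expected values) and behavioural
# contracts for the continuous-series tests.

test_that("correlation integrals match the hand count on [0,1,2]", {
  # pairs within radius 1.5: |0-1| and |1-2| only; |0-2| = 2 exceeds it
  ci <- irrev:::cpp_bds_integrals(c(0, 1, 2), m = 1L, eps = 1.5)
  expect_equal(ci$C1, 2 / 3)
  expect_equal(ci$Cm, 2 / 3)
})

test_that("BDS flags a chaotic map and errors on a too-small radius", {
  x <- generate_logistic(2000, seed = 21)
  expect_lt(bds_test(x)$pvalue, 0.01)
  expect_error(bds_test(x, epsilon = 1e-12), "no pairs")
  expect_error(bds_test(rnorm(100)), "too short")
})

test_that("increment skewness matches the moment-ratio value 0.382", {
  # diffs of [1,2,4,8] are [1,2,4]; g1 = m3 / m2^1.5
  expect_equal(irrev:::casali_statistic(c(1, 2, 4, 8), m = 1),
               sample_skewness(c(1, 2, 4)))
  expect_equal(sample_skewness(c(1, 2, 4)), 0.3818018, tolerance = 1e-6)
  # a sine sampled over whole periods: the increment multiset is exactly
  # sign-symmetric (half-period shift negates each increment)
  s <- sin(2 * pi * (0:400) / 50)
  expect_lt(abs(irrev:::casali_statistic(s)), 1e-8)
})

test_that("costa statistic counts rises and falls", {
  expect_equal(irrev:::costa_statistic(c(1, 2, 3, 2)), 1 / 3)
  expect_equal(irrev:::costa_statistic(1:60), 1)       # strictly monotone
  expect_equal(irrev:::costa_statistic(60:1), -1)
  expect_error(irrev:::costa_statistic(rep(2, 60)), "no increments")
})

test_that("quantile symbolisation splits at the median", {
  expect_equal(irrev:::symbolise_quantile(c(1, 5, 2, 8, 3, 9), 2),
               c(0L, 1L, 0L, 1L, 0L, 1L))
})

test_that("DFK is exact-null on reversal-symmetric word histograms", {
  # strictly alternating symbols, odd length: the two length-2 words appear
  # exactly 40 times each, a reversal-symmetric histogram
  x <- rep(c(0, 1), length.out = 81) + seq(0, 0.01, length.out = 81)
  r <- dfk_test(x, nSymbols = 2, wordLength = 2)
  expect_equal(r$statistic, 0)
  expect_equal(r$pvalue, 1)
})

test_that("Diks returns the null answer for palindromic series", {
  set.seed(88)
  base <- rnorm(150)
  x <- c(base, rev(base))
  r <- diks_test(x, m = 3, seed = 2)
  # identical forward/backward clouds: no asymmetry detectable
  expect_gt(r$pvalue, 0.3)
  expect_lt(abs(r$Q), 5e-2)
})

test_that("dHVG construction matches hand-built graphs", {
  # series [3,1,2]: edges (1,2),(2,3),(1,3); node 1 advanced CC = 1
  e <- irrev:::hvg_edges(c(3, 1, 2))
  expect_setequal(paste(e[, 1], e[, 2]), c("1 2", "2 3", "1 3"))
  dg <- irrev:::hvg_degrees(c(3, 1, 2))
  expect_equal(dg$out, c(2, 1, 0))
  expect_equal(dg$`in`, c(0, 1, 2))
  cc <- irrev:::hvg_clustering(c(3, 1, 2))
  expect_equal(cc$advanced[1], 1)
  # monotone series: a path; out-degrees all 1 except the last node
  dg2 <- irrev:::hvg_degrees(c(1, 2, 3, 4, 5))
  expect_equal(dg2$out, c(1, 1, 1, 1, 0))
  # monotone series has no triangles: local clustering test finds nothing
  r <- local_clustering_test(seq_len(60) + 0)
  expect_equal(r$pvalue, 1)
  expect_equal(r$statistic, 0)
})

test_that("window slopes are exact for exact lines and antisymmetric under reversal", {
  expect_equal(irrev:::mstrends_slopes(c(1, 2, 3), 3), 1)
  set.seed(31)
  x <- rnorm(20)
  s_fwd <- irrev:::mstrends_slopes(x, 5)
  s_bwd <- irrev:::mstrends_slopes(rev(x), 5)
  expect_equal(s_bwd, -rev(s_fwd), tolerance = 1e-12)
  expect_error(mstrends_test(rnorm(100), window = 200), "too short|window")
})

test_that("ordinal pattern counts match hand enumeration and reversal is an involution", {
  tab <- ordinal_pattern_counts(c(1, 3, 2, 4), pSize = 2)
  expect_equal(unname(tab[["12"]]), 2L)
  expect_equal(unname(tab[["21"]]), 1L)
  # reversal involution on codes: reversing twice restores each pattern
  set.seed(14)
  x <- rnorm(100)
  oc <- irrev:::ordinal_codes(x, 3L)
  oc_rev <- irrev:::ordinal_codes(rev(x), 3L)
  expect_setequal(oc$rcodes, oc_rev$codes)
})

test_that("pomeau statistic matches direct evaluation and is antisymmetric", {
  expect_equal(irrev:::pomeau_statistic(c(1, 2, 1, 2)), 2 / 3)
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(80)
    expect_equal(irrev:::pomeau_statistic(rev(x)),
                 -irrev:::pomeau_statistic(x), tolerance = 1e-12)
  }
})

test_that("ramsey bicovariance difference matches the worked example", {
  u <- irrev:::ramsey_terms(c(1, 2, 1, 2), 1)
  expect_equal(mean(u), 10 / 3 - 8 / 3)
  set.seed(10)
  x <- rnorm(200)
  r1 <- ramsey_test(x)
  r2 <- ramsey_test(rev(x))
  expect_equal(r1$statistic, -r2$statistic, tolerance = 1e-12)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)
})

test_that("skewness index reuses the increment skewness and reacts to asymmetry", {
  set.seed(12)
  x <- cumsum(rnorm(500))  # random walk; just contract checks
  r <- skewness_index_test(x)
  expect_equal(r$skew_diff, sample_skewness(diff(x)))
  expect_equal(r$statistic, r$skew_diff / r$skew_x)
  expect_equal(sample_skewness(diff(rev(x))), -r$skew_diff, tolerance = 1e-12)
})

test_that("ternary symbolisation and reversal behave as defined", {
  expect_equal(irrev:::ternary_symbols(c(1.0, 0.2, -0.9), 0.5),
               c(1L, 0L, -1L))
  # reversal maps the symbol stream to its reversed negation
  set.seed(13)
  d <- rnorm(50)
  expect_equal(irrev:::ternary_symbols(-rev(d), 0.4),
               -rev(irrev:::ternary_symbols(d, 0.4)))
  x <- rnorm(300)
  expect_equal(ternary_test(x)$pvalue, ternary_test(rev(x))$pvalue,
               tolerance = 1e-10)
})

test_that("trend run lengths match hand decomposition; alternating series is null", {
  rl <- irrev:::trend_run_lengths(c(1, 2, 3, 2, 1, 2))
  expect_equal(sort(rl$up), c(1, 2))
  expect_equal(rl$down, 2)
  # strictly alternating: all runs length 1, nothing to distinguish
  x <- rep(c(0, 1), 40) + seq(0, 0.01, length.out = 80)
  r <- tplength_test(x)
  expect_equal(r$pvalue, 1)
  # reversal swaps the two run-length multisets
  set.seed(15)
  y <- rnorm(100)
  a <- irrev:::trend_run_lengths(y)
  b <- irrev:::trend_run_lengths(rev(y))
  expect_equal(sort(a$up), sort(b$down))
  expect_equal(sort(a$down), sort(b$up))
})

test_that("zumbach statistic is antisymmetric under reversal on aligned grids", {
  # N chosen so the evaluation grid maps onto itself under reversal
  x <- generate_srgbm(504, seed = 44)
  s1 <- zumbach_test(x, window = 2)$statistic
  s2 <- zumbach_test(rev(x), window = 2)$statistic
  expect_equal(s1, -s2, tolerance = 1e-10)
})

test_that("COP distances vanish for a window's own pattern and the test needs length", {
  w <- c(0.3, 0.9, 0.1)
  z <- w - mean(w); z <- z / max(abs(z))
  Z <- matrix(z, 1)
  expect_equal(irrev:::cop_distances(Z, z), 0)
  expect_error(cop_test(rnorm(40)), "too short")
  # deterministic under fixed seed
  set.seed(77)
  x <- runif(400)
  expect_identical(cop_test(x, seed = 5)$pvalue, cop_test(x, seed = 5)$pvalue)
})
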