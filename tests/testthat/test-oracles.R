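# Oracle equivalence: every optimised statistic must match its naive,
# loop-based counterpart to <= 1e-10 relative error on random series.

rel_err <- function(a, b) {
  d <- abs(a - b)
  ifelse(d == 0, 0, d / pmax(abs(a), abs(b), 1e-300))
}

test_that("scalar statistics match their loop oracles on 20 random series", {
  set.seed(101)
  for (i in 1:20) {
    x <- fixture_series(200, seed = 1000 + i)
    expect_lt(rel_err(sample_skewness(x), oracle_skewness(x)), 1e-10)
    expect_lt(rel_err(irrev:::casali_statistic(x, 2), oracle_casali(x, 2)),
              1e-10)
    expect_lt(rel_err(irrev:::costa_statistic(x), oracle_costa(x)), 1e-10)
    expect_lt(rel_err(irrev:::pomeau_statistic(x), oracle_pomeau(x)), 1e-10)
    expect_lt(rel_err(mean(irrev:::ramsey_terms(x, 1)),
                      oracle_ramsey_diff(x, 1)), 1e-10)
    expect_lt(rel_err(irrev:::costa_discrete_statistic(round(x * 50)),
                      oracle_costa_discrete(round(x * 50))), 1e-10)
    expect_lt(rel_err(zumbach_test(x, window = 2)$statistic,
                      oracle_zumbach_stat(x, 2)), 1e-10)
  }
})

test_that("BDS correlation integrals match brute-force enumeration", {
  set.seed(102)
  for (i in 1:5) {
    x <- fixture_series(60, seed = 2000 + i)  # cubic oracle: keep n small
    eps <- 0.4 * sd(x)
    fast <- irrev:::cpp_bds_integrals(x, 2L, eps)
    slow <- oracle_bds_integrals(x, 2, eps)
    expect_lt(rel_err(fast$C1, slow$C1), 1e-10)
    expect_lt(rel_err(fast$Cm, slow$Cm), 1e-10)
    expect_lt(rel_err(fast$K, slow$K), 1e-10)
  }
})

test_that("the stack-based dHVG matches the definitional O(n^2) construction", {
  set.seed(103)
  for (i in 1:10) {
    x <- fixture_series(200, seed = 3000 + i)
    fast <- irrev:::hvg_degrees(x)
    slow <- oracle_hvg_degrees(x)
    expect_identical(fast$out, slow$out)
    expect_identical(fast$`in`, slow$`in`)
  }
  # with ties (plateaus block visibility)
  y <- c(1, 3, 3, 2, 5, 2, 2, 4, 1, 5, 5, 3)
  expect_identical(irrev:::hvg_degrees(y)$out, oracle_hvg_degrees(y)$out)
  cc_fast <- irrev:::hvg_clustering(y)
  cc_slow <- oracle_hvg_clustering(y)
  expect_equal(cc_fast$retarded, cc_slow$retarded)
  expect_equal(cc_fast$advanced, cc_slow$advanced)
})

test_that("matrix-based window fits match per-window lm fits", {
  set.seed(104)
  for (i in 1:5) {
    x <- fixture_series(200, seed = 4000 + i)
    expect_lt(max(rel_err(irrev:::mstrends_slopes(x, 7, 1),
                          oracle_slopes(x, 7, 1))), 1e-9)
    expect_lt(max(rel_err(irrev:::mstrends_slopes(x, 9, 2),
                          oracle_slopes(x, 9, 2))), 1e-9)
  }
})

test_that("vectorised ordinal pattern counting matches rank-based enumeration", {
  set.seed(105)
  for (i in 1:10) {
    x <- fixture_series(200, seed = 5000 + i)
    fast <- ordinal_pattern_counts(x, 3)
    slow <- oracle_ordinal_counts(x, 3)
    expect_equal(as.vector(fast[order(names(fast))]),
                 as.vector(slow[order(names(slow))]))
    expect_equal(sort(names(fast)), sort(names(slow)))
  }
})

test_that("vectorised COP distances match the per-window loop", {
  set.seed(106)
  for (i in 1:5) {
    x <- fixture_series(200, seed = 6000 + i)
    W <- irrev:::sliding_windows(x, 4)
    Z <- irrev:::normalise_windows(W)$Z
    pat <- irrev:::random_cop(4)
    fast <- irrev:::cop_distances(Z, pat)
    slow <- vapply(seq_len(nrow(W)),
                   function(r) oracle_cop_distance(W[r, ], pat), numeric(1))
    expect_lt(max(rel_err(fast, slow)), 1e-10)
  }
})

test_that("the C++ Diks U-statistic matches the naive kernel double loop", {
  set.seed(107)
  for (i in 1:5) {
    x <- fixture_series(200, seed = 7000 + i)
    starts <- seq(1, length(x) - 2, by = 3)
    X <- matrix(x[outer(starts - 1L, 1:3, `+`)], ncol = 3)
    h <- sd(x) * 0.8
    fast <- irrev:::cpp_diks(X, h, 2L)
    expect_lt(rel_err(fast$Q, oracle_diks_q(X, h)), 1e-10)
  }
})

test_that("the Markov entropy-production estimator matches the naive loops", {
  set.seed(108)
  for (i in 1:5) {
    codes <- sample.int(3, 500, replace = TRUE)
    expect_lt(rel_err(irrev:::gaspard_statistic(codes, 3L),
                      oracle_gaspard(codes, 3)), 1e-10)
  }
})
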