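test_that("downsampling methods match the worked examples", {
  expect_equal(downsample(c(1, 3, 2, 4), 2, "average"), c(2, 3))
  expect_equal(downsample(c(1, 3, 2, 4), 2, "skip"), c(1, 2))
  x <- rnorm(101)
  expect_identical(downsample(x, 1, "skip"), x)
  expect_identical(downsample(x, 1, "average"), x)
  expect_identical(downsample(x, 1, "decimate"), x)
  # output length floor(N / tau) for every method
  for (tau in c(2, 3, 7)) {
    for (m in c("average", "skip", "decimate")) {
      expect_length(downsample(x, tau, m), floor(101 / tau))
    }
  }
  expect_error(downsample(x, 200), "exceeds")
  # decimation of a pure low-frequency tone survives coarse sampling
  t <- seq_len(400)
  tone <- sin(2 * pi * t / 100)
  dec <- downsample(tone, 2, "decimate")
  expect_equal(dec, sin(2 * pi * (2 * seq_len(200) - 1) / 100),
               tolerance = 0.05)
})

test_that("parameter optimisation returns grid members and honours Fisher's method", {
  set.seed(71)
  ens <- lapply(1:4, function(i) generate_logistic(600))
  # degenerate single-combination grid: that combination is returned
  r1 <- optimise_parameters("MSTrends", ens, grid = list(window = 5))
  expect_equal(r1$best_params$window, 5)
  # Fisher closed form: combined p = upper chi-square tail of -2 sum(log p)
  ps <- vapply(ens, function(s) mstrends_test(s, window = 5)$pvalue, numeric(1))
  expect_equal(r1$best_log_pvalue,
               pchisq(-2 * sum(log(pmax(ps, 1e-300))), df = 2 * length(ps),
                      lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
  # superset grids can only improve the best combined p-value
  r2 <- optimise_parameters("MSTrends", ens, grid = list(window = c(3, 5)))
  expect_lte(r2$best_log_pvalue, r1$best_log_pvalue)
  expect_true(r2$best_params$window %in% c(3, 5))
  expect_error(optimise_parameters("MSTrends", list()), "empty ensemble")
  expect_error(optimise_parameters("TPLength", ens), "no parameter grid")
})

test_that("median combination is available as a robust alternative", {
  set.seed(72)
  ens <- lapply(1:3, function(i) generate_logistic(600))
  r <- optimise_parameters("MSTrends", ens, grid = list(window = 5),
                           combine = "median")
  ps <- vapply(ens, function(s) mstrends_test(s, window = 5)$pvalue, numeric(1))
  expect_equal(r$best_pvalue, median(ps), tolerance = 1e-12)
})

test_that("manipulation is reproducible, bounded, and honours its threshold contract", {
  set.seed(73)
  x <- runif(2000)
  # single-candidate run under a fixed seed is deterministic
  m1 <- suppressWarnings(manipulate(x, increase = TRUE, numIterations = 1,
                                    pSize = 4, pvThreshold = 1, seed = 5))
  m2 <- suppressWarnings(manipulate(x, increase = TRUE, numIterations = 1,
                                    pSize = 4, pvThreshold = 1, seed = 5))
  expect_identical(m1$series, m2$series)
  expect_identical(m1$pvalue, m2$pvalue)
  expect_lte(abs(m1$correlation), 1)
  expect_length(m1$series, length(x) - 4 + 1)
  # increase mode never reports success above the threshold
  m3 <- suppressWarnings(manipulate(x, increase = TRUE, numIterations = 50,
                                    pSize = 4, pvThreshold = 0.01, seed = 6))
  if (m3$success) expect_lte(m3$pvalue, 0.01)
  # an unreachable threshold yields an explicit failure, not an exception
  m4 <- suppressWarnings(manipulate(x, increase = TRUE, numIterations = 3,
                                    pSize = 4, pvThreshold = 1e-300, seed = 7))
  expect_false(m4$success)
  expect_true(is.finite(m4$pvalue))
})

test_that("generators honour their invariants and seeds", {
  x <- generate_logistic(500, seed = 1)
  expect_true(all(x >= 0 & x <= 1))
  expect_identical(x, generate_logistic(500, seed = 1))
  expect_error(generate_logistic(10, r = 5), "r must")
  expect_error(generate_logistic(10, x0 = 0.5), "x0")
  expect_error(generate_logistic(10, x0 = 1.2), "x0")

  h <- generate_henon(500, seed = 2)
  expect_true(all(is.finite(h)))

  l <- generate_lcg(500, seed = 3)
  expect_true(all(l >= 0 & l < 1))

  lz <- generate_lorenz(300, seed = 4)
  expect_true(all(is.finite(lz)))
  expect_gt(sd(lz), 1)

  ou <- generate_ou(5000, seed = 5)
  expect_lt(abs(mean(ou)), 0.3)
  expect_identical(ou, generate_ou(5000, seed = 5))
  expect_error(generate_ou(10, theta = -1), "positive")

  g <- generate_srgbm(1000, seed = 6)
  expect_true(all(g > 0))

  w <- generate_weierstrass_asym(400)
  expect_length(w, 400)
  expect_error(generate_weierstrass_asym(100, gamma = 1.2), "gamma")

  ms <- generate_multiscale_irrev(600, tau_star = 5, seed = 7)
  expect_length(ms, 600)

  sw <- generate_symbolic_walk(200, alphabet = letters[1:4], seed = 8)
  expect_true(all(sw %in% letters[1:4]))
  expect_identical(sw, generate_symbolic_walk(200, alphabet = letters[1:4],
                                              seed = 8))
})

test_that("known processes behave as expected under the tests", {
  # srGBM: resetting breaks detailed balance; strongly irreversible
  # (slow multiplicative growth, abrupt resets -> skewed increments)
  g <- generate_srgbm(5000, seed = 16)
  expect_lt(casali_test(g, plan = surrogate_plan("zscore", seed = 1))$pvalue,
            0.01)
  expect_lt(costa_test(g, plan = surrogate_plan("zscore", seed = 2))$pvalue,
            0.05)
  # multiscale model: invisible at native scale, exposed at tau*, gone far above
  ms <- generate_multiscale_irrev(20000, tau_star = 5, seed = 17)
  p_tau <- suppressWarnings(
    cop_test(downsample(ms, 5, "average"), seed = 2)$pvalue)
  p_far <- suppressWarnings(
    cop_test(downsample(ms, 50, "average"), seed = 3)$pvalue)
  expect_lt(p_tau, 0.01)
  expect_gt(p_far, 0.01)
})
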