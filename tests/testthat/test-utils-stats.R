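# Statistical building blocks validated against independent references:
# the Epps-Singleton and skewness-test values below were computed with
# scipy.stats (epps_singleton_2samp, skewtest) on the same fixtures.

test_that("Epps-Singleton matches reference values on continuous samples", {
  x <- c(-1.423825, 1.263728, -0.870662, -0.259173, -0.075343, -0.740885,
         -1.367793, 0.648893, 0.361058, -1.952863, 2.34741, 0.968497,
         -0.759387, 0.902198, -0.466953, -0.06069, 0.788844, -1.256668,
         0.575858, 1.398979, 1.322298, -0.299699, 0.902919, -1.621583,
         -0.158189, 0.449484, -1.343601, -0.081688, 1.72474, 2.618159)
  y <- c(1.51057, 1.577223, -0.746685, -1.072205, -1.33598, 1.204011,
         1.477521, -0.356388, -1.097277, 0.834825, 0.906774, 0.329945,
         2.150978, 0.379149, 0.414004, -0.940679, 0.676744, 2.251201,
         0.579487, 0.592189, 1.063751, 0.860729, 1.189328, 1.197737,
         1.303855, -0.533523, 0.89004, -1.583512, 0.846838, -1.140111,
         0.407348, 1.116265, -0.03931, 0.627031, -1.632543, -0.614436,
         1.394766, -1.000888, 1.345588, -1.304868)
  es <- irrev:::epps_singleton_test(x, y)
  expect_equal(es$statistic, 5.053042838319583, tolerance = 1e-10)
  expect_equal(es$pvalue, 0.281898143165414, tolerance = 1e-10)
})

test_that("Epps-Singleton matches reference values on tied discrete samples", {
  a <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 4, 5, 1, 2, 2, 2, 3, 4, 4, 5, 6)
  b <- c(1, 2, 2, 2, 3, 3, 4, 4, 4, 4, 5, 5, 6, 6, 1, 1, 2, 3, 3, 2)
  es <- irrev:::epps_singleton_test(a, b)
  expect_equal(es$statistic, 0.3527414885017884, tolerance = 1e-10)
  expect_equal(es$pvalue, 0.9861599802744072, tolerance = 1e-10)
  expect_error(irrev:::epps_singleton_test(rep(1, 10), rep(1, 12)),
               "degenerate")
})

test_that("D'Agostino skewness test matches the reference transformation", {
  z <- c(0.748256, 1.675909, 0.63463, 4.759919, 0.819728, 1.394301, 0.257153,
         1.032817, 0.6361, 2.830605, 1.528142, 3.101095, 2.103354, 1.244323,
         0.705136, 1.370466, 1.474169, 1.336064, 1.51124, 1.941283, 5.372664,
         1.542802, 2.22646, 4.334886, 1.782477, 0.822892, 3.653577, 1.736105,
         1.713238, 0.596651, 1.175847, 4.742234, 1.36106, 2.058006, 3.574931,
         0.85226, 3.848747, 1.903434, 1.972047, 0.141469, 2.569521, 0.777495,
         1.726343, 0.530085, 0.719711, 1.576809, 1.635117, 0.930474, 3.572356,
         1.562519, 3.831441, 2.247506, 2.06877, 4.200088, 2.634163, 4.13722,
         2.207745, 0.57342, 1.480098, 0.625427)
  expect_equal(sample_skewness(z), 0.9528759377418861, tolerance = 1e-10)
  sk <- irrev:::dagostino_skew_test(z)
  expect_equal(sk$statistic, 2.9272968629056306, tolerance = 1e-9)
  expect_equal(sk$pvalue, 0.0034192234143216806, tolerance = 1e-9)
  expect_error(irrev:::dagostino_skew_test(rnorm(5)), "n >= 8")
})

test_that("the fast two-sample KS agrees with stats::ks.test", {
  set.seed(91)
  for (i in 1:10) {
    a <- rnorm(sample(50:300, 1))
    b <- rnorm(sample(50:300, 1), mean = runif(1, -0.5, 0.5))
    ours <- irrev:::ks2_test(a, b)
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$pvalue, ref$p.value, tolerance = 1e-4)
  }
})

test_that("long-run variance estimators recover the iid case", {
  set.seed(92)
  u <- rnorm(2000)
  v_iid <- var(u) / length(u)
  expect_equal(irrev:::hac_var_of_mean(u, 0), v_iid, tolerance = 0.01)
  expect_equal(irrev:::flat_var_of_mean(u, 0), v_iid, tolerance = 0.01)
  # strong negative MA(1) dependence: flat-top captures it, Bartlett lags
  d <- diff(rnorm(4001))
  vf <- irrev:::flat_var_of_mean(d, 5) * length(d)
  # true long-run variance of mean(diff) is ~ 2 sigma^2 / n^2 * n -> ~ 0
  expect_lt(vf, 0.2 * var(d))
})
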