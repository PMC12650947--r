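#' Sample skewness
#'
#' Moment-ratio estimator `g1 = m3 / m2^(3/2)` with biased central moments,
#' the convention used throughout the package.
#'
#' @param x numeric vector.
#' @return the sample skewness (scalar).
#' @export
sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  d <- x - m
  m2 <- sum(d^2) / n
  if (m2 == 0) stop("zero variance: skewness undefined", call. = FALSE)
  (sum(d^3) / n) / m2^1.5
}

# D'Agostino (1970) test of zero skewness: transforms g1 to an approximately
# standard-normal Z. Returns list(statistic = Z, pvalue = two-sided p).
# Requires n >= 8 for the approximation to make sense.
dagostino_skew_test <- function(x) {
  n <- length(x)
  if (n < 8) stop("skewness test needs n >= 8", call. = FALSE)
  g1 <- sample_skewness(x)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * asinh(y / alpha)
  list(statistic = z, pvalue = 2 * stats::pnorm(-abs(z)), skewness = g1)
}

# Epps-Singleton (1986) two-sample test based on the empirical characteristic
# function, with the small-sample covariance correction; W2 ~ chi-square with
# 2 * length(t) d.o.f. `t` values are scaled by the semi-interquartile range
# of the pooled sample, following the original construction.
epps_singleton_test <- function(x, y, t = c(0.4, 0.8)) {
  nx <- length(x); ny <- length(y)
  if (nx < 5 || ny < 5) stop("Epps-Singleton needs at least 5 per sample",
                             call. = FALSE)
  pooled <- c(x, y)
  sigma <- (stats::quantile(pooled, 0.75, names = FALSE) -
            stats::quantile(pooled, 0.25, names = FALSE)) / 2
  if (sigma <= 0) sigma <- stats::sd(pooled)  # heavily tied samples
  if (sigma <= 0) stop("degenerate pooled sample (zero spread)", call. = FALSE)
  ts <- t / sigma
  gfun <- function(v) {
    # rows: observations; cols: cos(t1 v), sin(t1 v), cos(t2 v), sin(t2 v), ...
    out <- matrix(0, length(v), 2L * length(ts))
    for (j in seq_along(ts)) {
      out[, 2L * j - 1L] <- cos(ts[j] * v)
      out[, 2L * j] <- sin(ts[j] * v)
    }
    out
  }
  gx <- gfun(x); gy <- gfun(y)
  mx <- colMeans(gx); my <- colMeans(gy)
  # covariance of the difference of means, per-sample empirical covariances
  cx <- stats::cov(gx) * (nx - 1) / nx
  cy <- stats::cov(gy) * (ny - 1) / ny
  omega <- cx / nx + cy / ny
  d <- mx - my
  # use a pseudo-inverse for near-singular omega (heavily tied samples)
  eg <- eigen(omega, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos)) stop("degenerate characteristic-function covariance",
                      call. = FALSE)
  oinv <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  w2 <- drop(t(d) %*% oinv %*% d)
  df <- sum(pos)
  # small-sample correction, per the original construction (small samples only)
  if (max(nx, ny) < 25) {
    n <- nx + ny
    w2 <- w2 / (1 + n^(-0.45) + 10.1 * (nx^(-1.7) + ny^(-1.7)))
  }
  list(statistic = w2, pvalue = stats::pchisq(w2, df, lower.tail = FALSE),
       df = df)
}

# Two-sample Kolmogorov-Smirnov via the C++ kernel; asymptotic p-value
# (Kolmogorov distribution at sqrt(n_e) * D).
ks2_test <- function(x, y) {
  r <- cpp_ks2(as.numeric(x), as.numeric(y))
  list(statistic = r[["D"]], pvalue = r[["p"]])
}

# Bartlett-kernel (Newey-West) long-run variance of the MEAN of a series:
# Var(mean(u)) ~ (gamma0 + 2 sum w_j gamma_j) / n. `lags = 0` reduces to the
# iid formula. Used by the HAC-corrected native tests.
hac_var_of_mean <- function(u, lags) {
  n <- length(u)
  u <- u - mean(u)
  g0 <- sum(u^2) / n
  s <- g0
  if (lags > 0) {
    for (j in seq_len(min(lags, n - 1))) {
      gj <- sum(u[(j + 1):n] * u[1:(n - j)]) / n
      s <- s + 2 * (1 - j / (lags + 1)) * gj
    }
  }
  max(s, 0) / n
}

# Flat-top (truncated, unweighted) long-run variance of the mean: unbiased
# when the dependence range is below `lags`, at the price of occasional
# negative estimates (returned as-is; callers must guard). Suits streams with
# strong negative autocovariances that Bartlett downweighting misses.
flat_var_of_mean <- function(u, lags) {
  n <- length(u)
  u <- u - mean(u)
  s <- sum(u^2) / n
  if (lags > 0) {
    for (j in seq_len(min(lags, n - 1))) {
      s <- s + 2 * sum(u[(j + 1):n] * u[1:(n - j)]) / n
    }
  }
  s / n
}

# Chi-square-type statistic over count pairs (a_t vs b_t indicator streams):
# for each pair, z^2 = (sum d_t)^2 / Var(sum d_t) with d_t = a_t - b_t and a
# long-run variance estimate (Bartlett HAC by default; flat-top for streams
# with strong negative autocovariances, falling back to Bartlett when the
# flat-top estimate is non-positive). Returns the summed statistic and the
# number of contributing pairs (df).
paired_count_chisq <- function(ind_a, ind_b, lags,
                               estimator = c("bartlett", "flat")) {
  # ind_a, ind_b: list of 0/1 integer vectors, one per pattern pair
  estimator <- match.arg(estimator)
  stat <- 0
  df <- 0L
  for (k in seq_along(ind_a)) {
    d <- ind_a[[k]] - ind_b[[k]]
    tot <- sum(ind_a[[k]]) + sum(ind_b[[k]])
    if (tot == 0) next
    vm <- if (estimator == "flat") {
      v0 <- flat_var_of_mean(d, lags)
      if (v0 <= 0) hac_var_of_mean(d, lags) else v0
    } else hac_var_of_mean(d, lags)
    v <- vm * length(d)^2  # Var(sum d)
    if (v <= 0) next
    stat <- stat + sum(d)^2 / v
    df <- df + 1L
  }
  list(statistic = stat, df = df)
}

# Sliding windows of length w (step 1) as a matrix with one window per row.
sliding_windows <- function(x, w) {
  n <- length(x)
  if (n < w) stop("series shorter than window", call. = FALSE)
  matrix(x[outer(seq_len(n - w + 1L) - 1L, seq_len(w), `+`)], ncol = w)
}

# Normalise window rows: subtract row mean, divide by max absolute deviation.
# Constant rows are flagged (returned in `constant`), left as zero rows.
normalise_windows <- function(W) {
  m <- rowMeans(W)
  Z <- W - m
  s <- apply(abs(Z), 1L, max)
  constant <- s == 0
  s[constant] <- 1
  list(Z = Z / s, constant = constant)
}
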