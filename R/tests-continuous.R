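# The sixteen irreversibility tests for real-valued series. All share the
# same contract: input a finite numeric series of sufficient length, output
# an `irrev_result` holding exactly (pvalue, statistic). Tests whose original
# construction yields only a measure (Casali, Costa, Pomeau) are wrapped in
# the shuffled-surrogate machinery; the rest return a native p-value.


# Signed measure helpers shared by the surrogate-wrapped tests (and exposed
# internally for oracle checks).
casali_statistic <- function(z, m = 1) {
  d <- z[(1 + m):length(z)] - z[1:(length(z) - m)]
  sample_skewness(d)
}

costa_statistic <- function(z) {
  d <- diff(z)
  nu <- sum(d > 0)
  nd <- sum(d < 0)
  if (nu + nd == 0) stop("constant series: no increments", call. = FALSE)
  (nu - nd) / (nu + nd)
}

pomeau_statistic <- function(z) {
  n <- length(z)
  mean(z[-n] * z[-1]^2 - z[-n]^2 * z[-1])
}

# Per-term lag-k bicovariance differences x_i^2 x_(i-k) - x_i x_(i-k)^2.
ramsey_terms <- function(x, k) {
  n <- length(x)
  x[(k + 1):n]^2 * x[1:(n - k)] - x[(k + 1):n] * x[1:(n - k)]^2
}

# Ternary increment symbolisation: strong rises (+1), strong drops (-1),
# maintaining (0) below the absolute threshold.
ternary_symbols <- function(d, thr) {
  ifelse(abs(d) < thr, 0L, ifelse(d > 0, 1L, -1L))
}

#' BDS test
#'
#' Brock-Dechert-Scheinkman test: the sample correlation integral at embedding
#' dimension `m` is compared with the `m`-th power of the one at dimension 1;
#' under an iid null the normalised difference is asymptotically N(0,1).
#' Originally a test of iid-ness (significance may reflect low-dimensional
#' chaos or any serial dependence, not specifically time asymmetry).
#'
#' @param x numeric series (N >= 200).
#' @param m embedding dimension (>= 2).
#' @param epsilon neighbourhood radius; default `0.5 * sd(x)`.
#' @return an `irrev_result`; statistic is the standardised difference.
#' @export
bds_test <- function(x, m = 2, epsilon = NULL) {
  x <- as_real_series(x, min_n = 200L, require_var = TRUE)
  m <- as.integer(m)
  if (m < 2L) stop("embedding dimension m must be >= 2", call. = FALSE)
  if (is.null(epsilon)) epsilon <- 0.5 * stats::sd(x)
  if (epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  ci <- cpp_bds_integrals(x, m, epsilon)
  C <- ci$C1; Cm <- ci$Cm; K <- ci$K; M <- ci$M
  if (C == 0) stop("epsilon too small: no pairs within radius", call. = FALSE)
  j <- seq_len(m - 1)
  V <- 4 * (K^m + 2 * sum(K^(m - j) * C^(2 * j)) +
            (m - 1)^2 * C^(2 * m) - m^2 * K * C^(2 * m - 2))
  if (V <= 0) stop("degenerate BDS variance", call. = FALSE)
  w <- sqrt(M) * (Cm - C^m) / sqrt(V)
  irrev_result(2 * stats::pnorm(-abs(w)), w, "BDS",
               params = list(m = m, epsilon = epsilon))
}

#' Casali test
#'
#' Skewness of the distribution of lag-`m` increments `x[i+m] - x[i]`: a
#' skewed increment distribution is a signature of time asymmetry.
#' Significance via shuffled surrogates (the skewness magnitude is compared
#' to the shuffled ensemble).
#'
#' @param x numeric series (N >= 50).
#' @param m lag between compared points.
#' @param plan a [surrogate_plan()]; default Z-score with 20 surrogates.
#' @return an `irrev_result`; statistic is the signed increment skewness.
#' @export
casali_test <- function(x, m = 1, plan = surrogate_plan("zscore")) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  m <- as.integer(m)
  if (m < 1L || m >= length(x)) stop("invalid lag m", call. = FALSE)
  stat_fun <- function(z) casali_statistic(z, m)
  res <- surrogate_test(function(z) abs(stat_fun(z)), x, plan,
                        statistic = stat_fun(x))
  irrev_result(res$pvalue, res$statistic, "Casali",
               params = list(m = m, method = plan$method, S = plan$S))
}

# Distance profile of a normalised pattern against every (already normalised)
# sliding window; rows of Z are the windows.
cop_distances <- function(Z, pattern) {
  D <- abs(Z - matrix(pattern, nrow(Z), length(pattern), byrow = TRUE))
  rowMeans(D)
}

# Draw a random continuous ordinal pattern: standard-normal values normalised
# to zero mean and unit maximum absolute deviation.
random_cop <- function(pSize) {
  repeat {
    p <- stats::rnorm(pSize)
    p <- p - mean(p)
    s <- max(abs(p))
    if (s > 0) return(p / s)
  }
}

#' Continuous Ordinal Patterns (COP) test
#'
#' For each of `nPatterns` random normalised reference patterns, the series
#' and its time-reversed version are transcribed into sequences of distances
#' between the pattern and every normalised sliding window; the two distance
#' samples are compared with a two-sample Kolmogorov-Smirnov test. The
#' reported p-value is the smallest per-pattern p, Bonferroni-corrected for
#' the number of patterns; the statistic is the largest KS distance.
#'
#' @param x numeric series (N >= 100).
#' @param pSize pattern length (>= 2).
#' @param nPatterns number of random patterns tested.
#' @param seed RNG seed for the pattern draws.
#' @return an `irrev_result`.
#' @export
cop_test <- function(x, pSize = 3, nPatterns = 100, seed = NULL) {
  x <- as_real_series(x, min_n = 100L, require_var = TRUE)
  pSize <- as.integer(pSize)
  if (pSize < 2L) stop("pSize must be >= 2", call. = FALSE)
  if (length(x) < pSize + 30L) stop("series too short for pSize", call. = FALSE)
  W <- sliding_windows(x, pSize)
  nw <- normalise_windows(W)
  if (any(nw$constant)) {
    warning(sprintf("%d constant window(s) skipped", sum(nw$constant)))
  }
  Z <- nw$Z[!nw$constant, , drop = FALSE]
  Zb <- Z[, pSize:1, drop = FALSE]  # windows of the time-reversed series
  if (nrow(Z) < 30L) stop("too few non-constant windows", call. = FALSE)
  patterns <- with_local_seed(seed,
    lapply(seq_len(nPatterns), function(i) random_cop(pSize)))
  # Overlapping windows are serially dependent (inflating the KS effective
  # sample size), and forward/backward distances of the same window are not
  # independent samples. Compare distances over non-overlapping windows,
  # interleaved between the two sides, so the KS two-sample assumptions
  # approximately hold while slow nonstationarity cannot masquerade as
  # irreversibility.
  sel <- seq(1L, nrow(Z), by = pSize)
  sel_f <- sel[seq(1L, length(sel), by = 2L)]
  sel_b <- sel[seq(2L, length(sel), by = 2L)]
  best_D <- 0
  min_p <- 1
  for (p in patterns) {
    df_ <- cop_distances(Z, p)[sel_f]
    db_ <- cop_distances(Zb, p)[sel_b]
    ks <- ks2_test(df_, db_)
    if (ks$statistic > best_D) best_D <- ks$statistic
    if (ks$pvalue < min_p) min_p <- ks$pvalue
  }
  irrev_result(min(1, nPatterns * min_p), best_D, "COP",
               params = list(pSize = pSize, nPatterns = nPatterns, seed = seed))
}

#' Costa index (continuous version)
#'
#' Compares the number of increases and decreases of the series, ignoring
#' their amplitude: statistic `(N_up - N_down) / (N_up + N_down)`.
#' Significance via shuffled surrogates on the magnitude.
#'
#' @param x numeric series (N >= 50).
#' @param plan a [surrogate_plan()].
#' @return an `irrev_result`; statistic is the signed up/down asymmetry.
#' @export
costa_test <- function(x, plan = surrogate_plan("zscore")) {
  x <- as_real_series(x, min_n = 50L)
  res <- surrogate_test(function(z) abs(costa_statistic(z)), x, plan,
                        statistic = costa_statistic(x))
  irrev_result(res$pvalue, res$statistic, "Costa Index",
               params = list(method = plan$method, S = plan$S))
}

# Equal-probability (empirical quantile) symbolisation into nSymbols bins.
symbolise_quantile <- function(x, nSymbols) {
  br <- stats::quantile(x, probs = seq(0, 1, length.out = nSymbols + 1),
                        names = FALSE, type = 7)
  br <- unique(br)
  if (length(br) < 3) stop("too many ties to symbolise", call. = FALSE)
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)) - 1L
}

symbolise_width <- function(x, nSymbols) {
  br <- seq(min(x), max(x), length.out = nSymbols + 1)
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)) - 1L
}

# Chi-square comparison over (word, reversed word) count pairs from a coded
# symbol stream. Words of length L are read with step 1; each pair's count
# difference is studentised with a Bartlett HAC variance (overlapping words
# are serially dependent). Returns statistic, df, p.
word_reversal_chisq <- function(sym, K, L, lags) {
  n <- length(sym)
  if (n < L + 10L) stop("series too short for word counting", call. = FALSE)
  nw <- n - L + 1L
  pw <- K^(0:(L - 1L))
  codes <- integer(nw)
  rcodes <- integer(nw)
  for (l in seq_len(L)) {
    s <- sym[l:(nw + l - 1L)]
    codes <- codes + s * pw[l]
    rcodes <- rcodes + s * pw[L - l + 1L]
  }
  present <- unique(c(codes, rcodes))
  ind_a <- list(); ind_b <- list()
  done <- integer(0)
  for (cd in present) {
    rc <- rev_code(cd, K, L)
    if (cd >= rc) next  # palindromes (cd == rc) carry no asymmetry
    ind_a[[length(ind_a) + 1L]] <- as.integer(codes == cd)
    ind_b[[length(ind_b) + 1L]] <- as.integer(codes == rc)
    done <- c(done, cd)
  }
  if (!length(ind_a)) return(list(statistic = 0, df = 0L, pvalue = 1))
  r <- paired_count_chisq(ind_a, ind_b, lags)
  p <- if (r$df == 0L) 1 else stats::pchisq(r$statistic, r$df,
                                            lower.tail = FALSE)
  list(statistic = r$statistic, df = r$df, pvalue = p)
}

rev_code <- function(code, K, L) {
  digs <- integer(L)
  for (l in seq_len(L)) {
    digs[l] <- code %% K
    code <- code %/% K
  }
  sum(rev(digs) * K^(0:(L - 1L)))
}

#' Daw-Finney-Kennel (DFK) test
#'
#' Symbolises the series (equal-probability bins by default), merges symbols
#' into overlapping words, and compares the frequency of each word with that
#' of its time-reversed counterpart through a HAC-studentised chi-square
#' statistic.
#'
#' The default is the original binary partition. Note that a binary alphabet
#' makes the test structurally conservative: in any binary sequence the
#' counts of a word and of its reversal are nearly balanced (each maximal
#' run contributes one boundary occurrence of each), so detection power only
#' appears for `nSymbols >= 3` — which is what parameter optimisation finds.
#'
#' @param x numeric series (N >= 50).
#' @param nSymbols alphabet size for the symbolisation (default 2).
#' @param wordLength word length.
#' @param binning `"quantile"` (equal-probability) or `"width"` (equal-width).
#' @return an `irrev_result`.
#' @export
dfk_test <- function(x, nSymbols = 2, wordLength = 3,
                     binning = c("quantile", "width")) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  binning <- match.arg(binning)
  nSymbols <- as.integer(nSymbols); wordLength <- as.integer(wordLength)
  sym <- if (binning == "quantile") symbolise_quantile(x, nSymbols)
         else symbolise_width(x, nSymbols)
  K <- max(sym) + 1L
  nwords <- length(x) - wordLength + 1L
  if (nwords / K^wordLength < 5) {
    warning("fewer than 5 expected counts per word; p-value unreliable")
  }
  r <- word_reversal_chisq(sym, K, wordLength, lags = wordLength)
  irrev_result(r$pvalue, r$statistic, "DFK",
               params = list(nSymbols = nSymbols, wordLength = wordLength,
                             binning = binning),
               extra = list(df = r$df))
}

#' Diks test
#'
#' Compares the cloud of `m`-dimensional delay vectors of the series with the
#' cloud obtained from the time-reversed series, through a Gaussian-kernel
#' two-sample U-statistic. The kernel U-statistic is degenerate under the
#' null (the delay-vector law is reversal-symmetric), so significance comes
#' from an exact sign-flip randomisation: under reversibility each pair
#' (vector, reversed vector) is exchangeable, and the null distribution is
#' sampled by swapping pairs with fair coin flips. Delay vectors are taken
#' non-overlapping to limit serial dependence, and at most `max_vectors` of
#' them (evenly spaced) are used.
#'
#' @param x numeric series (N >= 10 m, and >= 200 by default policy).
#' @param m embedding dimension.
#' @param bandwidth Gaussian kernel bandwidth; Silverman-type default.
#' @param B randomisation replicates; the smallest attainable p is 1/(B+1).
#' @param seed RNG seed for the randomisation.
#' @param max_vectors cap on the number of delay vectors.
#' @return an `irrev_result`; statistic is the U-statistic standardised by
#'   the randomisation-null spread.
#' @export
diks_test <- function(x, m = 3, bandwidth = NULL, B = 200, seed = NULL,
                      max_vectors = 1000) {
  m <- as.integer(m)
  x <- as_real_series(x, min_n = max(200L, 10L * m), require_var = TRUE)
  starts <- seq(1L, length(x) - m + 1L, by = m)
  if (length(starts) > max_vectors) {
    starts <- starts[unique(round(seq(1, length(starts),
                                      length.out = max_vectors)))]
  }
  X <- matrix(x[outer(starts - 1L, seq_len(m), `+`)], ncol = m)
  M <- nrow(X)
  if (is.null(bandwidth)) {
    bandwidth <- stats::sd(x) * (4 / (m + 2))^(1 / (m + 4)) * M^(-1 / (m + 4))
  }
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  r <- with_local_seed(seed, cpp_diks(X, bandwidth, as.integer(B)))
  p <- (1 + sum(r$Qnull >= r$Q)) / (B + 1)
  s <- stats::sd(r$Qnull)
  z <- if (s > 0) (r$Q - mean(r$Qnull)) / s else 0
  irrev_result(p, z, "Diks",
               params = list(m = m, bandwidth = bandwidth, B = B),
               extra = list(Q = r$Q))
}

#' Local clustering coefficient test
#'
#' Builds the directed horizontal visibility graph and compares, across
#' nodes, the retarded (past-neighbour) and advanced (future-neighbour)
#' local clustering coefficients with an Epps-Singleton two-sample test.
#'
#' @param x numeric series (N >= 50).
#' @return an `irrev_result`.
#' @export
local_clustering_test <- function(x) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  cc <- hvg_clustering(x)
  a <- cc$retarded; b <- cc$advanced
  if (stats::var(c(a, b)) == 0) {
    # e.g. monotone series: the dHVG is triangle-free on both sides
    return(irrev_result(1, 0, "Local CC"))
  }
  es <- epps_singleton_test(a, b)
  irrev_result(es$pvalue, es$statistic, "Local CC",
               extra = list(df = es$df))
}

# Leading polynomial coefficient of a least-squares fit on every stride-1
# window; degree 1 gives the ordinary slope.
mstrends_slopes <- function(x, window, degree = 1) {
  W <- sliding_windows(x, window)
  tt <- seq_len(window)
  A <- outer(tt, 0:degree, `^`)
  # row of the pseudo-inverse extracting the leading coefficient
  q <- solve(crossprod(A), t(A))[degree + 1L, ]
  drop(W %*% q)
}

#' Multiscale trends (MSTrends) test
#'
#' Fits a polynomial of the stated degree on short sub-windows and compares
#' the distribution of leading coefficients of the series against that of its
#' time-reversed version. The compared samples are taken from alternating
#' disjoint blocks (forward fits on odd blocks, reversed fits on even blocks)
#' so that the two-sample Kolmogorov-Smirnov comparison is between
#' (asymptotically) independent samples.
#'
#' @param x numeric series (N >= 6 * window).
#' @param window sub-window length; the default 3 is the shortest window with
#'   a redundant observation per linear fit, which maximises the number of
#'   independent blocks and keeps the test sensitive to short-memory dynamics.
#' @param degree polynomial degree; the leading coefficient is compared.
#' @return an `irrev_result`; statistic is the KS distance.
#' @export
mstrends_test <- function(x, window = 3, degree = 1) {
  window <- as.integer(window); degree <- as.integer(degree)
  x <- as_real_series(x, min_n = 6L * window, require_var = TRUE)
  if (window > length(x)) stop("window longer than series", call. = FALSE)
  nblk <- length(x) %/% window
  blocks <- matrix(x[seq_len(nblk * window)], nrow = window)
  tt <- seq_len(window)
  A <- outer(tt, 0:degree, `^`)
  q <- solve(crossprod(A), t(A))[degree + 1L, ]
  coefs_fwd <- drop(q %*% blocks)                       # forward fits
  coefs_bwd <- drop(q %*% blocks[window:1, , drop = FALSE])  # reversed fits
  odd <- seq(1L, nblk, by = 2L)
  even <- seq(2L, nblk, by = 2L)
  if (length(odd) < 5L || length(even) < 5L) {
    stop("too few blocks for the trend comparison", call. = FALSE)
  }
  ks <- ks2_test(coefs_fwd[odd], coefs_bwd[even])
  irrev_result(ks$pvalue, ks$statistic, "MSTrends",
               params = list(window = window, degree = degree))
}

# Ordinal pattern codes (0-based, mixed radix on ranks) for every stride-1
# window, with stable earlier-index-first tie breaking; also the code each
# window would take in the time-reversed series.
ordinal_codes <- function(x, pSize) {
  W <- sliding_windows(x, pSize)
  n <- nrow(W)
  R <- matrix(1L, n, pSize)
  for (l in seq_len(pSize)) {
    for (k in seq_len(pSize)) {
      if (k == l) next
      R[, l] <- R[, l] + (W[, k] < W[, l]) + if (k < l) (W[, k] == W[, l]) else 0L
    }
  }
  pw <- pSize^(0:(pSize - 1L))
  codes <- as.integer((R - 1L) %*% pw)
  rcodes <- as.integer((R - 1L)[, pSize:1, drop = FALSE] %*% pw)
  list(codes = codes, rcodes = rcodes)
}

#' Ordinal pattern counts
#'
#' Frequency of each ordinal (permutation) pattern over stride-1 windows,
#' with stable earlier-index-first tie breaking.
#'
#' @param x numeric series.
#' @param pSize pattern length.
#' @return named integer vector of counts; names are the rank sequences.
#' @export
ordinal_pattern_counts <- function(x, pSize = 3) {
  x <- as_real_series(x, min_n = pSize)
  oc <- ordinal_codes(x, as.integer(pSize))
  tab <- table(oc$codes)
  names(tab) <- vapply(as.integer(names(tab)), function(cd) {
    digs <- integer(pSize)
    for (l in seq_len(pSize)) { digs[l] <- cd %% pSize + 1L; cd <- cd %/% pSize }
    paste(digs, collapse = "")
  }, character(1))
  tab
}

#' Permutation patterns test
#'
#' Counts the ordinal pattern of every stride-1 window and compares the
#' frequency of each pattern with that of its time-reversed partner through a
#' HAC-studentised chi-square statistic (the HAC variance accounts for the
#' serial dependence of overlapping windows).
#'
#' @param x numeric series (N >= 50).
#' @param pSize pattern length (>= 2).
#' @return an `irrev_result`.
#' @export
perm_patterns_test <- function(x, pSize = 3) {
  pSize <- as.integer(pSize)
  x <- as_real_series(x, min_n = max(50L, pSize + 1L), require_var = TRUE)
  oc <- ordinal_codes(x, pSize)
  present <- unique(c(oc$codes, oc$rcodes))
  # map observed code -> its reversal via the rcodes of identical windows
  ind_a <- list(); ind_b <- list()
  seen <- integer(0)
  for (cd in present) {
    idx <- match(cd, oc$codes)
    rc <- if (is.na(idx)) {
      ridx <- match(cd, oc$rcodes)
      oc$codes[ridx]  # reversal is an involution
    } else oc$rcodes[idx]
    lo <- min(cd, rc); hi <- max(cd, rc)
    if (cd == rc || lo %in% seen) next
    seen <- c(seen, lo)
    ind_a[[length(ind_a) + 1L]] <- as.integer(oc$codes == lo)
    ind_b[[length(ind_b) + 1L]] <- as.integer(oc$codes == hi)
  }
  if (!length(ind_a)) return(irrev_result(1, 0, "Permutation Patterns",
                                          params = list(pSize = pSize)))
  r <- paired_count_chisq(ind_a, ind_b, lags = pSize)
  p <- if (r$df == 0L) 1 else stats::pchisq(r$statistic, r$df,
                                            lower.tail = FALSE)
  irrev_result(p, r$statistic, "Permutation Patterns",
               params = list(pSize = pSize), extra = list(df = r$df))
}

#' Pomeau test
#'
#' The canonical third-order time-asymmetric polynomial
#' `mean(x[t] * x[t+1]^2 - x[t]^2 * x[t+1])`, which changes sign under time
#' reversal and vanishes in expectation for any exchangeable series.
#' Significance via shuffled surrogates on the magnitude.
#'
#' @param x numeric series (N >= 3).
#' @param plan a [surrogate_plan()].
#' @return an `irrev_result`; statistic is the signed polynomial mean.
#' @export
pomeau_test <- function(x, plan = surrogate_plan("zscore")) {
  x <- as_real_series(x, min_n = 3L, require_var = TRUE)
  res <- surrogate_test(function(z) abs(pomeau_statistic(z)), x, plan,
                        statistic = pomeau_statistic(x))
  irrev_result(res$pvalue, res$statistic, "Pomeau",
               params = list(method = plan$method, S = plan$S))
}

#' Ramsey test
#'
#' Method-of-moments comparison of the two lag-`k` sample bicovariances
#' `mean(x[i]^2 * x[i-k])` and `mean(x[i] * x[i-k]^2)`; their difference is
#' antisymmetric under time reversal and has zero mean for any iid series.
#' The difference is studentised with a Bartlett HAC variance estimate and
#' referred to the standard normal (two-sided).
#'
#' @param x numeric series (N >= 50).
#' @param k lag.
#' @return an `irrev_result`; statistic is the signed bicovariance difference.
#' @export
ramsey_test <- function(x, k = 1) {
  k <- as.integer(k)
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  if (k >= length(x)) stop("lag k must be smaller than N", call. = FALSE)
  u <- ramsey_terms(x, k)
  lags <- max(k, floor(1.5 * length(u)^(1 / 3)))
  v <- hac_var_of_mean(u, lags)
  if (v <= 0) stop("degenerate bicovariance variance", call. = FALSE)
  z <- mean(u) / sqrt(v)
  irrev_result(2 * stats::pnorm(-abs(z)), mean(u), "Ramsey",
               params = list(k = k), extra = list(z = z))
}

#' Skewness index test
#'
#' Relates the skewness of the differenced series to that of the original:
#' the reported statistic is the ratio `skew(diff(x)) / skew(x)`; the p-value
#' comes from the D'Agostino test of zero skewness applied to the differenced
#' series (a skewed increment distribution implies time asymmetry).
#'
#' @param x numeric series (N >= 50).
#' @return an `irrev_result`.
#' @export
skewness_index_test <- function(x) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  d <- diff(x)
  if (stats::var(d) == 0) stop("differenced series has zero variance",
                               call. = FALSE)
  sx <- sample_skewness(x)
  sd_ <- sample_skewness(d)
  if (sx == 0) stop("skewness of x is exactly zero: index undefined",
                    call. = FALSE)
  dt <- dagostino_skew_test(d)
  # the differenced series is serially dependent (MA(1) for iid input), which
  # shrinks the sampling variance of its skewness by the factor
  # sum_j rho_j^3; rescale the z-score accordingly
  rho <- stats::acf(d, lag.max = 20, plot = FALSE)$acf[-1]
  cfac <- 1 + 2 * sum(rho^3)
  cfac <- min(max(cfac, 0.2), 3)
  z <- dt$statistic / sqrt(cfac)
  irrev_result(2 * stats::pnorm(-abs(z)), sd_ / sx, "Skewness",
               extra = list(skew_diff = sd_, skew_x = sx, z = z))
}

#' Ternary coding test
#'
#' Maps each increment to one of three symbols (strongly increasing, strongly
#' decreasing, maintaining) using a magnitude threshold, then compares the
#' frequency of each short symbol word with that of its time-reversed image
#' (reversal reverses the word and flips its signs), via a HAC-studentised
#' chi-square statistic.
#'
#' @param x numeric series (N >= 50).
#' @param q quantile of `abs(diff(x))` used as the "strong move" threshold
#'   (increments below it map to the maintaining symbol).
#' @param threshold absolute threshold overriding `q` when supplied.
#' @param wordLength length of the symbol words compared (default 1: single
#'   symbols, i.e. counts of strong rises vs strong drops).
#' @return an `irrev_result`.
#' @export
ternary_test <- function(x, q = 0.33, threshold = NULL, wordLength = 1) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  wordLength <- as.integer(wordLength)
  d <- diff(x)
  thr <- if (is.null(threshold)) stats::quantile(abs(d), q, names = FALSE)
         else threshold
  sym <- ternary_symbols(d, thr)
  if (length(unique(sym)) < 2L) {
    stop("all increments fall in one ternary class", call. = FALSE)
  }
  # recode {-1,0,1} -> {0,1,2}; reversal maps word (s1..sL) -> (-sL..-s1)
  code3 <- sym + 1L
  n <- length(code3)
  L <- wordLength
  nw <- n - L + 1L
  pw <- 3L^(0:(L - 1L))
  codes <- integer(nw); rcodes <- integer(nw)
  for (l in seq_len(L)) {
    s <- code3[l:(nw + l - 1L)]
    codes <- codes + s * pw[l]
    rcodes <- rcodes + (2L - s) * pw[L - l + 1L]  # negate and reverse
  }
  present <- unique(c(codes, rcodes))
  ind_a <- list(); ind_b <- list()
  seen <- integer(0)
  for (cd in present) {
    rc <- tern_rev_code(cd, L)
    lo <- min(cd, rc); hi <- max(cd, rc)
    if (cd == rc || lo %in% seen) next
    seen <- c(seen, lo)
    ind_a[[length(ind_a) + 1L]] <- as.integer(codes == lo)
    ind_b[[length(ind_b) + 1L]] <- as.integer(codes == hi)
  }
  if (!length(ind_a)) return(irrev_result(1, 0, "Ternary Coding",
                                          params = list(q = q)))
  # differencing plus thresholding leaves strongly negative autocovariances,
  # which the Bartlett kernel cannot represent; use the flat-top estimator
  r <- paired_count_chisq(ind_a, ind_b, lags = L + 5L, estimator = "flat")
  p <- if (r$df == 0L) 1 else stats::pchisq(r$statistic, r$df,
                                            lower.tail = FALSE)
  irrev_result(p, r$statistic, "Ternary Coding",
               params = list(q = q, threshold = thr, wordLength = L),
               extra = list(df = r$df))
}

tern_rev_code <- function(code, L) {
  digs <- integer(L)
  for (l in seq_len(L)) { digs[l] <- code %% 3L; code <- code %/% 3L }
  sum((2L - rev(digs)) * 3L^(0:(L - 1L)))
}

# Maximal up-run and down-run lengths of a series (zero increments break
# runs and belong to neither sign).
trend_run_lengths <- function(x) {
  s <- sign(diff(x))
  r <- rle(s)
  list(up = r$lengths[r$values == 1], down = r$lengths[r$values == -1])
}

#' Trend pattern length (TPLength) test
#'
#' Decomposes the series into maximal increasing and decreasing runs and
#' compares the two run-length distributions with an Epps-Singleton
#' two-sample test; time reversal swaps the two distributions, so any
#' significant difference flags irreversibility.
#'
#' @param x numeric series (N >= 50).
#' @return an `irrev_result`.
#' @export
tplength_test <- function(x) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  rl <- trend_run_lengths(x)
  if (length(rl$up) < 2L || length(rl$down) < 2L) {
    stop("fewer than 2 runs of each sign", call. = FALSE)
  }
  if (stats::var(c(rl$up, rl$down)) == 0) {
    # e.g. strictly alternating series: all runs have length 1
    return(irrev_result(1, 0, "TPLength"))
  }
  es <- epps_singleton_test(rl$up, rl$down)
  irrev_result(es$pvalue, es$statistic, "TPLength", extra = list(df = es$df))
}

#' Visibility graph degree test
#'
#' Builds the directed horizontal visibility graph and compares the
#' distributions of in-degrees (links arriving at nodes) and out-degrees
#' (links departing from nodes) with an Epps-Singleton two-sample test.
#' Boundary nodes are dropped by default (their degrees are truncated by the
#' series edges).
#'
#' @param x numeric series (N >= 50).
#' @param drop_boundary drop the first and last node before comparing.
#' @return an `irrev_result`.
#' @export
visibility_test <- function(x, drop_boundary = TRUE) {
  x <- as_real_series(x, min_n = 50L, require_var = TRUE)
  dg <- hvg_degrees(x)
  keep <- if (drop_boundary) 2:(length(x) - 1L) else seq_along(x)
  outd <- dg$out[keep]; ind <- dg$`in`[keep]
  if (stats::var(c(outd, ind)) == 0) {
    return(irrev_result(1, 0, "Visibility Graph"))
  }
  es <- epps_singleton_test(outd, ind)
  irrev_result(es$pvalue, es$statistic, "Visibility Graph",
               extra = list(df = es$df))
}

#' Zumbach volatility-asymmetry test
#'
#' Transforms the series into returns and compares how the squared return at
#' time t correlates with the realised (future) versus the historical (past)
#' root-mean-square volatility over a window; time reversal swaps the two
#' correlations, so their difference is a signed irreversibility statistic.
#' Evaluation points are spaced `2 * window + 2` samples apart, so that the
#' return stretches feeding different points are disjoint: under an iid null
#' the per-point contributions are independent and a one-sample t-test on
#' them is exactly calibrated.
#'
#' Returns are simple differences by default; log-returns (appropriate for
#' multiplicative/financial series) are available via `returns = "log"` for
#' strictly positive data.
#'
#' @param x numeric series (N >= 60 and >= 6 * window).
#' @param window volatility window length. Volatility asymmetry is only
#'   visible at scales where the process has memory, so the default is short.
#' @param returns `"simple"` or `"log"`.
#' @return an `irrev_result`; statistic is the correlation difference.
#' @export
zumbach_test <- function(x, window = 2, returns = c("simple", "log")) {
  window <- as.integer(window)
  returns <- match.arg(returns)
  x <- as_real_series(x, min_n = max(60L, 6L * window), require_var = TRUE)
  r <- if (returns == "log") {
    if (any(x <= 0)) stop("log-returns need strictly positive values",
                          call. = FALSE)
    diff(log(x))
  } else diff(x)
  nr <- length(r)
  ts_ <- seq(window + 1L, nr - window, by = 2L * window + 2L)
  if (length(ts_) < 8L) stop("too few evaluation points", call. = FALSE)
  g <- r[ts_]^2
  cs <- cumsum(c(0, r^2))
  h <- sqrt((cs[ts_] - cs[ts_ - window]) / window)        # historical RMS
  f <- sqrt((cs[ts_ + window + 1L] - cs[ts_ + 1L]) / window)  # realised RMS
  if (stats::sd(g) == 0 || stats::sd(h) == 0 || stats::sd(f) == 0) {
    return(irrev_result(1, 0, "Zumbach", params = list(window = window)))
  }
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  delta <- zs(g) * (zs(f) - zs(h))   # mean(delta) ~ cor(g,f) - cor(g,h)
  if (stats::sd(delta) == 0) {
    return(irrev_result(1, 0, "Zumbach", params = list(window = window)))
  }
  tt <- stats::t.test(delta)
  irrev_result(tt$p.value, stats::cor(g, f) - stats::cor(g, h),
               "Zumbach", params = list(window = window, returns = returns),
               extra = list(z = unname(tt$statistic)))
}
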