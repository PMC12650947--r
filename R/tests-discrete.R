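# Irreversibility tests for symbolic series: Gaspard entropy production and
# the discrete (amplitude-aware) Costa index.

# Entropy production per step of the empirical Markov chain:
#   sum_ij pi_i P_ij log(P_ij / P_ji)
# with pi_i P_ij estimated by bigram frequencies n_ij / (N - 1). `order > 1`
# recodes the series into overlapping k-grams and runs the same estimator on
# the word chain.
gaspard_statistic <- function(codes, K, order = 1, pseudocount = 0) {
  if (order > 1) {
    L <- as.integer(order)
    nw <- length(codes) - L + 1L
    pw <- K^(0:(L - 1L))
    w <- integer(nw)
    for (l in seq_len(L)) w <- w + (codes[l:(nw + l - 1L)] - 1L) * pw[l]
    codes <- match(w, sort(unique(w)))
    K <- max(codes)
  }
  n <- length(codes)
  from <- codes[-n]; to <- codes[-1]
  cnt <- matrix(0, K, K)
  for (t in seq_len(n - 1L)) cnt[from[t], to[t]] <- cnt[from[t], to[t]] + 1
  cnt <- cnt + pseudocount
  bad <- (cnt > 0) & (t(cnt) == 0)
  if (any(bad)) {
    stop(paste("transition observed whose reverse is never observed;",
               "entropy production is infinite (set pseudocount > 0)"),
         call. = FALSE)
  }
  rows <- rowSums(cnt)
  tot <- sum(cnt)
  s <- 0
  for (i in seq_len(K)) {
    if (rows[i] == 0) next
    for (j in seq_len(K)) {
      if (cnt[i, j] == 0) next
      pij <- cnt[i, j] / rows[i]
      pji <- cnt[j, i] / rows[j]
      s <- s + (cnt[i, j] / tot) * log(pij / pji)
    }
  }
  s
}

#' Gaspard entropy-production test
#'
#' Models the symbol stream as a Markov chain and estimates the entropy
#' production per step, i.e. the difference between the time-reversed and
#' forward entropy rates: `sum pi_i P_ij log(P_ij / P_ji)`. The statistic is
#' non-negative (zero exactly under estimated detailed balance) and
#' significance is assessed against shuffled surrogates.
#'
#' @param s symbolic series (integer or character vector).
#' @param order Markov order; orders above 1 recode the stream into
#'   overlapping words.
#' @param pseudocount added to every transition count; with the default 0, an
#'   observed transition whose reverse is never observed is an error
#'   (the statistic would be infinite) rather than silently regularised.
#' @param alphabet optional symbol set (may include unobserved symbols).
#' @param plan a [surrogate_plan()].
#' @return an `irrev_result`; statistic is the entropy production.
#' @export
gaspard_test <- function(s, order = 1, pseudocount = 0, alphabet = NULL,
                         plan = surrogate_plan("zscore")) {
  ss <- as_symbol_series(s, alphabet = alphabet)
  K <- length(ss$alphabet)
  if (ss$n < 10 * K^2) {
    stop(sprintf("series too short: need N >= 10 * |A|^2 = %d", 10 * K^2),
         call. = FALSE)
  }
  res <- surrogate_test(
    function(codes) gaspard_statistic(codes, K, order, pseudocount),
    ss$symbols, plan)
  irrev_result(res$pvalue, res$statistic, "Gaspard",
               params = list(order = order, pseudocount = pseudocount,
                             method = plan$method, S = plan$S))
}

# Signed amplitude-aware asymmetry between positive and (negated) negative
# increments: the excess share of the total squared increment carried by
# rises over drops,
#   (sum_{d>0} d^2 - sum_{d<0} d^2) / sum_{d != 0} d^2  in [-1, 1].
# Antisymmetric under time reversal, zero for sign-symmetric increments, and
# reduces to the continuous Costa count asymmetry when all magnitudes are
# equal.
costa_discrete_statistic <- function(v) {
  d <- diff(v)
  d <- d[d != 0]
  if (!length(d)) stop("no non-zero increments", call. = FALSE)
  (sum(d[d > 0]^2) - sum(d[d < 0]^2)) / sum(d^2)
}

#' Costa index, discrete version
#'
#' Amplitude-aware irreversibility index for symbolic series over a totally
#' ordered alphabet with numeric differences: the statistic is the excess
#' share of the total squared increment carried by rises over drops, the
#' amplitude-aware generalisation of the up/down count asymmetry (equal to it
#' when all increment magnitudes coincide). Significance via shuffled
#' surrogates on the magnitude.
#'
#' @param s symbolic series of rankable values (numeric/integer), or a
#'   character series with `alphabet` supplying the order.
#' @param alphabet optional ordered alphabet; positions define the numeric
#'   values used for differences.
#' @param plan a [surrogate_plan()].
#' @return an `irrev_result`; statistic is the signed divergence difference.
#' @export
costa_discrete_test <- function(s, alphabet = NULL,
                                plan = surrogate_plan("zscore")) {
  if (is.numeric(s) && is.null(alphabet)) {
    v <- as.numeric(s)
    if (length(v) < 50L) stop("series too short: need N >= 50", call. = FALSE)
    if (anyNA(v)) stop("missing values rejected", call. = FALSE)
  } else {
    ss <- as_symbol_series(s, alphabet = alphabet, min_n = 50L)
    v <- as.numeric(ss$symbols)  # alphabet position carries the order
  }
  stat_fun <- function(z) costa_discrete_statistic(z)
  res <- surrogate_test(function(z) abs(stat_fun(z)), v, plan,
                        statistic = stat_fun(v))
  irrev_result(res$pvalue, res$statistic, "Costa Index (discrete)",
               params = list(method = plan$method, S = plan$S))
}
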