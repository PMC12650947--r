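#' Surrogate plan
#'
#' Describes how a measure-only statistic is turned into a p-value: an
#' ensemble of `S` randomly shuffled copies of the series is generated,
#' the statistic is recomputed on each, and the observed value is compared
#' to the null ensemble either by proportion (`"proportional"`) or through a
#' Z-score transformed by the standard-normal tail (`"zscore"`). Shuffling
#' destroys all temporal structure and therefore all time irreversibility,
#' which is what makes the shuffled ensemble a valid null.
#'
#' @param method `"proportional"` or `"zscore"`.
#' @param S ensemble size. Defaults to 100 for the proportional scheme and
#'   20 for the Z-score scheme (a Z-score ensemble that small already gives a
#'   good approximation, at the price of not being a true p-value).
#' @param seed RNG seed for the surrogate ensemble; `NULL` leaves the global
#'   stream untouched.
#' @param tail `"upper"` (default: statistics are oriented so that larger
#'   means more irreversible) or `"two_sided"` (Z-score scheme only).
#' @return an object of class `surrogate_plan`.
#' @export
surrogate_plan <- function(method = c("proportional", "zscore"), S = NULL,
                           seed = NULL, tail = c("upper", "two_sided")) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  if (is.null(S)) S <- if (method == "proportional") 100L else 20L
  S <- as.integer(S)
  if (S < 1L) stop("surrogate ensemble size S must be >= 1", call. = FALSE)
  structure(list(method = method, S = S, seed = seed, tail = tail),
            class = "surrogate_plan")
}

#' Shuffled surrogate ensemble
#'
#' `S` independent uniform random permutations of the values of `x`. Every
#' surrogate has exactly the same value multiset (hence mean, variance and
#' all marginal moments) as `x`; only the temporal order is destroyed.
#'
#' @param x series (numeric or symbolic vector).
#' @param S number of surrogates.
#' @param seed RNG seed; the full ensemble is reproducible bit-for-bit for a
#'   fixed seed.
#' @return a list of `S` shuffled copies of `x`.
#' @export
shuffle_surrogates <- function(x, S, seed = NULL) {
  S <- as.integer(S)
  if (S < 1L) stop("S must be >= 1", call. = FALSE)
  with_local_seed(seed, lapply(seq_len(S), function(j) sample(x)))
}

#' Proportional surrogate p-value
#'
#' Fraction of surrogate statistics equal to or higher than the observed one,
#' clamped below at `1/S`: with `S` surrogates the smallest attainable
#' p-value is exactly `1/S` (0.01 at the default `S = 100`).
#'
#' @param stat_obs observed statistic.
#' @param stat_null numeric vector of surrogate statistics.
#' @return p-value in `[1/S, 1]`.
#' @export
proportional_pvalue <- function(stat_obs, stat_null) {
  S <- length(stat_null)
  if (S < 1L) stop("empty null ensemble", call. = FALSE)
  max(sum(stat_null >= stat_obs), 1L) / S
}

#' Z-score surrogate p-value
#'
#' The observed statistic is standardised against the surrogate ensemble and
#' the Z-score is mapped through the standard-normal tail. Cheap (useful from
#' ensembles as small as 20) but an approximation: the result is not a true
#' p-value, since the surrogate null need not be Gaussian.
#'
#' @param stat_obs observed statistic.
#' @param stat_null numeric vector of surrogate statistics (>= 2 values with
#'   non-zero spread).
#' @param tail `"upper"` or `"two_sided"`.
#' @return approximate p-value in `[0, 1]`.
#' @export
zscore_pvalue <- function(stat_obs, stat_null, tail = c("upper", "two_sided")) {
  tail <- match.arg(tail)
  if (length(stat_null) < 2L) stop("need >= 2 surrogate statistics",
                                   call. = FALSE)
  s <- stats::sd(stat_null)
  if (!is.finite(s) || s == 0) stop("degenerate null: zero spread",
                                    call. = FALSE)
  z <- (stat_obs - mean(stat_null)) / s
  if (tail == "upper") stats::pnorm(z, lower.tail = FALSE)
  else 2 * stats::pnorm(-abs(z))
}

#' Surrogate-based significance wrapper
#'
#' Turns a measure (a function returning a single statistic) into a full
#' test: the measure is evaluated on `x` and on an ensemble of shuffled
#' surrogates, and a p-value is computed per the plan. The comparison uses
#' the orientation "larger = more irreversible"; signed measures should be
#' wrapped in `abs()` by the caller (the built-in registry does this).
#'
#' @param measure function of a series returning a finite scalar.
#' @param x the series.
#' @param plan a [surrogate_plan()].
#' @param statistic optional signed statistic to report in the result (the
#'   p-value is still computed from `measure`); defaults to `measure(x)`.
#' @return an `irrev_result` with the p-value and the statistic.
#' @export
surrogate_test <- function(measure, x, plan = surrogate_plan(),
                           statistic = NULL) {
  stopifnot(inherits(plan, "surrogate_plan"))
  obs <- measure(x)
  surr <- shuffle_surrogates(x, plan$S, plan$seed)
  null_stats <- vapply(surr, function(s) {
    v <- tryCatch(measure(s), error = function(e) NA_real_)
    # a surrogate on which the measure degenerates to +Inf/-error is treated
    # as exceeding the observed value (conservative)
    if (!is.finite(v)) Inf else v
  }, numeric(1))
  p <- if (plan$method == "proportional") {
    proportional_pvalue(obs, null_stats)
  } else {
    zscore_pvalue(obs, null_stats, plan$tail)
  }
  irrev_result(p, if (is.null(statistic)) obs else statistic,
               test = "surrogate", params = list(method = plan$method,
                                                 S = plan$S, seed = plan$seed),
               extra = list(null_stats = null_stats))
}
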