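# Multiscale utilities: downsampling, per-test parameter optimisation, and
# the ordinal-pattern-based irreversibility manipulator.

#' Downsample a time series
#'
#' Three coarse-graining methods for multiscale analysis: `"skip"` retains the
#' first observation of every block of `tau`; `"average"` replaces each block
#' of `tau` consecutive values by its mean; `"decimate"` applies a low-pass
#' anti-aliasing filter (order-8 Butterworth at 0.8/tau of Nyquist, zero-phase)
#' before taking every `tau`-th sample.
#'
#' @param x numeric series.
#' @param tau integer scale factor (>= 1); `tau = 1` returns the series
#'   unchanged for `"skip"` and `"average"`.
#' @param method one of `"average"`, `"skip"`, `"decimate"`.
#' @return the downsampled series, length `floor(N / tau)`.
#' @export
downsample <- function(x, tau, method = c("average", "skip", "decimate")) {
  method <- match.arg(method)
  x <- as_real_series(x, min_n = 2L)
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1", call. = FALSE)
  if (tau > length(x)) stop("tau exceeds series length", call. = FALSE)
  if (tau == 1L) return(x)
  nb <- length(x) %/% tau
  switch(method,
    skip = x[(seq_len(nb) - 1L) * tau + 1L],
    average = colMeans(matrix(x[seq_len(nb * tau)], nrow = tau)),
    decimate = {
      bf <- signal::butter(8, 0.8 / tau, type = "low")
      xf <- signal::filtfilt(bf, x)
      xf[(seq_len(nb) - 1L) * tau + 1L]
    })
}

#' Optimise the parameters of a test over an ensemble of series
#'
#' Runs a test on every series of the ensemble for every combination of a
#' parameter grid, combines the per-series p-values with Fisher's method
#' (log-scale, so arbitrarily small combined p-values remain comparable), and
#' returns the combination yielding the smallest combined p-value. To avoid
#' overfitting on real data, tune on one subset of series and evaluate on
#' another.
#'
#' @param test a test name or an `irrev_descriptor`.
#' @param ensemble list of series.
#' @param grid named list of candidate values per parameter; defaults to the
#'   descriptor's declared grid.
#' @param combine `"fisher"` (default) or `"median"` (median per-series p,
#'   a robust alternative).
#' @return list with `best_params`, `best_pvalue`, `best_log_pvalue` (natural
#'   log), and `grid_report` (one row per combination).
#' @export
optimise_parameters <- function(test, ensemble, grid = NULL,
                                combine = c("fisher", "median")) {
  combine <- match.arg(combine)
  d <- if (inherits(test, "irrev_descriptor")) test else get_test(test)
  if (!length(ensemble)) stop("empty ensemble", call. = FALSE)
  if (is.null(grid)) grid <- d$param_grid
  if (!length(grid)) stop("no parameter grid declared or supplied",
                          call. = FALSE)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  logp <- rep(NA_real_, nrow(combos))
  for (i in seq_len(nrow(combos))) {
    params <- as.list(combos[i, , drop = FALSE])
    ps <- tryCatch(
      vapply(ensemble, function(s) run_test(d$name, s, params)$pvalue,
             numeric(1)),
      error = function(e) NULL)
    if (is.null(ps)) next  # combination failed on some series: skipped
    ps <- pmax(ps, 1e-300)
    logp[i] <- if (combine == "fisher") {
      stats::pchisq(-2 * sum(log(ps)), df = 2 * length(ps),
                    lower.tail = FALSE, log.p = TRUE)
    } else {
      log(stats::median(ps))
    }
  }
  if (all(is.na(logp))) stop("every grid combination failed", call. = FALSE)
  best <- which.min(logp)
  report <- cbind(combos, log_pvalue = logp, pvalue = exp(logp))
  list(best_params = as.list(combos[best, , drop = FALSE]),
       best_pvalue = exp(logp[best]),
       best_log_pvalue = logp[best],
       grid_report = report)
}

#' Manipulate the irreversibility of a series
#'
#' Transforms the series through continuous ordinal patterns: each candidate
#' transform is the sequence of distances between one random normalised
#' pattern and every normalised sliding window of `x`. Among candidates whose
#' p-value (under `test_fun`) satisfies the threshold — `<= pvThreshold` when
#' increasing irreversibility, `>= pvThreshold` when decreasing — the one with
#' the highest Pearson correlation with the original series (aligned to the
#' window starts) is returned. Candidates are examined in decreasing order of
#' correlation, so evaluation stops at the first that satisfies the threshold.
#'
#' @param x numeric series.
#' @param increase if `TRUE` the irreversibility is increased (p-value pushed
#'   below `pvThreshold`); if `FALSE`, decreased.
#' @param numIterations number of random candidate patterns.
#' @param pSize pattern length of the transforming patterns.
#' @param pvThreshold acceptance threshold on the candidate's p-value.
#' @param test_fun function of a series returning an `irrev_result`; defaults
#'   to the COP test with its default parameters.
#' @param seed RNG seed.
#' @return list with `series` (the transformed series), `pvalue`,
#'   `correlation`, `success` (whether some candidate met the threshold;
#'   when `FALSE` the best achieved candidate is still reported), and
#'   `pattern` (the selected transforming pattern).
#' @export
manipulate <- function(x, increase = TRUE, numIterations = 1000, pSize = 4,
                       pvThreshold = 0.01, test_fun = NULL, seed = NULL) {
  x <- as_real_series(x, min_n = 100L, require_var = TRUE)
  numIterations <- as.integer(numIterations)
  if (numIterations < 1L) stop("numIterations must be >= 1", call. = FALSE)
  if (is.null(test_fun)) {
    cop_seed <- if (is.null(seed)) NULL else as.integer(seed) + 1L
    test_fun <- function(z) cop_test(z, seed = cop_seed)
  }
  W <- sliding_windows(x, pSize)
  nw <- normalise_windows(W)
  Z <- nw$Z
  xs <- x[seq_len(nrow(Z))]  # original series on the window-start support
  patterns <- with_local_seed(seed,
    lapply(seq_len(numIterations), function(i) random_cop(pSize)))
  cand <- lapply(patterns, function(p) cop_distances(Z, p))
  cors <- vapply(cand, function(y) {
    if (stats::sd(y) == 0) return(-Inf)
    stats::cor(xs, y)
  }, numeric(1))
  ord <- order(cors, decreasing = TRUE)
  best_fail <- NULL
  for (i in ord) {
    if (!is.finite(cors[i])) next
    res <- tryCatch(test_fun(cand[[i]]), error = function(e) NULL)
    if (is.null(res)) next
    ok <- if (increase) res$pvalue <= pvThreshold else res$pvalue >= pvThreshold
    if (ok) {
      return(list(series = cand[[i]], pvalue = res$pvalue,
                  correlation = cors[i], success = TRUE,
                  pattern = patterns[[i]]))
    }
    if (is.null(best_fail) ||
        (increase && res$pvalue < best_fail$pvalue) ||
        (!increase && res$pvalue > best_fail$pvalue)) {
      best_fail <- list(series = cand[[i]], pvalue = res$pvalue,
                        correlation = cors[i], success = FALSE,
                        pattern = patterns[[i]])
    }
  }
  if (is.null(best_fail)) stop("no valid candidate produced", call. = FALSE)
  best_fail
}
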