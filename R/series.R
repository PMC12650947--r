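#' Validate a real-valued time series
#'
#' Checks that `x` is an ordered numeric vector of finite values with at least
#' `min_n` observations. Missing values are rejected, never imputed: silent
#' imputation would corrupt the ordinal and spectral structure every
#' irreversibility statistic relies on.
#'
#' @param x numeric vector, the series in temporal order.
#' @param min_n minimum admissible length.
#' @param require_var if `TRUE`, a zero-variance (constant) series is an error.
#' @return `x`, invisibly coerced to a plain numeric vector.
#' @export
as_real_series <- function(x, min_n = 2L, require_var = FALSE) {
  if (is.data.frame(x) && ncol(x) == 1L) x <- x[[1L]]
  if (!is.numeric(x)) stop("series must be numeric", call. = FALSE)
  x <- as.numeric(x)
  if (length(x) < min_n) {
    stop(sprintf("series too short: N = %d, need N >= %d", length(x), min_n),
         call. = FALSE)
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("series contains missing or non-finite values (rejected, not imputed)",
         call. = FALSE)
  }
  if (require_var && stats::var(x) == 0) {
    stop("series has zero variance", call. = FALSE)
  }
  x
}

#' Validate a symbolic time series
#'
#' @param s vector of symbols (integer, character or factor) in temporal order.
#' @param alphabet optional vector of admissible symbols; inferred from the
#'   data when `NULL`. A supplied alphabet may contain symbols never observed.
#' @param min_n minimum admissible length.
#' @return a list with components `symbols` (integer codes 1..K), `alphabet`
#'   (the symbol set, in order) and `n`.
#' @export
as_symbol_series <- function(s, alphabet = NULL, min_n = 2L) {
  if (is.factor(s)) s <- as.character(s)
  if (length(s) < min_n) {
    stop(sprintf("symbol series too short: N = %d, need N >= %d",
                 length(s), min_n), call. = FALSE)
  }
  if (anyNA(s)) stop("symbol series contains missing values", call. = FALSE)
  if (is.null(alphabet)) {
    alphabet <- sort(unique(s))
  } else if (!all(s %in% alphabet)) {
    stop("symbol outside the supplied alphabet", call. = FALSE)
  }
  codes <- match(s, alphabet)
  list(symbols = as.integer(codes), alphabet = alphabet, n = length(s))
}

#' Time-reverse a series
#'
#' The reversal operator `rev(x)_i = x_(N+1-i)`; an involution. Works for both
#' real-valued and symbolic series.
#'
#' @param x a vector (real or symbolic series).
#' @return the time-reversed series.
#' @export
reverse_series <- function(x) rev(x)

# Run `expr` under a locally seeded RNG, restoring the caller's RNG state.
# All seedable functions in the package route through this so that library
# code never clobbers the user's random stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Construct the uniform test result object: every test, continuous or
# discrete, native or surrogate-based, returns exactly this pair plus
# bookkeeping fields.
irrev_result <- function(pvalue, statistic, test, params = list(),
                         extra = list()) {
  stopifnot(is.finite(statistic))
  pvalue <- min(max(pvalue, 0), 1)
  out <- c(list(pvalue = as.numeric(pvalue),
                statistic = as.numeric(statistic),
                test = test, params = params), extra)
  class(out) <- "irrev_result"
  out
}

#' @export
print.irrev_result <- function(x, ...) {
  cat(sprintf("Time-irreversibility test: %s\n", x$test))
  cat(sprintf("  statistic = %.6g\n  p-value   = %.6g\n",
              x$statistic, x$pvalue))
  if (length(x$params)) {
    cat("  params    =",
        paste(names(x$params),
              vapply(x$params, function(p) paste(format(p), collapse = ","),
                     character(1)),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
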