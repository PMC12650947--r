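# The test registry: one descriptor per test, making every test
# interchangeable behind the uniform (pvalue, statistic) contract.

make_descriptor <- function(name, fun, value_kind, significance_modes,
                            default_params = list(), param_grid = list(),
                            analysis_class, min_n, sided = "two_sided") {
  structure(list(name = name, fun = fun, value_kind = value_kind,
                 significance_modes = significance_modes,
                 default_params = default_params, param_grid = param_grid,
                 analysis_class = analysis_class, min_n = min_n,
                 sided = sided),
            class = "irrev_descriptor")
}

irrev_registry <- function() {
  list(
    make_descriptor("BDS", bds_test, "continuous", "native",
                    default_params = list(m = 2),
                    param_grid = list(m = 2:4),
                    analysis_class = "Correlations between data points",
                    min_n = 200L),
    make_descriptor("Casali", casali_test, "continuous",
                    c("proportional", "zscore"),
                    default_params = list(m = 1),
                    param_grid = list(m = 1:3),
                    analysis_class = "Correlations between data points",
                    min_n = 50L),
    make_descriptor("COP", cop_test, "continuous", "native",
                    default_params = list(pSize = 3, nPatterns = 100),
                    param_grid = list(pSize = 3:6),
                    analysis_class = "Ranking between successive values",
                    min_n = 100L),
    make_descriptor("Costa Index", costa_test, "continuous",
                    c("proportional", "zscore"),
                    analysis_class = "Ranking between successive values",
                    min_n = 50L),
    make_descriptor("DFK", dfk_test, "continuous", "native",
                    default_params = list(nSymbols = 2, wordLength = 3),
                    param_grid = list(nSymbols = 2:4, wordLength = 2:4),
                    analysis_class = "Symbolisation of individual values",
                    min_n = 50L),
    make_descriptor("Diks", diks_test, "continuous", "native",
                    default_params = list(m = 3),
                    param_grid = list(m = 2:4),
                    analysis_class = "Correlations between data points",
                    min_n = 200L, sided = "upper"),
    make_descriptor("Local CC", local_clustering_test, "continuous", "native",
                    analysis_class = "Network embedding", min_n = 50L),
    make_descriptor("MSTrends", mstrends_test, "continuous", "native",
                    default_params = list(window = 3, degree = 1),
                    param_grid = list(window = c(3, 5, 10, 20)),
                    analysis_class = "Linear and non-linear trends",
                    min_n = 60L),
    make_descriptor("Permutation Patterns", perm_patterns_test, "continuous",
                    "native",
                    default_params = list(pSize = 3),
                    param_grid = list(pSize = 3:5),
                    analysis_class = "Ranking between successive values",
                    min_n = 50L),
    make_descriptor("Pomeau", pomeau_test, "continuous",
                    c("proportional", "zscore"),
                    analysis_class = "Asymmetric function", min_n = 50L),
    make_descriptor("Ramsey", ramsey_test, "continuous", "native",
                    default_params = list(k = 1),
                    param_grid = list(k = 1:3),
                    analysis_class = "Statistics on data", min_n = 50L),
    make_descriptor("Skewness", skewness_index_test, "continuous", "native",
                    analysis_class = "Statistics on data", min_n = 50L),
    make_descriptor("Ternary Coding", ternary_test, "continuous", "native",
                    default_params = list(q = 0.33),
                    param_grid = list(q = c(0.2, 0.33, 0.5)),
                    analysis_class = "Symbolisation of individual values",
                    min_n = 50L),
    make_descriptor("TPLength", tplength_test, "continuous", "native",
                    analysis_class = "Linear and non-linear trends",
                    min_n = 50L),
    make_descriptor("Visibility Graph", visibility_test, "continuous",
                    "native",
                    analysis_class = "Network embedding", min_n = 50L),
    make_descriptor("Zumbach", zumbach_test, "continuous", "native",
                    default_params = list(window = 2),
                    param_grid = list(window = c(1, 2, 5, 10, 20)),
                    analysis_class = "Statistics on data", min_n = 60L),
    make_descriptor("Gaspard", gaspard_test, "discrete",
                    c("proportional", "zscore"),
                    default_params = list(order = 1, pseudocount = 0),
                    analysis_class = "Symbolisation of individual values",
                    min_n = 40L),
    make_descriptor("Costa Index (discrete)", costa_discrete_test, "discrete",
                    c("proportional", "zscore"),
                    analysis_class = "Ranking between successive values",
                    min_n = 50L)
  )
}

#' Registry of all irreversibility tests
#'
#' Returns the ordered collection of test descriptors. Every descriptor
#' carries the test function, its kind (continuous/discrete), the available
#' significance modes, default parameters, the default optimisation grid, its
#' analysis class and the minimum admissible series length. All tests share
#' the same interface: calling a descriptor's function on a valid series
#' yields a result holding exactly a p-value and a statistic.
#'
#' @param kind `"all"` (default, 18 tests), `"continuous"` (16) or
#'   `"discrete"` (2).
#' @return a named list of `irrev_descriptor` objects.
#' @export
all_tests <- function(kind = c("all", "continuous", "discrete")) {
  kind <- match.arg(kind)
  reg <- irrev_registry()
  names(reg) <- vapply(reg, `[[`, character(1), "name")
  if (kind == "all") return(reg)
  reg[vapply(reg, function(d) d$value_kind == kind, logical(1))]
}

#' Look up one test descriptor by name
#'
#' @param name test name as listed by [all_tests()] (case-insensitive).
#' @return an `irrev_descriptor`.
#' @export
get_test <- function(name) {
  reg <- all_tests()
  hit <- match(tolower(name), tolower(names(reg)))
  if (is.na(hit)) {
    stop(sprintf("unknown test '%s'; see all_tests()", name), call. = FALSE)
  }
  reg[[hit]]
}

#' Run a registered test by name
#'
#' @param name test name.
#' @param x the series (numeric, or symbolic for discrete tests).
#' @param params named list of parameter overrides; keys must be declared
#'   parameters of the test function.
#' @return an `irrev_result`.
#' @export
run_test <- function(name, x, params = list()) {
  d <- get_test(name)
  args <- utils::modifyList(d$default_params, params)
  ok <- names(args) %in% names(formals(d$fun))
  if (!all(ok)) {
    stop(sprintf("unknown parameter(s) for %s: %s", d$name,
                 paste(names(args)[!ok], collapse = ", ")), call. = FALSE)
  }
  do.call(d$fun, c(list(x), args))
}

#' @export
print.irrev_descriptor <- function(x, ...) {
  cat(sprintf("<%s test: %s; significance: %s; class: %s>\n",
              x$value_kind, x$name,
              paste(x$significance_modes, collapse = "/"),
              x$analysis_class))
  invisible(x)
}
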