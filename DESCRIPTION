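Package: irrev
Title: Time-Irreversibility Tests for Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified suite of statistical tests of time irreversibility for
    real-valued and symbolic time series, with a common (p-value, statistic)
    interface. Includes sixteen tests for real-valued series (BDS, Casali,
    continuous ordinal patterns, Costa index, Daw-Finney-Kennel, Diks,
    horizontal-visibility local clustering, multiscale trends, permutation
    patterns, Pomeau, Ramsey, skewness index, ternary coding, trend-pattern
    lengths, visibility-graph degrees, Zumbach) and two tests for symbolic
    series (Gaspard entropy production and the discrete Costa index), together
    with shuffled-surrogate significance schemes, multiscale downsampling,
    per-test parameter optimisation, an ordinal-pattern-based irreversibility
    manipulator, and generators of series with known irreversibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
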