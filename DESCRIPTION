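Package: diaryvar
Title: Stationarity-Gated Vector Autoregression for Daily Diary Time Series
Version: 0.1.0
Authors@R: person("diaryvar", "maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Per-patient multivariate time-series analysis for daily diary
    (ecological momentary assessment) data on 0-100 visual analogue scales:
    regression imputation of missing days, augmented Dickey-Fuller
    stationarity screening with automated analysis-window determination,
    bivariate VAR estimation with information-criterion lag selection and a
    diagnostic re-estimation loop (eigenvalue stability, Portmanteau white
    noise), Granger causality tests, orthogonalised and accumulated impulse
    response functions with Hall bootstrap bands, forecast error variance
    decomposition, linear time trends and same-day correlations, plus a
    ground-truth synthetic diary generator and a cohort pipeline with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
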