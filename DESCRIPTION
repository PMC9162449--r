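Package: penfund
Title: Stochastic Actuarial Projection of Basic Pension Fund Reserves
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Long-horizon financial evaluation of a pay-as-you-go basic
    pension system that combines a social pooling account with notional
    individual accounts. Provides Lee-Carter mortality fitting and
    stochastic forecasting with a Coale-Kisker old-age closure,
    cohort-component population projection, first-order autoregressive
    difference models for unemployment, urbanization and wage growth, a
    mean-reverting (Vasicek) return-on-investment process, an actuarial
    contribution and expenditure model for old/middle/new retiree cohorts,
    six fund-reserve indicators with depletion-year and trend statistics,
    Monte Carlo ensembles with empirical 95 percent bands, elasticity
    scans, single-parameter influence indices, and decile backtracking of
    parameter paths. A synthetic pseudo-yearbook generator with known
    ground truth makes the whole pipeline self-contained and testable.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
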