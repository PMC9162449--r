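# memoized fixtures shared across test files; everything is generated in
# code at test time
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

fx_bundle <- function(seed = 42) {
  memo(paste0("bundle", seed), generate_bundle(synth_config(seed = seed)))
}

# noise-free bundle: every fitting stage must recover its truth exactly
fx_bundle_zero <- function(seed = 7) {
  memo(paste0("zero", seed), generate_bundle(synth_config(
    seed = seed,
    true_lc = list(innovation_sd = 0, residual_sd = 0),
    true_ar = list(unemployment = list(sd = 0),
                   urbanization = list(sd = 0),
                   wage_growth = list(sd = 0)),
    true_vasicek = list(sd = 0),
    true_lognormal = list(log_sd = 0)
  )))
}

# 20-year reporting horizon keeps engine tests quick
short_policy <- function(...) default_policy(end_year = 2041L, ...)

fx_baseline_short <- function() {
  memo("baseline_short", run_fixed_scenario(fx_bundle(), short_policy()))
}

# spec with every innovation switched off (degenerate noise)
zero_spec <- function() {
  sp <- default_randomization_spec()
  sp$unemployment$sd <- 0
  sp$urbanization$sd <- 0
  sp$wage_growth$sd <- 0
  sp$roi$sd <- 0
  sp$bookkeeping$log_sd <- 0
  sp$enterprise_rate$sd <- 0
  sp$individual_rate$sd <- 0
  sp
}

# flat economy for hand-checked actuarial arithmetic: constant wage 100,
# no pension growth, bookkeeping rate j, no seniority gradient
toy_series <- function(years = 1950:2060, sbar = 100, rho = 0, j = 0.1,
                       c_rate = 0.08, b_rate = 0.16, d = 1, Fnorm = 1) {
  economy_series(years, sbar, rho, j, c_rate, b_rate, d, Fnorm)
}

toy_policy <- function(...) default_policy(s = 0, d = 1, ...)
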