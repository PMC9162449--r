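#' Configuration for the synthetic pseudo-yearbook bundle
#'
#' Ground-truth parameters and table sizes for [generate_bundle()].  The
#' defaults emulate the statistical shape of the yearbook series the
#' projection consumes: a 26-year age-sex mortality surface driven by a
#' declining Lee-Carter index, a 42-year unemployment history and
#' 40-year urbanization history whose yearly differences follow AR(1)
#' recursions, a 23-year wage-level history implied by an AR(1) on
#' wage-growth differences, a 26-year deposit-rate history (lognormal),
#' a daily mean-reverting short-rate history, a unimodal fertility
#' schedule on ages 15-49 with total-fertility and sex-ratio paths, a
#' smooth initial age-sex pyramid over ages 0-100, and scalar initial
#' conditions (fund stock, weighted wage, ROI).
#'
#' @param seed integer seed; the bundle is a pure function of the config.
#' @param ... overrides of any default field (see the function body for
#'   the full list; noise scales may be set to zero for exact-recovery
#'   tests).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, ...) {
  ages_mort <- 0:84
  nm <- length(ages_mort)
  # level curve: infant mortality, background, accident hump, Gompertz
  base_m <- function(scale, hump) {
    0.008 * scale * exp(-0.35 * ages_mort) + 0.0002 +
      hump * exp(-0.5 * ((ages_mort - 22) / 6)^2) +
      5e-5 * scale * exp(0.093 * ages_mort)
  }
  beta_raw <- 1.5 * exp(-ages_mort / 30) + 0.5
  cfg <- list(
    seed = as.integer(seed),
    n_hist_years_mortality = 26L,    # 1994..2019
    n_hist_years_unemployment = 42L, # 1978..2019
    n_hist_years_urbanization = 40L, # 1980..2019
    n_hist_years_wage = 22L,         # growth observations, levels 1997..2019
    n_repo_obs = 1650L,
    true_lc = list(
      ages = ages_mort,
      alpha_m = log(base_m(1.0, 3e-4)),
      alpha_f = log(base_m(0.8, 1e-4)),
      beta = beta_raw / sum(beta_raw),
      drift = -1.0,
      innovation_sd = 0.6,
      residual_sd = 0.02
    ),
    true_ar = list(
      unemployment = list(intercept = 0, coef = 0.5851, sd = 0.2616,
                          start = 5.0, start_diff = 0.1),
      urbanization = list(intercept = 0.3106, coef = 0.7042, sd = 0.2815,
                          start = 19.4, start_diff = 0.8),
      wage_growth = list(intercept = -0.0010, coef = -0.3095, sd = 0.0258,
                         start = 0.105, start_diff = -0.002)
    ),
    true_vasicek = list(intercept = 0.0015002, coef = 0.95275,
                        sd = 0.0020282, start = 0.025),
    true_lognormal = list(log_mean = -3.173, log_sd = 0.364),
    fertility_shape = list(peak_age = 26, spread = 5.5),
    tfr_path = 1.70,                 # scalar or per-forecast-year vector
    srb_path = 1.10,
    pyramid = list(total = 1.4e9, male_ratio = 1.04),
    initial_fund = 4440.17e9,
    initial_wage = 63182,
    initial_roi = 0.0689,
    base_year = 2019L,
    end_year = 2094L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    for (f in names(ov)) {
      if (is.list(cfg[[f]]) && is.list(ov[[f]])) {
        cfg[[f]] <- modify_deep(cfg[[f]], ov[[f]])
      } else cfg[[f]] <- ov[[f]]
    }
  }
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

modify_deep <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]])) modify_deep(a[[nm]], b[[nm]]) else b[[nm]]
  }
  a
}

validate_synth_config <- function(cfg) {
  counts <- c(n_hist_years_mortality = cfg$n_hist_years_mortality,
              n_hist_years_unemployment = cfg$n_hist_years_unemployment,
              n_hist_years_urbanization = cfg$n_hist_years_urbanization,
              n_hist_years_wage = cfg$n_hist_years_wage,
              n_repo_obs = cfg$n_repo_obs)
  neg <- counts < 0
  if (any(neg)) stop("config field '", names(counts)[neg][1L], "': count must be >= 0")
  if (cfg$true_vasicek$coef <= 0 || cfg$true_vasicek$coef >= 1)
    stop("config field 'true_vasicek$coef': persistence must lie in (0, 1)")
  if (cfg$pyramid$total <= 0) stop("config field 'pyramid$total': must be positive")
  sds <- c(cfg$true_lc$innovation_sd, cfg$true_lc$residual_sd,
           cfg$true_ar$unemployment$sd, cfg$true_ar$urbanization$sd,
           cfg$true_ar$wage_growth$sd, cfg$true_vasicek$sd,
           cfg$true_lognormal$log_sd)
  if (any(sds < 0)) stop("config field: noise scales must be >= 0")
  invisible(cfg)
}

# smooth pyramid: piecewise-linear rise to a working-age plateau, mild
# decline after 50, exponential old-age decay.  Deliberately younger at
# the old ages than a full census pyramid: it stands in for the
# population relevant to the insurance scheme, whose historical coverage
# of today's elderly cohorts is incomplete.
pyramid_weights <- function(ages) {
  w <- numeric(length(ages))
  w[ages <= 20] <- 0.62 + 0.008 * ages[ages <= 20]
  mid <- ages > 20 & ages <= 32
  w[mid] <- 0.78 + 0.22 * (ages[mid] - 20) / 12
  w[ages > 32 & ages <= 50] <- 1
  late <- ages > 50 & ages <= 55
  w[late] <- 1 - 0.024 * (ages[late] - 50)
  old <- ages > 55
  w[old] <- 0.88 * exp(-0.10 * (ages[old] - 55))
  w
}

#' Generate a synthetic pseudo-yearbook bundle
#'
#' Draws every input table the projection pipeline needs, from known
#' ground truth, so each fitting stage can be validated by parameter
#' recovery.  Deterministic given `config$seed`.
#'
#' @param config a [synth_config()] list.
#' @return A list of class `pension_bundle` holding the tables
#'   `population_initial`, `mortality_hist`, `fertility_schedule`,
#'   `tfr_path`, `srb_path`, `unemployment_hist`, `urbanization_hist`,
#'   `wage_hist`, `deposit_rate_hist`, `repo_rate_hist`,
#'   `initial_conditions`, plus `ground_truth` (the config).
#' @export
generate_bundle <- function(config = synth_config()) {
  validate_synth_config(config)
  set.seed(config$seed)
  by <- config$base_year

  # -- mortality surface -------------------------------------------------
  lc <- config$true_lc
  ny <- config$n_hist_years_mortality
  years_m <- seq(by - ny + 1L, by)
  k <- cumsum(lc$drift + stats::rnorm(ny, 0, lc$innovation_sd))
  k <- k - mean(k)                     # identifiability: sum k = 0
  surf <- function(alpha) {
    lnm <- alpha + lc$beta %o% k
    if (lc$residual_sd > 0)
      lnm <- lnm + matrix(stats::rnorm(length(lnm), 0, lc$residual_sd), nrow(lnm))
    exp(lnm)
  }
  m_m <- surf(lc$alpha_m)
  m_f <- surf(lc$alpha_f)
  mort <- rbind(
    data.frame(year = rep(years_m, each = length(lc$ages)), age = lc$ages,
               sex = "m", central_rate = as.vector(m_m)),
    data.frame(year = rep(years_m, each = length(lc$ages)), age = lc$ages,
               sex = "f", central_rate = as.vector(m_f))
  )

  # -- AR-difference histories ------------------------------------------
  gen_ar <- function(par, n, lower = -Inf) {
    lv <- numeric(n); lv[1] <- par$start; dlag <- par$start_diff
    for (t in 2:n) {
      dlag <- par$intercept + par$coef * dlag + stats::rnorm(1, 0, par$sd)
      lv[t] <- max(lv[t - 1] + dlag, lower)
    }
    lv
  }
  nu <- config$n_hist_years_unemployment
  u_hist <- data.frame(year = seq(by - nu + 1L, by),
                       rate = gen_ar(config$true_ar$unemployment, nu, lower = 0.1))
  nub <- config$n_hist_years_urbanization
  ub_hist <- data.frame(year = seq(by - nub + 1L, by),
                        rate = gen_ar(config$true_ar$urbanization, nub, lower = 0))

  # wage growth path, then levels anchored so the base-year level equals
  # the configured initial wage
  ng <- config$n_hist_years_wage
  g_hist <- gen_ar(config$true_ar$wage_growth, ng + 1L)[-1L]  # growth in years by-ng+1..by
  lev <- numeric(ng + 1L)
  lev[ng + 1L] <- config$initial_wage
  for (t in ng:1) lev[t] <- lev[t + 1L] / (1 + g_hist[t])
  wage <- data.frame(year = seq(by - ng, by), avg_wage = lev)

  # -- deposit and repo rates -------------------------------------------
  dep_years <- seq(by - ny + 1L, by)
  dep <- data.frame(year = dep_years,
                    rate = exp(stats::rnorm(length(dep_years),
                                            config$true_lognormal$log_mean,
                                            config$true_lognormal$log_sd)))
  vz <- config$true_vasicek
  nr <- config$n_repo_obs
  repo <- numeric(nr); prev <- vz$start
  eps <- stats::rnorm(nr, 0, vz$sd)
  for (t in seq_len(nr)) {
    prev <- vz$intercept + vz$coef * prev + eps[t]
    repo[t] <- prev
  }
  repo <- data.frame(obs = seq_len(nr), rate = repo)

  # -- fertility and pyramid --------------------------------------------
  fa <- 15:49
  shape <- exp(-0.5 * ((fa - config$fertility_shape$peak_age) /
                         config$fertility_shape$spread)^2)
  shape <- shape / sum(shape)
  fert <- data.frame(age = fa, coefficient = shape)
  fy <- seq(by + 1L, config$end_year)
  tfr <- data.frame(year = fy, tfr = rep_len(config$tfr_path, length(fy)))
  srb <- data.frame(year = fy, srb = rep_len(config$srb_path, length(fy)))

  ages <- 0:100
  w <- pyramid_weights(ages)
  mr <- config$pyramid$male_ratio
  tot <- config$pyramid$total
  male <- w * mr / (1 + mr)
  female <- w * 1 / (1 + mr)
  scale <- tot / sum(male + female)
  pyr <- rbind(
    data.frame(age = ages, sex = "m", count = male * scale),
    data.frame(age = ages, sex = "f", count = female * scale)
  )

  init <- data.frame(
    name = c("initial_fund", "initial_wage", "initial_roi", "base_year"),
    value = c(config$initial_fund, config$initial_wage, config$initial_roi,
              as.numeric(by))
  )

  structure(list(
    population_initial = pyr,
    mortality_hist = mort,
    fertility_schedule = fert,
    tfr_path = tfr,
    srb_path = srb,
    unemployment_hist = u_hist,
    urbanization_hist = ub_hist,
    wage_hist = wage,
    deposit_rate_hist = dep,
    repo_rate_hist = repo,
    initial_conditions = init,
    ground_truth = list(config = unclass(config), k = k)
  ), class = "pension_bundle")
}

#' Write a bundle to a directory of CSV files
#'
#' Each table becomes `<name>.csv`; the ground truth is stored as
#' `ground_truth.json`.
#'
#' @param bundle a `pension_bundle`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in setdiff(names(bundle), "ground_truth")) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a bundle back from a directory of CSV files
#'
#' @param dir directory written by [write_bundle()].
#' @return A `pension_bundle`.
#' @export
read_bundle <- function(dir) {
  nms <- c("population_initial", "mortality_hist", "fertility_schedule",
           "tfr_path", "srb_path", "unemployment_hist", "urbanization_hist",
           "wage_hist", "deposit_rate_hist", "repo_rate_hist",
           "initial_conditions")
  out <- lapply(nms, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("bundle is missing table: ", nm)
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  names(out) <- nms
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) out$ground_truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  structure(out, class = "pension_bundle")
}
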