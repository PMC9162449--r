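#' Default randomization specification for the nine stochastic parameters
#'
#' One entry per stochastic driver of the projection: first-order
#' autoregressions on yearly differences for the unemployment rate,
#' urbanization rate and average wage growth rate; a mean-reverting
#' lag-one recursion for the return on investment (ROI); a lognormal
#' bookkeeping interest rate; independent yearly normal draws for the
#' enterprise and individual contribution rates; and the pension growth
#' rate tied to wage growth by a fixed multiplier.  Mortality, the ninth
#' parameter, is carried by the Lee-Carter index path and is configured
#' through its fitted model, not here.
#'
#' Units: unemployment and urbanization evolve in percentage points
#' (their innovation sds are in points); wage growth, ROI, bookkeeping
#' and contribution rates are fractions per year.
#'
#' @return A list of class `randomization_spec`.
#' @export
default_randomization_spec <- function() {
  spec <- list(
    unemployment = list(intercept = 0, coef = 0.5851, sd = 0.2616, lower = 0),
    urbanization = list(intercept = 1.0476, coef = 0.7042, sd = 0.2815, cap = 80),
    wage_growth = list(intercept = -0.0010, coef = -0.3095, sd = 0.0258,
                       lower = 0, upper = 0.092),
    roi = list(intercept = 0.0015002, coef = 0.95275, sd = 0.0020282),
    bookkeeping = list(log_mean = -3.173, log_sd = 0.364),
    enterprise_rate = list(mean = 0.16, sd = 0.0204),
    individual_rate = list(mean = 0.08, sd = 0.0153),
    pension_growth_multiplier = 0.8
  )
  class(spec) <- c("randomization_spec", "list")
  spec
}

validate_randomization_spec <- function(spec) {
  sds <- c(spec$unemployment$sd, spec$urbanization$sd, spec$wage_growth$sd,
           spec$roi$sd, spec$bookkeeping$log_sd,
           spec$enterprise_rate$sd, spec$individual_rate$sd)
  if (any(sds < 0)) stop("spec field: all sds must be >= 0")
  m <- spec$pension_growth_multiplier
  if (m < 0.6 || m > 0.8)
    stop("spec field 'pension_growth_multiplier': outside admissible range [0.6, 0.8]")
  invisible(spec)
}

#' Fit a first-order autoregression on first differences
#'
#' Differences the series once and regresses each difference on its lag
#' by least squares, the ARIMA(1,1,0) estimation used for unemployment,
#' urbanization and wage-growth histories.
#'
#' @param series numeric vector of levels, length >= 5.
#' @param with_intercept include an intercept in the lag regression?
#' @return List with `intercept`, `coef`, `innovation_sd` (residual sd).
#' @export
#' @examples
#' y <- cumsum(0.5 ^ (0:19))          # differences follow 0.5 * lag exactly
#' fit_difference_ar(y, with_intercept = FALSE)$coef  # 0.5
fit_difference_ar <- function(series, with_intercept = TRUE) {
  if (length(series) < 5L) stop("series must have length >= 5")
  if (stats::sd(series) == 0) stop("constant series: no variation to fit")
  d <- diff(series)
  y <- d[-1L]
  x <- d[-length(d)]
  if (stats::sd(x) == 0 && !with_intercept && stats::sd(y) == 0)
    stop("constant differences: no variation to fit")
  f <- if (with_intercept) stats::lm(y ~ x) else stats::lm(y ~ x - 1)
  cf <- stats::coef(f)
  list(
    intercept = if (with_intercept) unname(cf[1L]) else 0,
    coef = unname(cf[if (with_intercept) 2L else 1L]),
    innovation_sd = sqrt(mean(stats::residuals(f)^2))
  )
}

#' Fit a discretized Vasicek (mean-reverting lag-one) model
#'
#' Least-squares regression of the level on its lag,
#' \eqn{i_t = a + b\, i_{t-1} + \sigma \epsilon_t}; the implied
#' stationary mean is \eqn{a / (1 - b)}.
#'
#' @param series numeric vector of levels, length >= 30.
#' @return List with `intercept`, `coef` (persistence), `diffusion_sd`
#'   (residual sd) and `stationary_mean`.
#' @export
fit_vasicek <- function(series) {
  if (length(series) < 30L) stop("series must have length >= 30")
  if (!all(is.finite(series))) stop("series must be finite")
  if (stats::sd(series) == 0) stop("constant series: no variation to fit")
  y <- series[-1L]
  x <- series[-length(series)]
  f <- stats::lm(y ~ x)
  cf <- stats::coef(f)
  a <- unname(cf[1L]); b <- unname(cf[2L])
  list(intercept = a, coef = b,
       diffusion_sd = sqrt(mean(stats::residuals(f)^2)),
       stationary_mean = a / (1 - b))
}

#' Stationary mean of a mean-reverting lag-one recursion
#'
#' @param intercept,coef recursion parameters (persistence `coef` < 1).
#' @return `intercept / (1 - coef)`.
#' @export
vasicek_stationary_mean <- function(intercept, coef) {
  if (coef >= 1) stop("persistence must be < 1 for a stationary mean")
  intercept / (1 - coef)
}

#' Lognormal fit by maximum likelihood
#'
#' The MLE of a lognormal is the mean and (population) sd of the
#' log-values.
#'
#' @param series positive numeric vector.
#' @return List with `log_mean`, `log_sd`, and the implied `mean`
#'   \eqn{e^{\mu + \sigma^2/2}}.
#' @export
fit_lognormal <- function(series) {
  if (any(series <= 0)) stop("all values must be > 0")
  lx <- log(series)
  mu <- mean(lx)
  sg <- sqrt(mean((lx - mu)^2))
  list(log_mean = mu, log_sd = sg, mean = exp(mu + sg^2 / 2))
}

#' Mean of a lognormal distribution from its log-scale parameters
#'
#' @param log_mean,log_sd parameters on the log scale.
#' @return \eqn{e^{\mu + \sigma^2 / 2}}.
#' @export
lognormal_mean <- function(log_mean, log_sd) exp(log_mean + log_sd^2 / 2)

# ---- path simulation ---------------------------------------------------

# One joint draw of all parameter paths, using the current RNG state.
# init: list(u, du, ub, dub, g, dg, i) with u/ub in percent, g/i fractions.
# fluctuate: "all", "none", or a subset of
#   c("mortality","unemployment","urbanization","wage_growth","roi",
#     "bookkeeping","pension_growth","enterprise_rate","individual_rate")
draw_param_path <- function(spec, init, horizon, fluctuate = "all",
                            fixed_j = "mean", n_warm = 0L) {
  on_ <- function(p) identical(fluctuate, "all") || p %in% fluctuate
  H <- horizon
  eps <- function(active, sd) {
    if (!active || sd <= 0) return(numeric(H))
    e <- stats::rnorm(H, 0, sd)
    if (n_warm > 0L) e[seq_len(min(n_warm, H))] <- 0  # deterministic warm-up
    e
  }

  ar_level <- function(level0, d0, par, e, lower = -Inf, cap = Inf) {
    lv <- numeric(H); dlag <- d0; prev <- level0
    for (t in seq_len(H)) {
      dlag <- par$intercept + par$coef * dlag + e[t]
      prev <- min(max(prev + dlag, lower), cap)
      lv[t] <- prev
    }
    lv
  }

  u <- ar_level(init$u, init$du, spec$unemployment,
                eps(on_("unemployment"), spec$unemployment$sd),
                lower = spec$unemployment$lower)
  ub <- ar_level(init$ub, init$dub, spec$urbanization,
                 eps(on_("urbanization"), spec$urbanization$sd),
                 lower = 0, cap = spec$urbanization$cap)
  g <- ar_level(init$g, init$dg, spec$wage_growth,
                eps(on_("wage_growth"), spec$wage_growth$sd),
                lower = spec$wage_growth$lower, cap = spec$wage_growth$upper)
  # pension growth follows its own wage-growth-type path when it is the
  # only fluctuating parameter; in a full simulation it rides on g itself
  g_rho <- if (on_("pension_growth") && !on_("wage_growth")) {
    ar_level(init$g, init$dg, spec$wage_growth,
             eps(TRUE, spec$wage_growth$sd),
             lower = spec$wage_growth$lower, cap = spec$wage_growth$upper)
  } else g
  rho <- spec$pension_growth_multiplier * g_rho

  i <- numeric(H); prev <- init$i
  ei <- eps(on_("roi"), spec$roi$sd)
  for (t in seq_len(H)) {
    prev <- spec$roi$intercept + spec$roi$coef * prev + ei[t]
    i[t] <- prev
  }

  jfix <- if (fixed_j == "mean")
    lognormal_mean(spec$bookkeeping$log_mean, spec$bookkeeping$log_sd)
  else exp(spec$bookkeeping$log_mean)
  j <- if (on_("bookkeeping"))
    exp(stats::rnorm(H, spec$bookkeeping$log_mean, spec$bookkeeping$log_sd))
  else rep(jfix, H)
  b <- if (on_("enterprise_rate"))
    stats::rnorm(H, spec$enterprise_rate$mean, spec$enterprise_rate$sd)
  else rep(spec$enterprise_rate$mean, H)
  cc <- if (on_("individual_rate"))
    stats::rnorm(H, spec$individual_rate$mean, spec$individual_rate$sd)
  else rep(spec$individual_rate$mean, H)
  if (n_warm > 0L) {
    w <- seq_len(min(n_warm, H))
    j[w] <- jfix
    b[w] <- spec$enterprise_rate$mean
    cc[w] <- spec$individual_rate$mean
  }

  list(u = u / 100, ub = ub / 100, g = g, rho = rho, i = i, j = j, b = b, c = cc)
}

#' Simulate joint paths of the stochastic parameters
#'
#' Advances each parameter by its own recursion or yearly draw over the
#' forecast horizon, applying the clipping rules after every step:
#' unemployment floored at 0, urbanization capped at 80%, wage growth
#' confined to `[0, 9.2%]`; the pension growth rate is the configured
#' multiple (default 0.8) of wage growth.  Contribution rates are fresh
#' normal draws each year.  Paths are deterministic given `seed`; each
#' path consumes its own RNG substream, so results do not depend on
#' evaluation order.
#'
#' @param spec a [default_randomization_spec()] list.
#' @param init initial conditions: list with `u`, `du`, `ub`, `dub`
#'   (percent and percentage points), `g`, `dg`, `i` (fractions).
#' @param years forecast calendar years.
#' @param n_paths number of paths (>= 1).
#' @param seed master seed.
#' @param fluctuate `"all"`, `"none"`, or a character subset of parameter
#'   names; parameters not selected follow their zero-innovation path.
#' @param fixed_j `"mean"` or `"median"`: value the bookkeeping rate takes
#'   when it does not fluctuate.
#' @return Object of class `parameter_paths`: list of `years`, matrices
#'   (`horizon x n_paths`) `u`, `ub`, `g`, `rho`, `i`, `j`, `b`, `c`
#'   (all fractions), and the `seed`.
#' @export
simulate_paths <- function(spec, init, years, n_paths = 1L, seed = NULL,
                           fluctuate = "all", fixed_j = "mean") {
  if (length(years) < 1L) stop("horizon must be >= 1")
  if (n_paths < 1L) stop("n_paths must be >= 1")
  need <- c("u", "du", "ub", "dub", "g", "dg", "i")
  miss <- setdiff(need, names(init))
  if (length(miss)) stop("missing initial condition(s): ", paste(miss, collapse = ", "))
  validate_randomization_spec(spec)
  H <- length(years)
  if (!is.null(seed)) set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max - 1L, n_paths)
  nm <- c("u", "ub", "g", "rho", "i", "j", "b", "c")
  out <- stats::setNames(lapply(nm, function(x) matrix(NA_real_, H, n_paths)), nm)
  for (p in seq_len(n_paths)) {
    set.seed(path_seeds[p])
    pp <- draw_param_path(spec, init, H, fluctuate, fixed_j)
    for (x in nm) out[[x]][, p] <- pp[[x]]
  }
  structure(c(list(years = years), out,
              list(seed = seed, fluctuate = fluctuate)),
            class = "parameter_paths")
}

#' @export
as.data.frame.parameter_paths <- function(x, ...) {
  nm <- c("u", "ub", "g", "rho", "i", "j", "b", "c")
  do.call(rbind, lapply(nm, function(p) {
    m <- x[[p]]
    data.frame(
      path_id = rep(seq_len(ncol(m)), each = nrow(m)),
      year = rep(x$years, ncol(m)),
      parameter = p,
      value = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
}
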