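#' Fit the Lee-Carter mortality model
#'
#' Fits the log-bilinear model \eqn{\ln m_{x,t} = \alpha_x + \beta_x k_t +
#' \epsilon_{x,t}} to a rectangular surface of central death rates.
#' \eqn{\alpha_x} is the mean log rate per age; the first singular
#' component of the centred log surface gives \eqn{\beta_x} and
#' \eqn{k_t}, the least-squares rank-one fit.  The usual identifiability
#' normalization is imposed: \eqn{\sum_x \beta_x = 1},
#' \eqn{\sum_t k_t = 0}.  Weights may optionally down-weight ages with
#' noisy residuals (one re-weighted pass with inverse residual variance
#' per age); the default is the unweighted fit.
#'
#' @param surface data frame with columns `year`, `age`, `rate` (central
#'   death rates, strictly positive) forming a complete age-by-year grid
#'   for one sex.
#' @param weights `"none"` (default) or `"inverse-variance"`.
#' @return A list of class `lee_carter` with elements `ages`, `years`,
#'   `alpha`, `beta`, `k`, `drift` (mean yearly change of `k`),
#'   `innovation_sd` (sd of the `k` increments about the drift),
#'   `residual_sd`, and `fitted` (matrix of fitted log rates).
#' @export
#' @examples
#' sf <- expand.grid(year = 2001:2010, age = 60:70)
#' sf$rate <- 0.01 * exp(0.09 * (sf$age - 60)) * exp(-0.02 * (sf$year - 2001))
#' fit <- fit_lee_carter(sf)
#' c(sum(fit$beta), sum(fit$k))  # 1, 0
fit_lee_carter <- function(surface, weights = c("none", "inverse-variance")) {
  weights <- match.arg(weights)
  stopifnot(is.data.frame(surface), all(c("year", "age", "rate") %in% names(surface)))
  if (any(surface$rate <= 0)) stop("central rates must be strictly positive")
  ages <- sort(unique(surface$age))
  years <- sort(unique(surface$year))
  if (length(years) < 2L) stop("surface must span at least 2 years")
  if (length(ages) < 2L) stop("surface must span at least 2 ages")
  if (nrow(surface) != length(ages) * length(years))
    stop("surface must be a complete age-by-year grid")
  A <- matrix(NA_real_, length(ages), length(years),
              dimnames = list(ages, years))
  A[cbind(match(surface$age, ages), match(surface$year, years))] <- log(surface$rate)
  if (anyNA(A)) stop("surface must be a complete age-by-year grid")

  fit1 <- function(M, w) {
    alpha <- rowSums(M * rep(w, each = nrow(M))) / sum(w)
    R <- M - alpha
    sv <- svd(R * rep(sqrt(w), each = nrow(R)))
    if (sv$d[1L] < 1e-12) {  # no time variation: flat index, uniform loadings
      beta <- rep(1 / nrow(M), nrow(M))
      return(list(alpha = alpha, beta = beta, k = numeric(ncol(M))))
    }
    beta <- sv$u[, 1L]
    k <- sv$d[1L] * sv$v[, 1L] / sqrt(w)
    sb <- sum(beta)
    if (abs(sb) < .Machine$double.eps^0.5) sb <- 1  # degenerate: no age pattern
    beta <- beta / sb
    k <- k * sb
    mk <- mean(k)
    list(alpha = alpha + beta * mk, beta = beta, k = k - mk)
  }
  w <- rep(1, length(years))
  f <- fit1(A, w)
  fitted <- f$alpha + f$beta %o% f$k
  if (weights == "inverse-variance") {
    # one re-weighted pass: ages with larger residual variance count less,
    # implemented by scaling each age row before the singular decomposition
    res_age <- apply(A - fitted, 1L, stats::var)
    res_age[res_age < 1e-12] <- 1e-12
    wa <- 1 / res_age
    wa <- wa / mean(wa)
    alpha <- rowMeans(A)
    R <- (A - alpha) * sqrt(wa)
    sv <- svd(R)
    beta <- sv$u[, 1L] / sqrt(wa)
    k <- sv$d[1L] * sv$v[, 1L]
    sb <- sum(beta)
    beta <- beta / sb
    k <- k * sb
    mk <- mean(k)
    f <- list(alpha = alpha + beta * mk, beta = beta, k = k - mk)
    fitted <- f$alpha + f$beta %o% f$k
  }
  dk <- diff(f$k)
  res <- A - fitted
  structure(list(
    ages = ages, years = years,
    alpha = unname(f$alpha), beta = unname(f$beta), k = unname(f$k),
    drift = mean(dk),
    innovation_sd = if (length(dk) > 1L) stats::sd(dk) else 0,
    residual_sd = sqrt(mean(res^2)),
    fitted = unname(fitted)
  ), class = "lee_carter")
}

#' Forecast the Lee-Carter time index
#'
#' Random walk with drift started at the last fitted `k`.  The drift is
#' itself uncertain: each path resamples the drift from its sampling
#' distribution (sd `innovation_sd / sqrt(n_years - 1)`), giving a
#' doubly-stochastic forecast.  With `innovation_sd = 0` and
#' `drift_uncertainty = FALSE` the path is linear in time.
#'
#' @param params a `lee_carter` fit (or any list with `k`, `drift`,
#'   `innovation_sd`).
#' @param horizon number of years ahead (>= 1).
#' @param n_paths number of sample paths.
#' @param seed optional integer seed.
#' @param drift_uncertainty resample the drift per path?
#' @return Matrix `horizon x n_paths` of forecast `k` values.
#' @export
forecast_k <- function(params, horizon, n_paths = 1L, seed = NULL,
                       drift_uncertainty = TRUE) {
  if (horizon < 1L) stop("horizon must be >= 1")
  if (n_paths < 1L) stop("n_paths must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  out <- matrix(NA_real_, horizon, n_paths)
  for (p in seq_len(n_paths))
    out[, p] <- draw_k_path(params, horizon, drift_uncertainty)
  out
}

# one k path using the current RNG state; the first n_warm steps stay at
# the deterministic drift
draw_k_path <- function(params, horizon, drift_uncertainty = TRUE,
                        stochastic = TRUE, n_warm = 0L) {
  kT <- params$k[length(params$k)]
  se <- params$innovation_sd / sqrt(max(length(params$k) - 1L, 1L))
  drift <- rep(params$drift, horizon)
  if (stochastic && drift_uncertainty && se > 0) {
    noisy <- params$drift + stats::rnorm(1L, 0, se)
    if (n_warm < horizon) drift[seq.int(n_warm + 1L, horizon)] <- noisy
  }
  eps <- if (stochastic && params$innovation_sd > 0)
    stats::rnorm(horizon, 0, params$innovation_sd) else numeric(horizon)
  if (n_warm > 0L) eps[seq_len(min(n_warm, horizon))] <- 0
  kT + cumsum(drift + eps)
}

#' Extend death rates to the ultimate age (Coale-Kisker closure)
#'
#' Old-age central rates are closed out by letting the age-to-age
#' log-rate increment decline linearly from its value at the pivot age to
#' whatever increment forces \eqn{m_\omega} to equal `closing_rate`.
#'
#' @param m named numeric vector of central rates by age (names are ages),
#'   or a matrix with age rows (rownames) and year columns; rates must be
#'   available at `pivot_age - 1` and `pivot_age`.
#' @param pivot_age last trusted age (default 84).
#' @param closing_rate central rate imposed at `omega` (default 0.8).
#' @param omega ultimate age (default 100).
#' @return Vector (or matrix) of rates covering ages up to `omega`; ages
#'   already present at or below the pivot are returned unchanged, ages
#'   above it are replaced by the closure.
#' @export
#' @examples
#' m <- 0.01 * exp(0.1 * (0:24))            # Gompertz, ages 60..84
#' names(m) <- 60:84
#' ext <- extend_old_age(m, pivot_age = 84, closing_rate = 0.8)
#' ext["100"]  # 0.8
extend_old_age <- function(m, pivot_age = 84L, closing_rate = 0.8, omega = 100L) {
  if (pivot_age >= omega) stop("pivot_age must be below omega")
  if (is.matrix(m)) {
    ages <- as.integer(rownames(m))
    if (!all(c(pivot_age - 1L, pivot_age) %in% ages))
      stop("rates must be available at the pivot age and the age below it")
    keep <- m[ages <= pivot_age, , drop = FALSE]
    lp <- log(m[as.character(pivot_age), ])
    d_piv <- lp - log(m[as.character(pivot_age - 1L), ])
    n <- omega - pivot_age
    slope <- (log(closing_rate) - lp - n * d_piv) / (n * (n + 1) / 2)
    # cumulative increments: k * d_piv + slope * k(k+1)/2
    k <- seq_len(n)
    cumincr <- outer(k, d_piv) + outer(k * (k + 1) / 2, slope)
    ext <- exp(rep(lp, each = n) + cumincr)
    out <- rbind(keep, ext)
    rownames(out) <- c(rownames(keep), seq(pivot_age + 1L, omega))
    return(out)
  }
  ages <- as.integer(names(m))
  if (is.null(names(m)) || anyNA(ages)) stop("'m' must be named by integer age")
  if (!all(c(pivot_age - 1L, pivot_age) %in% ages))
    stop("rates must be available at the pivot age and the age below it")
  keep <- m[ages <= pivot_age]
  d_piv <- log(m[as.character(pivot_age)]) - log(m[as.character(pivot_age - 1L)])
  n <- omega - pivot_age
  total <- log(closing_rate) - log(m[as.character(pivot_age)])
  slope <- (total - n * d_piv) / (n * (n + 1) / 2)
  incr <- d_piv + slope * seq_len(n)
  ext <- exp(log(m[as.character(pivot_age)]) + cumsum(incr))
  out <- c(keep, ext)
  names(out) <- c(names(keep), seq(pivot_age + 1L, omega))
  out
}

#' Convert central death rates to death probabilities
#'
#' Constant-hazard conversion \eqn{q = 1 - e^{-m}}.  At the ultimate age
#' the probability is forced to one: omega is absorbing.
#'
#' @param m non-negative central rates.
#' @param age optional ages matching `m`; where `age == omega`, `q` is 1.
#' @param omega ultimate age.
#' @return Death probabilities in `[0, 1]`.
#' @export
#' @examples
#' central_to_q(0.01)  # 0.00995017
central_to_q <- function(m, age = NULL, omega = 100L) {
  if (any(m < 0)) stop("central rates must be non-negative")
  q <- 1 - exp(-m)
  if (!is.null(age)) q[age == omega] <- 1
  q
}
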