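PARAM_NAMES <- c("mortality", "unemployment", "urbanization", "wage_growth",
                 "roi", "bookkeeping", "pension_growth", "enterprise_rate",
                 "individual_rate")

# scale one parameter's fixed path by (1 + tau/100), re-applying its caps
scale_par <- function(par, spec, parameter, tau) {
  f <- 1 + tau / 100
  switch(parameter,
    unemployment = { par$u <- pmin(pmax(par$u * f, 0), 1) },
    urbanization = { par$ub <- pmin(pmax(par$ub * f, 0), spec$urbanization$cap / 100) },
    wage_growth = { par$g <- pmin(pmax(par$g * f, spec$wage_growth$lower),
                                  spec$wage_growth$upper) },
    pension_growth = { par$rho <- par$rho * f },
    roi = { par$i <- par$i * f },
    bookkeeping = { par$j <- par$j * f },
    enterprise_rate = { par$b <- par$b * f },
    individual_rate = { par$c <- par$c * f },
    mortality = NULL,
    stop("unknown parameter: ", parameter)
  )
  par
}

#' Elasticity scan of the accumulated balance to one parameter
#'
#' Starting from the fixed-parameter baseline, the parameter's whole
#' value path is scaled by `(1 + tau/100)` for each `tau` on the grid
#' (integers -25..-1 and 1..25 by default, 50 runs), the deterministic
#' pipeline re-run, and the accumulated-balance path recorded.  The
#' direction class is read off the end-of-horizon balance over the grid:
#' `"same"` if non-decreasing in `tau`, `"reverse"` if non-increasing,
#' `"mixed"` otherwise.  Caps (urbanization 80%, wage growth 0-9.2%)
#' stay in force under scaling; mortality scales the central death
#' rates before the probability conversion.
#'
#' @param baseline a `pension_baseline` from [run_fixed_scenario()].
#' @param parameter one of `"mortality"`, `"unemployment"`,
#'   `"urbanization"`, `"wage_growth"`, `"roi"`, `"bookkeeping"`,
#'   `"pension_growth"`, `"enterprise_rate"`, `"individual_rate"`.
#' @param tau integer grid of percentage perturbations.
#' @return Object of class `sensitivity_result`: list with `parameter`,
#'   `tau`, `end_balance` (trillions), `balance_paths` (years x tau),
#'   `direction`.
#' @export
elasticity_scan <- function(baseline, parameter,
                            tau = c(-25:-1, 1:25)) {
  if (!parameter %in% PARAM_NAMES) stop("unknown parameter: ", parameter)
  prep <- baseline$prep
  years <- prep$report_years
  paths <- matrix(NA_real_, length(years), length(tau),
                  dimnames = list(years, tau))
  for (ti in seq_along(tau)) {
    par2 <- scale_par(baseline$par, prep$spec, parameter, tau[ti])
    ms <- if (parameter == "mortality") 1 + tau[ti] / 100 else 1
    res <- run_path(prep, par2, baseline$kpaths, mort_scale = ms)
    paths[, ti] <- res$table$ind4
  }
  endv <- paths[nrow(paths), ]
  tol <- 1e-9 * max(abs(endv), 1)
  dif <- diff(endv[order(tau)])
  direction <- if (all(dif >= -tol)) "same"
  else if (all(dif <= tol)) "reverse"
  else "mixed"
  structure(list(parameter = parameter, tau = tau, end_balance = endv,
                 balance_paths = paths, direction = direction),
            class = "sensitivity_result")
}

#' Influence index A of one parameter
#'
#' Fixes the remaining parameters at their baseline paths, lets only the
#' named parameter fluctuate, runs a Monte Carlo ensemble, and takes the
#' mean over forecast years of the width (upper minus lower) of the 95%
#' band of the accumulated balance.
#'
#' @param bundle a `pension_bundle`.
#' @param parameter one of the nine parameter names.
#' @param n_paths ensemble size (a warning is issued below 100: the
#'   band quantiles become unstable).
#' @param seed master seed.
#' @param policy,spec model settings.
#' @return Object of class `influence_index`: list with `parameter`,
#'   `A` (mean yearly band width, trillions), `band` (per-year limits),
#'   and the underlying `result`.
#' @export
influence_index <- function(bundle, parameter, n_paths = 5000L, seed = 1L,
                            policy = default_policy(),
                            spec = default_randomization_spec()) {
  if (!parameter %in% PARAM_NAMES) stop("unknown parameter: ", parameter)
  if (n_paths < 100L) warning("n_paths < 100: band quantiles are unstable")
  res <- run_monte_carlo(bundle, policy, spec, n_paths = n_paths, seed = seed,
                         fluctuate = parameter)
  band <- res$summary$ind4
  structure(list(parameter = parameter,
                 A = mean(band$upper - band$lower),
                 band = band, result = res),
            class = "influence_index")
}

#' Influence ranking of all nine parameters
#'
#' Runs [influence_index()] for every parameter at a common seed and
#' ranks them by descending index A.
#'
#' @inheritParams influence_index
#' @return Data frame `parameter`, `A`, `rank` (1 = most influential).
#' @export
influence_ranking <- function(bundle, n_paths = 5000L, seed = 1L,
                              policy = default_policy(),
                              spec = default_randomization_spec()) {
  A <- vapply(PARAM_NAMES, function(p)
    influence_index(bundle, p, n_paths, seed, policy, spec)$A, numeric(1L))
  out <- data.frame(parameter = PARAM_NAMES, A = unname(A))
  out$rank <- rank(-out$A, ties.method = "first")
  out[order(out$rank), ]
}

#' Backtrack parameter paths of the best and worst outcome deciles
#'
#' Splits the ensemble by final accumulated balance into the "better"
#' (top decile) and "worse" (bottom decile) groups and compares, for
#' each tracked parameter, the two groups' year-by-year mean value
#' paths.  A parameter is flagged divergent when the group means differ
#' by more than twice the pooled standard error over a contiguous run of
#' at least `run_len` years.  The number-of-insureds path summarizes the
#' joint mortality / unemployment / urbanization draw of each path.
#'
#' @param result a `pension_simulation` with stored paths.
#' @param params parameters to track (default: insured count, wage
#'   growth, ROI, bookkeeping rate, and both contribution rates).
#' @param run_len minimum run of significant years to flag divergence.
#' @return Object of class `backtrack_report`: list with `groups`
#'   (membership masks), `report` (long data frame: group, parameter,
#'   year, mean, se) and `flags` (parameter, divergent).
#' @export
backtrack <- function(result,
                      params = c("insured", "wage_growth", "roi",
                                 "bookkeeping", "enterprise_rate",
                                 "individual_rate"),
                      run_len = 10L) {
  if (is.null(result$paths)) stop("simulation result does not store per-path values")
  key <- c(insured = "insured", wage_growth = "g", roi = "i",
           bookkeeping = "j", enterprise_rate = "b", individual_rate = "c",
           unemployment = "u", urbanization = "ub", pension_growth = "rho")
  bad <- setdiff(params, names(key))
  if (length(bad)) stop("unknown parameter: ", bad[1L])
  fr <- final_reserve_distribution(result)
  years <- result$years
  rows <- list()
  flags <- data.frame(parameter = params, divergent = FALSE)
  for (pi in seq_along(params)) {
    m <- result$paths[[key[[params[pi]]]]]
    stats_g <- lapply(list(better = fr$top, worse = fr$bottom), function(mask) {
      sub <- m[, mask, drop = FALSE]
      n <- ncol(sub)
      mu <- rowMeans(sub)
      va <- apply(sub, 1L, stats::var)
      list(mean = mu, var = va, n = n)
    })
    se <- sqrt(stats_g$better$var / stats_g$better$n +
                 stats_g$worse$var / stats_g$worse$n)
    gap <- abs(stats_g$better$mean - stats_g$worse$mean)
    sig <- se > 0 & gap > 2 * se
    runs <- rle(sig)
    flags$divergent[pi] <- any(runs$values & runs$lengths >= run_len)
    for (gn in c("better", "worse")) {
      rows[[length(rows) + 1L]] <- data.frame(
        group = gn, parameter = params[pi], year = years,
        mean = stats_g[[gn]]$mean, se = se)
    }
  }
  structure(list(groups = list(better = fr$top, worse = fr$bottom, k = fr$k),
                 report = do.call(rbind, rows), flags = flags),
            class = "backtrack_report")
}

#' Run the full pipeline: bundle, baseline, ensemble, analytics
#'
#' Convenience driver binding all stages: generates (or reads) the
#' pseudo-yearbook bundle, runs the fixed-parameter baseline, the Monte
#' Carlo ensemble, the elasticity scan and influence index for every
#' parameter, and the decile backtracking, writing each result as CSV
#' into `out_dir` together with a small JSON manifest (seed, sizes).
#'
#' @param config a list as returned by [load_config()]; `bundle_dir`
#'   may name an existing bundle, otherwise a synthetic one is generated
#'   with the run seed.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @param n_influence ensemble size for the per-parameter influence
#'   runs (they cost one full ensemble each).
#' @return Invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config = load_config(NULL), out_dir = NULL,
                         n_influence = 500L) {
  out_dir <- if (!is.null(out_dir)) out_dir else config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  bundle <- if (!is.null(config$bundle_dir) && dir.exists(config$bundle_dir))
    read_bundle(config$bundle_dir)
  else generate_bundle(synth_config(seed = config$seed))

  base <- run_fixed_scenario(bundle, config$policy, config$spec)
  utils::write.csv(base$table, file.path(out_dir, "baseline_indicators.csv"),
                   row.names = FALSE)
  utils::write.csv(base$aging, file.path(out_dir, "baseline_aging.csv"),
                   row.names = FALSE)

  sim <- run_monte_carlo(bundle, config$policy, config$spec,
                         n_paths = config$n_paths, seed = config$seed)
  for (nm in names(sim$summary))
    utils::write.csv(sim$summary[[nm]],
                     file.path(out_dir, paste0("band_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(data.frame(path_id = seq_along(sim$final_balance),
                              final_balance = sim$final_balance),
                   file.path(out_dir, "final_balances.csv"), row.names = FALSE)

  scans <- lapply(PARAM_NAMES, function(p) elasticity_scan(base, p))
  names(scans) <- PARAM_NAMES
  utils::write.csv(do.call(rbind, lapply(scans, function(s)
    data.frame(parameter = s$parameter, tau = s$tau,
               end_balance = unname(s$end_balance),
               direction = s$direction))),
    file.path(out_dir, "sensitivity.csv"), row.names = FALSE)

  infl <- influence_ranking(bundle, n_paths = n_influence, seed = config$seed,
                            policy = config$policy, spec = config$spec)
  utils::write.csv(infl, file.path(out_dir, "influence.csv"), row.names = FALSE)

  bt <- backtrack(sim)
  utils::write.csv(bt$report, file.path(out_dir, "backtrack_paths.csv"),
                   row.names = FALSE)
  utils::write.csv(bt$flags, file.path(out_dir, "backtrack_flags.csv"),
                   row.names = FALSE)

  jsonlite::write_json(
    list(seed = config$seed, n_paths = config$n_paths,
         n_influence = n_influence,
         horizon = c(config$policy$start_year, config$policy$end_year),
         depletion_year = depletion_year(base$table)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)

  invisible(list(bundle = bundle, baseline = base, simulation = sim,
                 scans = scans, influence = infl, backtrack = bt))
}
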