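#' Prepare a projection environment from a pseudo-yearbook bundle
#'
#' Fits the Lee-Carter model per sex on the bundled mortality history,
#' fits nothing else (the randomization spec carries the stochastic
#' recursions), assembles the historical wage / bookkeeping / pension
#' growth series with backward extension, extracts initial conditions
#' for the parameter recursions, and fixes the projection calendar:
#' population projected from the base-year pyramid, fund stock rolled
#' from its valuation year through the pre-report year, indicators
#' reported from `start_year` to `end_year`.
#'
#' @param bundle a `pension_bundle` (see [generate_bundle()] /
#'   [read_bundle()]).
#' @param policy a [default_policy()] list.
#' @param spec a [default_randomization_spec()] list.
#' @return A list of class `projection_prep`.
#' @export
prepare_projection <- function(bundle, policy = default_policy(),
                               spec = default_randomization_spec()) {
  needed <- c("population_initial", "mortality_hist", "fertility_schedule",
              "tfr_path", "srb_path", "unemployment_hist", "urbanization_hist",
              "wage_hist", "deposit_rate_hist", "initial_conditions")
  miss <- setdiff(needed, names(bundle))
  if (length(miss)) stop("bundle is missing table: ", miss[1L])

  ic <- stats::setNames(bundle$initial_conditions$value,
                        bundle$initial_conditions$name)
  base_year <- as.integer(if ("base_year" %in% names(ic)) ic["base_year"]
                          else policy$base_year)
  proj_years <- seq.int(base_year + 1L, policy$end_year)

  lc <- lapply(c(m = "m", f = "f"), function(sx) {
    sub <- bundle$mortality_hist[bundle$mortality_hist$sex == sx, ]
    fit_lee_carter(data.frame(year = sub$year, age = sub$age,
                              rate = sub$central_rate))
  })

  # historical wage levels and growth, extended back to the series origin
  wh <- bundle$wage_hist[order(bundle$wage_hist$year), ]
  g_hist <- diff(wh$avg_wage) / wh$avg_wage[-nrow(wh)]
  hist_start <- 1950L
  years_full <- seq.int(hist_start, policy$end_year)
  g_back <- mean(g_hist)
  sbar_hist <- numeric(base_year - hist_start + 1L)
  names(sbar_hist) <- seq.int(hist_start, base_year)
  sbar_hist[as.character(wh$year)] <- wh$avg_wage
  for (y in rev(seq.int(hist_start, wh$year[1L] - 1L)))
    sbar_hist[as.character(y)] <- sbar_hist[as.character(y + 1L)] / (1 + g_back)
  g_hist_full <- diff(sbar_hist) / sbar_hist[-length(sbar_hist)]

  dep <- bundle$deposit_rate_hist
  j_hist <- stats::setNames(rep(mean(dep$rate), base_year - hist_start + 1L),
                            seq.int(hist_start, base_year))
  j_hist[as.character(dep$year)] <- dep$rate

  u_h <- bundle$unemployment_hist$rate
  ub_h <- bundle$urbanization_hist$rate
  init <- list(
    u = u_h[length(u_h)], du = diff(u_h)[length(u_h) - 1L],
    ub = ub_h[length(ub_h)], dub = diff(ub_h)[length(ub_h) - 1L],
    g = g_hist[length(g_hist)], dg = diff(g_hist)[length(g_hist) - 1L],
    i = unname(ic["initial_roi"])
  )

  fert <- list(
    schedule = bundle$fertility_schedule[, c("age", "coefficient")],
    tfr = bundle$tfr_path,
    srb = bundle$srb_path
  )
  # extend fertility paths over any missing projected years
  for (nm in c("tfr", "srb")) {
    f <- fert[[nm]]
    val <- names(f)[2L]
    missing_years <- setdiff(proj_years, f$year)
    if (length(missing_years)) {
      add <- f[rep(which.max(f$year), length(missing_years)), ]
      add$year <- missing_years
      fert[[nm]] <- rbind(f, add)
    }
  }
  names(fert$schedule) <- c("age", "coefficient")

  structure(list(
    policy = policy, spec = spec,
    base_year = base_year, proj_years = proj_years,
    flow_years = seq.int(policy$fund_year + 1L, policy$end_year),
    report_years = seq.int(policy$start_year, policy$end_year),
    years_full = years_full,
    lc = lc,
    initial = bundle$population_initial,
    fert = fert,
    sbar_hist = sbar_hist, g_hist_full = g_hist_full,
    j_hist = j_hist,
    init = init,
    initial_fund = unname(ic["initial_fund"]),
    initial_wage = unname(ic["initial_wage"])
  ), class = "projection_prep")
}

# death-probability array [age 0..omega, proj year, sex] from k paths
build_q_array <- function(prep, kpaths, mort_scale = 1) {
  pol <- prep$policy
  ages <- 0:pol$omega
  yrs <- prep$proj_years
  q <- array(NA_real_, c(length(ages), length(yrs), 2L),
             dimnames = list(ages, yrs, c("m", "f")))
  for (sx in c("m", "f")) {
    lc <- prep$lc[[sx]]
    m_raw <- exp(lc$alpha + lc$beta %o% kpaths[[sx]]) * mort_scale
    rownames(m_raw) <- lc$ages
    m_ext <- extend_old_age(m_raw, pol$ck_pivot, pol$ck_close, pol$omega)
    qs <- central_to_q(m_ext)
    qs[nrow(qs), ] <- 1  # omega absorbing
    q[, , sx] <- qs
  }
  q
}

# one full deterministic projection given parameter and mortality paths;
# par holds vectors over prep$proj_years (fractions)
run_path <- function(prep, par, kpaths, mort_scale = 1) {
  pol <- prep$policy
  e <- pol$e; omega <- pol$omega; z <- pol$z; s <- pol$s
  yrs <- prep$proj_years
  H <- length(yrs)

  q <- build_q_array(prep, kpaths, mort_scale)
  pop <- project_population(prep$initial, prep$fert, q, yrs, omega)
  P <- pop$P

  fac <- (1 - par$u) * par$ub * coverage_rate(yrs, pol)
  cl <- pol$classes
  W <- Rt <- Din <- Dret <- vector("list", nrow(cl))
  names(W) <- names(Rt) <- names(Din) <- names(Dret) <- cl$class
  for (ic in seq_len(nrow(cl))) {
    r <- cl$r[ic]; sx <- cl$sex[ic]
    aw <- e:(r - 1L); ar <- r:omega
    W[[ic]] <- P[as.character(aw), , sx] * cl$share[ic] *
      rep(fac * pol$enterprise_share, each = length(aw))
    Rt[[ic]] <- P[as.character(ar), , sx] * cl$share[ic] *
      rep(fac * pol$retiree_share, each = length(ar))
    Din[[ic]] <- W[[ic]] * q[as.character(aw), , sx]
    Dret[[ic]] <- Rt[[ic]] * q[as.character(ar), , sx]
  }

  # salary-profile normalization from the pooled in-service distribution
  num <- den <- numeric(H)
  for (ic in seq_len(nrow(cl))) {
    aw <- e:(cl$r[ic] - 1L)
    gr <- (1 + s)^(aw - e)
    num <- num + colSums(W[[ic]])
    den <- den + colSums(W[[ic]] * gr)
  }
  Fnorm_fore <- num / den

  # full economic series (history + this path's forecast)
  yf <- prep$years_full
  nh <- prep$base_year - yf[1L] + 1L          # history length
  sbar <- c(prep$sbar_hist, prep$initial_wage * cumprod(1 + par$g))
  mult <- prep$spec$pension_growth_multiplier
  rho <- c(mult * prep$g_hist_full[1L], mult * prep$g_hist_full, par$rho)[seq_along(yf)]
  # (first history year has no growth observation; reuse the next one)
  jser <- c(unname(prep$j_hist), par$j)
  cser <- c(rep(prep$spec$individual_rate$mean, nh), par$c)
  bser <- c(rep(prep$spec$enterprise_rate$mean, nh), par$b)
  Fser <- c(rep(Fnorm_fore[1L], nh), Fnorm_fore)
  series <- economy_series(yf, unname(sbar), rho, jser, cser, bser, pol$d, Fser)

  # per-person account balances: ages e..max(r)-1, years z..end
  acc_years <- seq.int(z, pol$end_year)
  acc_ages <- e:(max(cl$r) - 1L)
  B2 <- matrix(0, length(acc_ages), length(acc_years),
               dimnames = list(acc_ages, acc_years))
  for (yi in seq_along(acc_years)) {
    y <- acc_years[yi]
    iy <- ser_i(series, y)
    contrib <- series$c_rate[iy] * series$d[iy] *
      salary_at(series, y - 1L, acc_ages - 1L, s, e)
    prev <- if (yi == 1L) 0 else c(0, B2[-length(acc_ages), yi - 1L])
    B2[, yi] <- (1 + series$j[iy]) * (prev + contrib)
  }

  # benefit tables by retirement year per class (vectorized over years)
  ret_all <- seq.int(z + 1L, pol$end_year)
  bases <- vector("list", nrow(cl))
  names(bases) <- cl$class
  i_ret1 <- ser_i(series, ret_all - 1L)
  for (ic in seq_len(nrow(cl))) {
    r <- cl$r[ic]
    K <- r - e
    pow <- (1 + s)^(r - seq_len(K) - 1L - e)          # k = 1..K
    # hmat[ri, k] = d_{ret-k} * F_{ret-k-1} * (1+s)^(r-k-1-e)
    ri_k <- outer(ret_all, seq_len(K), "-")            # ret - k
    hmat <- matrix(series$d[ser_i(series, as.vector(ri_k))] *
                     series$Fnorm[ser_i(series, as.vector(ri_k) - 1L)],
                   nrow = length(ret_all)) *
      rep(pow, each = length(ret_all))
    hcum <- t(apply(hmat, 1L, cumsum))
    n_ctr <- pmin(ret_all - z, K)
    mbar <- hcum[cbind(seq_along(ret_all), n_ctr)] / n_ctr
    B0 <- series$sbar[i_ret1] / 2 * (1 + mbar) * n_ctr / 100
    pre <- K - (ret_all - z)
    T0 <- ifelse(pre > 0,
                 series$sbar[i_ret1] *
                   (hcum[cbind(seq_along(ret_all), pmin(pmax(ret_all - z, 1L), K))] /
                      pmax(ret_all - z, 1L)) * pmax(pre, 0) * pol$epsilon,
                 0)
    bal <- B2[as.character(r - 1L), as.character(ret_all - 1L)]
    I0 <- individual_account_pension(bal, cl$m_r[ic])
    names(B0) <- names(T0) <- names(I0) <- ret_all
    bases[[ic]] <- list(B0 = B0, T0 = T0, I0 = I0)
  }

  fy <- prep$flow_years
  flows <- engine_flows(prep, series, cl, W, Rt, Din, Dret, bases, B2, fy)

  # roll the fund stock through the pre-report years, then tabulate
  roi_flow <- par$i[match(fy, yrs)]
  pre <- fy < pol$start_year
  fund <- prep$initial_fund
  for (k in which(pre))
    fund <- accumulate_balance(fund, roi_flow[k], flows$balance[k])
  rep_rows <- !pre
  table <- indicator_table(flows[rep_rows, c("year", "contributions", "expenditures")],
                           fund, roi_flow[rep_rows])

  # aging of the insured population (report years)
  ri <- match(prep$report_years, yrs)
  eld <- list(m = 0, f = 0); tot <- list(m = 0, f = 0)
  for (ic in seq_len(nrow(cl))) {
    sx <- cl$sex[ic]
    ar <- cl$r[ic]:omega
    eld[[sx]] <- eld[[sx]] + colSums(Rt[[ic]][ar >= 60, ri, drop = FALSE])
    tot[[sx]] <- tot[[sx]] + colSums(Rt[[ic]][, ri]) + colSums(W[[ic]][, ri])
  }
  insured_total <- tot$m + tot$f

  list(table = table, flows = flows, fund_pre_report = fund,
       elderly = eld, insured_by_sex = tot, insured_total = insured_total,
       Fnorm = Fnorm_fore, series = series,
       internals = list(bases = bases, W = W, Rt = Rt, Din = Din,
                        Dret = Dret, B2 = B2, q = q, pop = pop))
}

# vectorized yearly flows over all flow years at once; the per-year
# reference implementation is yearly_fund_flow(), against which this is
# cross-checked in the test suite
engine_flows <- function(prep, series, cl, W, Rt, Din, Dret, bases, B2, fy) {
  pol <- prep$policy
  e <- pol$e; z <- pol$z; s <- pol$s; omega <- pol$omega
  yrs <- prep$proj_years
  fi <- match(fy, yrs)
  nT <- length(fy)
  i_t <- ser_i(series, fy)
  i_tm1 <- i_t - 1L
  clr <- series$cumlogrho
  rho_t <- series$rho[i_t]
  wage_prev <- series$Fnorm[i_tm1] * series$sbar[i_tm1]

  # previous-year per-person balances aligned to account ages
  acc_ages <- as.integer(rownames(B2))
  prevB <- matrix(0, length(acc_ages), nT, dimnames = list(acc_ages, fy))
  ci <- match(fy - 1L, as.integer(colnames(B2)))
  prevB[-1L, ] <- B2[-nrow(B2), ci]

  zero <- numeric(nT)
  out <- list(pooling_contrib = zero, individual_contrib = zero,
              old_basic = zero, middle_basic = zero, middle_transition = zero,
              middle_account_pool = zero, new_basic = zero,
              new_account_pool = zero, account_individual = zero,
              refund_in_service = zero, refund_retiree = zero)

  for (ic in seq_len(nrow(cl))) {
    r <- cl$r[ic]; m_r <- cl$m_r[ic]
    aw <- e:(r - 1L); ar <- r:omega
    nA <- length(ar)
    Wm <- W[[ic]][, fi, drop = FALSE]
    Rm <- Rt[[ic]][, fi, drop = FALSE]
    Dim <- Din[[ic]][, fi, drop = FALSE]
    Drm <- Dret[[ic]][, fi, drop = FALSE]

    pow_prev <- (1 + s)^(aw - 1L - e)
    payroll <- colSums(Wm * pow_prev) * wage_prev * series$d[i_t]
    out$pooling_contrib <- out$pooling_contrib + series$b_rate[i_t] * payroll
    out$individual_contrib <- out$individual_contrib + series$c_rate[i_t] * payroll

    retM <- outer(r - ar, fy, "+")                 # retirement year per cell
    iret <- retM - series$years[1L] + 1L
    X <- exp(rep(clr[i_t], each = nA) - clr[iret - 1L])
    X <- if (pol$index_denominator == "retirement-year")
      X / (1 + series$rho[iret]) else X / rep(1 + rho_t, each = nA)
    dim(X) <- dim(retM)

    oldm <- retM <= z
    midm <- retM > z & retM <= z + (r - e)
    newm <- retM > z + (r - e)
    pos <- pmax(retM - z, 1L)                      # index into ret z+1..end
    mk <- function(v) { m <- v[pos]; dim(m) <- dim(retM); m }
    B0m <- mk(bases[[ic]]$B0)
    T0m <- mk(bases[[ic]]$T0)
    I0m <- mk(bases[[ic]]$I0)
    PO0m <- pol$R_hat * (1 + s)^(r - 1L - e) *
      series$Fnorm[iret - 1L] * series$sbar[iret - 1L]
    dim(PO0m) <- dim(retM)

    out$old_basic <- out$old_basic + colSums(Rm * PO0m * X * oldm)
    out$middle_basic <- out$middle_basic + colSums(Rm * B0m * X * midm)
    out$new_basic <- out$new_basic + colSums(Rm * B0m * X * newm)
    out$middle_transition <- out$middle_transition + colSums(Rm * T0m * X * midm)

    payer_ind <- (ar - r) < m_r / 12
    acct_mid <- Rm * I0m * midm
    acct_new <- Rm * I0m * newm
    out$account_individual <- out$account_individual +
      colSums((acct_mid + acct_new)[payer_ind, , drop = FALSE])
    out$middle_account_pool <- out$middle_account_pool +
      colSums(acct_mid[!payer_ind, , drop = FALSE])
    out$new_account_pool <- out$new_account_pool +
      colSums(acct_new[!payer_ind, , drop = FALSE])

    fac <- pmax(m_r / 12 - (ar - r) - 1, 0)
    out$refund_retiree <- out$refund_retiree +
      colSums(Drm * I0m * (midm | newm) * fac)

    contribM <- outer(pow_prev, wage_prev * series$c_rate[i_t] * series$d[i_t])
    out$refund_in_service <- out$refund_in_service +
      colSums(Dim * (prevB[as.character(aw), , drop = FALSE] + contribM))
  }

  pool_exp <- out$old_basic + out$middle_basic + out$middle_transition +
    out$middle_account_pool + out$new_basic + out$new_account_pool
  ind_exp <- out$account_individual + out$refund_in_service + out$refund_retiree
  contributions <- out$pooling_contrib + out$individual_contrib
  expenditures <- pool_exp + ind_exp
  data.frame(year = fy, as.data.frame(out),
             pooling_exp = pool_exp, individual_exp = ind_exp,
             contributions = contributions, expenditures = expenditures,
             balance = contributions - expenditures)
}

# fixed-parameter path (all innovations at their mean)
fixed_paths <- function(prep) {
  H <- length(prep$proj_years)
  par <- draw_param_path(prep$spec, prep$init, H, fluctuate = "none",
                         fixed_j = prep$policy$fixed_j)
  kp <- lapply(prep$lc, function(lcf)
    draw_k_path(lcf, H, stochastic = FALSE))
  list(par = par, kpaths = kp)
}

#' Run the fixed-parameter baseline scenario
#'
#' Every stochastic recursion is advanced with innovations at their mean
#' (zero) and every distributional draw at its mean (enterprise rate
#' 0.16, individual rate 0.08, bookkeeping rate at the lognormal mean by
#' default), and the deterministic pipeline is run once.
#'
#' @param bundle a `pension_bundle`.
#' @param policy a [default_policy()] list.
#' @param spec a [default_randomization_spec()] list.
#' @return Object of class `pension_baseline`: list with the indicator
#'   `table`, the flow components `flows`, aging summaries `aging`, the
#'   parameter paths `par`, and the reusable `prep`.
#' @export
run_fixed_scenario <- function(bundle, policy = default_policy(),
                               spec = default_randomization_spec()) {
  prep <- prepare_projection(bundle, policy, spec)
  fx <- fixed_paths(prep)
  res <- run_path(prep, fx$par, fx$kpaths)
  aging <- data.frame(
    year = rep(prep$report_years, 2L),
    sex = rep(c("m", "f"), each = length(prep$report_years)),
    elderly_count = c(res$elderly$m, res$elderly$f),
    total = c(res$insured_by_sex$m, res$insured_by_sex$f)
  )
  aging$elderly_share <- aging$elderly_count / aging$total
  structure(list(table = res$table, flows = res$flows, aging = aging,
                 par = fx$par, kpaths = fx$kpaths, insured_total = res$insured_total,
                 prep = prep),
            class = "pension_baseline")
}

#' Monte Carlo ensemble of the pension projection
#'
#' Draws `n_paths` independent joint parameter paths (each including its
#' own mortality-index path) from one master seed, runs the full
#' deterministic pipeline on each, and summarizes the six indicators by
#' per-year median, mean and empirical 2.5% / 97.5% quantiles (order
#' statistics).  Deterministic given `seed`: each path consumes its own
#' substream, so results do not depend on evaluation order.
#'
#' @param bundle a `pension_bundle`.
#' @param policy a [default_policy()] list.
#' @param spec a [default_randomization_spec()] list.
#' @param n_paths ensemble size (>= 2).
#' @param seed master seed.
#' @param fluctuate `"all"`, or a subset of the nine parameter names to
#'   let fluctuate while the rest stay fixed (used by
#'   [influence_index()]).
#' @param progress_every log a line every so many paths (0 = silent).
#' @return Object of class `pension_simulation`: per-year indicator
#'   matrices (`paths$ind1` ... `paths$ind6`, years by paths), stored
#'   parameter paths, insured totals, final accumulated balances
#'   (trillions), and band `summary` per indicator.
#' @export
run_monte_carlo <- function(bundle, policy = default_policy(),
                            spec = default_randomization_spec(),
                            n_paths = 5000L, seed = 1L, fluctuate = "all",
                            progress_every = 0L) {
  if (n_paths < 2L) stop("n_paths must be >= 2")
  prep <- prepare_projection(bundle, policy, spec)
  H <- length(prep$proj_years)
  ry <- prep$report_years
  ri <- match(ry, prep$proj_years)
  nr <- length(ry)
  mort_on <- identical(fluctuate, "all") || "mortality" %in% fluctuate

  set.seed(seed)
  path_seeds <- sample.int(.Machine$integer.max - 1L, n_paths)

  ind_names <- paste0("ind", 1:6)
  paths <- stats::setNames(
    lapply(seq_len(6 + 9), function(i) matrix(NA_real_, nr, n_paths,
                                              dimnames = list(ry, NULL))),
    c(ind_names, "u", "ub", "g", "rho", "i", "j", "b", "c", "insured"))
  for (p in seq_len(n_paths)) {
    set.seed(path_seeds[p])
    par <- draw_param_path(prep$spec, prep$init, H, fluctuate,
                           prep$policy$fixed_j, n_warm = ri[1L] - 1L)
    kp <- list(
      m = draw_k_path(prep$lc$m, H, stochastic = mort_on, n_warm = ri[1L] - 1L),
      f = draw_k_path(prep$lc$f, H, stochastic = mort_on, n_warm = ri[1L] - 1L))
    res <- run_path(prep, par, kp)
    for (nm in ind_names) paths[[nm]][, p] <- res$table[[nm]]
    for (nm in c("u", "ub", "g", "rho", "i", "j", "b", "c"))
      paths[[nm]][, p] <- par[[nm]][ri]
    paths$insured[, p] <- res$insured_total
    if (progress_every > 0L && p %% progress_every == 0L)
      message("path ", p, " / ", n_paths)
  }

  qs <- function(m) data.frame(
    year = ry,
    mean = rowMeans(m, na.rm = TRUE),
    median = apply(m, 1L, stats::median, na.rm = TRUE),
    lower = apply(m, 1L, stats::quantile, probs = 0.025, type = 1, na.rm = TRUE),
    upper = apply(m, 1L, stats::quantile, probs = 0.975, type = 1, na.rm = TRUE))
  summary <- lapply(paths[ind_names], qs)

  structure(list(years = ry, n_paths = n_paths, seed = seed,
                 fluctuate = fluctuate, paths = paths,
                 final_balance = paths$ind4[nr, ],
                 summary = summary, prep = prep),
            class = "pension_simulation")
}

#' Distribution of the final accumulated balance across an ensemble
#'
#' Sorts the end-of-horizon accumulated balances from small to large and
#' marks the bottom and top deciles (`floor(n/10)` paths each), the
#' "worse" and "better" fund-reserve groups.
#'
#' @param result a `pension_simulation`.
#' @return List with `sorted` (ascending final balances), `cut_lower`
#'   (10% quantile order statistic), `cut_upper` (90%), `bottom` and
#'   `top` (logical membership masks over paths), `k` (group size).
#' @export
final_reserve_distribution <- function(result) {
  fin <- result$final_balance
  n <- length(fin)
  k <- n %/% 10L
  ord <- order(fin)
  bottom <- top <- logical(n)
  bottom[ord[seq_len(k)]] <- TRUE
  top[ord[seq.int(n - k + 1L, n)]] <- TRUE
  sorted <- fin[ord]
  list(sorted = sorted,
       cut_lower = sorted[k], cut_upper = sorted[n - k + 1L],
       bottom = bottom, top = top, k = k)
}
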