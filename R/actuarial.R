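#' Economic series container for the actuarial model
#'
#' Bundles the yearly series every benefit formula reads: the weighted
#' average wage, pension growth rate, bookkeeping interest rate,
#' individual and enterprise contribution rates, the contributory-salary
#' ratio, and the salary-profile normalization factor `Fnorm` (the ratio
#' of the entry-age salary to the average wage implied by the in-service
#' age distribution and seniority growth).
#'
#' @param years consecutive calendar years covered.
#' @param sbar average wage per year (yuan/year).
#' @param rho pension growth rate per year (fraction).
#' @param j bookkeeping interest rate per year (fraction).
#' @param c_rate individual contribution rate per year.
#' @param b_rate enterprise contribution rate per year.
#' @param d contributory-to-statistical salary ratio (scalar or vector).
#' @param Fnorm salary normalization factor per year.
#' @return A list of class `economy_series`.
#' @export
economy_series <- function(years, sbar, rho, j, c_rate, b_rate, d, Fnorm) {
  n <- length(years)
  if (any(diff(years) != 1L)) stop("years must be consecutive")
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  out <- list(years = years, sbar = rec(sbar), rho = rec(rho), j = rec(j),
              c_rate = rec(c_rate), b_rate = rec(b_rate), d = rec(d),
              Fnorm = rec(Fnorm))
  lens <- vapply(out[-1L], length, 1L)
  if (any(lens != n)) stop("all series must match the length of 'years'")
  out$cumlogrho <- cumsum(log1p(out$rho))
  class(out) <- "economy_series"
  out
}

ser_i <- function(series, year) {
  i <- year - series$years[1L] + 1L
  if (any(i < 1L | i > length(series$years)))
    stop("year ", paste(year[i < 1L | i > length(series$years)], collapse = ","),
         " outside the economic series")
  i
}

# salary of an x-year-old in year t under the seniority structure
salary_at <- function(series, t, x, s, e) {
  i <- ser_i(series, t)
  series$Fnorm[i] * series$sbar[i] * (1 + s)^(x - e)
}

#' Indexation factor applied to basic, transition and legacy pensions
#'
#' The product \eqn{\prod_{h=ret}^{t}(1+\rho_h)} divided by
#' \eqn{(1+\rho_t)} (the as-printed convention) or by
#' \eqn{(1+\rho_{ret})} (the retirement-year convention); with constant
#' \eqn{\rho} both telescope to \eqn{(1+\rho)^{t-ret}}.
#'
#' @param series an [economy_series()].
#' @param t current year; `ret` retirement year(s), `ret <= t`.
#' @param ret retirement year(s).
#' @param denominator `"as-printed"` or `"retirement-year"`.
#' @return Numeric factor(s).
#' @export
pension_index <- function(series, t, ret, denominator = "as-printed") {
  it <- ser_i(series, t)
  ir <- ser_i(series, ret)
  num <- exp(series$cumlogrho[it] -
               ifelse(ir > 1L, series$cumlogrho[ir - 1L], 0))
  den <- if (denominator == "retirement-year") 1 + series$rho[ir] else 1 + series$rho[it]
  num / den
}

#' Build the seniority salary profile for one year
#'
#' Salaries grow with seniority at rate `s`, so
#' \eqn{S_{t,x} = (1+s)^{x-e} S_{t,e}}; the entry-age salary is pinned
#' down by requiring the insured-weighted mean salary to equal the
#' average wage: \eqn{S_{t,e} = \bar S_t \sum_x L_x / \sum_x L_x (1+s)^{x-e}}.
#'
#' @param sbar average wage (yuan/year).
#' @param counts in-service insured counts by age.
#' @param ages ages matching `counts`.
#' @param s seniority growth rate.
#' @param e entry age.
#' @return List with `S_e`, `Fnorm` (= `S_e / sbar`), `ages`, `salary`
#'   (vector of `S_x`).
#' @export
#' @examples
#' build_salary_profile(105, c(1, 1), c(20, 21), s = 0.10)$salary  # 100, 110
build_salary_profile <- function(sbar, counts, ages, s, e = 20L) {
  if (sbar <= 0) stop("average wage must be positive")
  if (length(counts) == 0L || sum(counts) <= 0) stop("no insureds: cannot build a salary profile")
  gr <- (1 + s)^(ages - e)
  Fnorm <- sum(counts) / sum(counts * gr)
  S_e <- sbar * Fnorm
  list(S_e = S_e, Fnorm = Fnorm, ages = ages, salary = S_e * gr)
}

#' Contribution revenues for one year
#'
#' Pooling-account revenue is the enterprise rate times the contributory
#' payroll \eqn{\sum_{x=e}^{r-1} L_{t,x}\, d_t\, S_{t-1,x-1}} (previous
#' year's salary at the previous age); individual-account revenue is the
#' same payroll times the individual rate.
#'
#' @param t calendar year.
#' @param classes list of class ledgers, each with `r` and `in_service`
#'   (counts named by age).
#' @param series an [economy_series()] covering `t - 1` and `t`.
#' @param policy a [default_policy()] list.
#' @return List with `pooling`, `individual`, `payroll`.
#' @export
contribution_revenue <- function(t, classes, series, policy) {
  it <- ser_i(series, t)
  payroll <- 0
  for (cc in classes) {
    L <- cc$in_service
    if (!length(L)) next
    x <- as.integer(names(L))
    payroll <- payroll + sum(L * series$d[it] * salary_at(series, t - 1L, x - 1L,
                                                          policy$s, policy$e))
  }
  list(pooling = series$b_rate[it] * payroll,
       individual = series$c_rate[it] * payroll,
       payroll = payroll)
}

# mean indexed contribution-wage ratio over the n years before retirement:
# (1/n) sum_{k=1..n} d_{ret-k} S_{ret-k-1, r-k-1} / sbar_{ret-k-1}
mean_contribution_ratio <- function(series, ret, r, n, s, e) {
  if (n < 1L) return(0)
  k <- seq_len(n)
  i <- ser_i(series, ret - k - 1L)
  mean(series$d[ser_i(series, ret - k)] * series$Fnorm[i] * (1 + s)^(r - k - 1L - e))
}

#' Basic pension at retirement, before indexation
#'
#' Half the prior-year average wage, scaled by one plus the mean
#' contribution-wage ratio over the contribution years, times one
#' percent per contribution year (`min(ret - z, r - e)` years).
#'
#' @param ret retirement year(s), `>= z + 1`.
#' @param r retirement age of the class.
#' @param series an [economy_series()].
#' @param policy a [default_policy()] list.
#' @return Currency per person per year, at retirement-year value.
#' @export
basic_pension_base <- function(ret, r, series, policy) {
  vapply(ret, function(rt) {
    n <- min(rt - policy$z, r - policy$e)
    if (n < 1L) stop("contribution years must be positive (retirement year ", rt, ")")
    mbar <- mean_contribution_ratio(series, rt, r, n, policy$s, policy$e)
    series$sbar[ser_i(series, rt - 1L)] / 2 * (1 + mbar) * n / 100
  }, numeric(1L))
}

#' Transition pension at retirement, before indexation
#'
#' Compensates middle people for their `r - e - (ret - z)` pre-reform
#' years at coefficient `epsilon` per year, scaled by the prior-year
#' average wage and the mean contribution-wage ratio over the post-reform
#' years.  Zero for new people (no pre-reform years).
#'
#' @inheritParams basic_pension_base
#' @return Currency per person per year, at retirement-year value.
#' @export
transition_pension_base <- function(ret, r, series, policy) {
  vapply(ret, function(rt) {
    ny <- rt - policy$z
    pre <- r - policy$e - ny
    if (pre <= 0L) return(0)
    mbar <- mean_contribution_ratio(series, rt, r, ny, policy$s, policy$e)
    series$sbar[ser_i(series, rt - 1L)] * mbar * pre * policy$epsilon
  }, numeric(1L))
}

#' Individual-account balance at retirement
#'
#' Contributions `c_k d_k S_{k-1, x_k - 1}` credited from
#' `max(z, ret - r + e)` through `ret - 1` and compounded at the
#' bookkeeping rates of the contribution year through `ret - 1`.
#'
#' @inheritParams basic_pension_base
#' @return Balance (currency) per person at the start of the retirement
#'   year.
#' @export
account_balance_at_retirement <- function(ret, r, series, policy) {
  clj <- cumsum(log1p(series$j))
  vapply(ret, function(rt) {
    kmin <- max(policy$z, rt - r + policy$e)
    if (kmin > rt - 1L) return(0)
    k <- seq.int(kmin, rt - 1L)
    ik <- ser_i(series, k)
    iend <- ser_i(series, rt - 1L)
    contrib <- series$c_rate[ik] * series$d[ik] *
      salary_at(series, k - 1L, r - (rt - k) - 1L, policy$s, policy$e)
    growth <- exp(clj[iend] - clj[ik] + log1p(series$j[ik]))
    sum(contrib * growth)
  }, numeric(1L))
}

#' Individual-account pension annuity
#'
#' Twelve times the retirement balance divided by the stipulated payment
#' months; fixed in nominal terms after retirement.
#'
#' @param balance account balance at retirement (>= 0).
#' @param m_r stipulated payment months (139 / 195 / 170 for retirement
#'   ages 60 / 50 / 55).
#' @return Currency per person per year.
#' @export
#' @examples
#' individual_account_pension(139000, 139)  # 12000 / year
individual_account_pension <- function(balance, m_r) {
  if (any(m_r <= 0)) stop("m_r must be positive")
  if (any(balance < 0)) stop("balance must be >= 0")
  12 * balance / m_r
}

#' Which account pays the account pension at a given age
#'
#' The individual account pays while the years since retirement are
#' strictly below `m_r / 12`; afterwards the pooling account takes over.
#' The split never changes the total paid.
#'
#' @param x current age(s).
#' @param r retirement age.
#' @param m_r stipulated payment months.
#' @return `"individual"` or `"pooling"` per age.
#' @export
#' @examples
#' account_payer(65, 60, 139)  # individual (5 < 139/12)
account_payer <- function(x, r, m_r) {
  ifelse(x - r < m_r / 12, "individual", "pooling")
}

#' Basic pension payable in year t to a cohort retired in `ret`
#'
#' @inheritParams basic_pension_base
#' @param t payment year (`>= ret`).
#' @return Currency per person per year, indexed to `t`.
#' @export
basic_pension <- function(t, ret, r, series, policy) {
  basic_pension_base(ret, r, series, policy) *
    pension_index(series, t, ret, policy$index_denominator)
}

#' Transition pension payable in year t to a cohort retired in `ret`
#'
#' @inheritParams basic_pension
#' @return Currency per person per year, indexed to `t`.
#' @export
transition_pension <- function(t, ret, r, series, policy) {
  transition_pension_base(ret, r, series, policy) *
    pension_index(series, t, ret, policy$index_denominator)
}

# legacy pension of a pre-reform retiree: replacement rate times the
# salary earned at age r-1 the year before retirement, indexed to t
old_people_pension <- function(t, ret, r, series, policy) {
  salary_at(series, ret - 1L, r - 1L, policy$s, policy$e) * policy$R_hat *
    pension_index(series, t, ret, policy$index_denominator)
}

#' Pension expenditure on pre-reform ("old") retirees in year t
#'
#' Sums, over the old-people age range, the retiree counts times the
#' legacy pension (replacement rate `R_hat` applied to the salary at
#' `r - 1` in the year before retirement, indexed to `t`).  Paid wholly
#' by the pooling account.
#'
#' @param t calendar year.
#' @param retired counts named by age (`r..omega`) for one class.
#' @param r retirement age of the class.
#' @param series an [economy_series()].
#' @param policy a [default_policy()] list.
#' @return Currency total.
#' @export
old_people_expenditure <- function(t, retired, r, series, policy) {
  rng <- cohort_age_ranges(t, r, policy$e, policy$z, policy$omega)$old
  ages <- intersect(as.integer(names(retired)), rng)
  if (!length(ages)) return(0)
  L <- retired[as.character(ages)]
  ret <- t - (ages - r)
  if (min(ret) - 1L < series$years[1L])
    stop("wage history missing before retirement year ", min(ret))
  sum(L * old_people_pension(t, ret, r, series, policy))
}

#' Individual-account refunds on death in year t
#'
#' In-service decedents refund their accumulated account balance
#' (last year's balance plus the current-year contribution, no interest
#' in the death year); retirees dying within the stipulated months
#' refund the remaining annuity years `m_r/12 - (x - r) - 1` times their
#' account pension.
#'
#' @param t calendar year.
#' @param classes list of class ledgers: `r`, `m_r`, `deaths_in` and
#'   `deaths_ret` (deaths named by age), and `I_by_ret` (account pension
#'   per retirement year, named by year) or `NULL` to compute it.
#' @param accounts_prev per-person account balances at the end of
#'   `t - 1`, named by age.
#' @param series an [economy_series()].
#' @param policy a [default_policy()] list.
#' @return List with `in_service`, `retiree`, `total`.
#' @export
death_refunds <- function(t, classes, accounts_prev, series, policy) {
  it <- ser_i(series, t)
  ref_in <- 0
  ref_ret <- 0
  for (cc in classes) {
    D <- cc$deaths_in
    if (length(D)) {
      x <- as.integer(names(D))
      contrib <- series$c_rate[it] * series$d[it] *
        salary_at(series, t - 1L, x - 1L, policy$s, policy$e)
      prev <- ifelse(x - 1L >= policy$e, accounts_prev[as.character(x - 1L)], 0)
      prev[is.na(prev)] <- 0
      ref_in <- ref_in + sum(D * (prev + contrib))
    }
    Dr <- cc$deaths_ret
    if (length(Dr)) {
      hi <- min(cc$r + t - policy$z - 1L, cc$r + floor(cc$m_r / 12) - 1L)
      x <- as.integer(names(Dr))
      x <- x[x >= cc$r & x <= hi]
      if (length(x)) {
        ret <- t - (x - cc$r)
        I <- if (!is.null(cc$I_by_ret)) cc$I_by_ret[as.character(ret)]
        else individual_account_pension(
          account_balance_at_retirement(ret, cc$r, series, policy), cc$m_r)
        fac <- pmax(cc$m_r / 12 - (x - cc$r) - 1, 0)
        ref_ret <- ref_ret + sum(Dr[as.character(x)] * fac * I)
      }
    }
  }
  list(in_service = ref_in, retiree = ref_ret, total = ref_in + ref_ret)
}

#' Assemble the full fund flow for one year
#'
#' Combines contribution revenues, the legacy pensions of old people,
#' the basic/transition/account pensions of middle and new retirees
#' (with the account pension charged to the individual account within
#' the stipulated months and to the pooling account afterwards), and
#' death refunds, into the year's pooling and individual account flows.
#'
#' @param t calendar year.
#' @param ins list with `classes` (per class: `r`, `m_r`, `in_service`,
#'   `retired`, `deaths_in`, `deaths_ret`, all counts named by age) and
#'   `accounts_prev` (per-person balances at end of `t - 1`, named by
#'   age).
#' @param series an [economy_series()].
#' @param policy a [default_policy()] list.
#' @param bases optional precomputed per-class benefit tables (list per
#'   class with `B0`, `T0`, `I0` named by retirement year) as built by
#'   the projection engine; computed on the fly when `NULL`.
#' @return List of class `fund_flow` with contribution and expenditure
#'   components, `contributions`, `expenditures` and `balance` totals.
#' @export
yearly_fund_flow <- function(t, ins, series, policy, bases = NULL) {
  classes <- ins$classes
  rev <- contribution_revenue(t, classes, series, policy)
  comp <- c(old_basic = 0, middle_basic = 0, middle_transition = 0,
            middle_account_pool = 0, new_basic = 0, new_account_pool = 0,
            account_individual = 0)
  for (cn in names(classes)) {
    cc <- classes[[cn]]
    rng <- cohort_age_ranges(t, cc$r, policy$e, policy$z, policy$omega)
    retired <- cc$retired
    comp["old_basic"] <- comp["old_basic"] +
      old_people_expenditure(t, retired, cc$r, series, policy)
    for (grp in c("middle", "new")) {
      ages <- intersect(as.integer(names(retired)), rng[[grp]])
      ages <- ages[retired[as.character(ages)] > 0]
      if (!length(ages)) next
      L <- retired[as.character(ages)]
      ret <- t - (ages - cc$r)
      if (is.null(bases)) {
        B <- basic_pension(t, ret, cc$r, series, policy)
        TT <- transition_pension(t, ret, cc$r, series, policy)
        I <- individual_account_pension(
          account_balance_at_retirement(ret, cc$r, series, policy), cc$m_r)
      } else {
        bb <- bases[[cn]]
        idx <- pension_index(series, t, ret, policy$index_denominator)
        B <- bb$B0[as.character(ret)] * idx
        TT <- bb$T0[as.character(ret)] * idx
        I <- bb$I0[as.character(ret)]
      }
      ind <- account_payer(ages, cc$r, cc$m_r) == "individual"
      comp[paste0(grp, "_basic")] <- comp[paste0(grp, "_basic")] + sum(L * B)
      if (grp == "middle")
        comp["middle_transition"] <- comp["middle_transition"] + sum(L * TT)
      comp[paste0(grp, "_account_pool")] <-
        comp[paste0(grp, "_account_pool")] + sum(L * I * !ind)
      comp["account_individual"] <- comp["account_individual"] + sum(L * I * ind)
    }
    if (!is.null(bases)) classes[[cn]]$I_by_ret <- bases[[cn]]$I0
  }
  ref <- death_refunds(t, classes, ins$accounts_prev, series, policy)
  pool_exp <- sum(comp[c("old_basic", "middle_basic", "middle_transition",
                         "middle_account_pool", "new_basic", "new_account_pool")])
  ind_exp <- comp[["account_individual"]] + ref$total
  structure(list(
    year = t,
    pooling_contrib = rev$pooling,
    individual_contrib = rev$individual,
    old_basic = comp[["old_basic"]],
    middle_basic = comp[["middle_basic"]],
    middle_transition = comp[["middle_transition"]],
    middle_account_pool = comp[["middle_account_pool"]],
    new_basic = comp[["new_basic"]],
    new_account_pool = comp[["new_account_pool"]],
    account_individual = comp[["account_individual"]],
    refund_in_service = ref$in_service,
    refund_retiree = ref$retiree,
    pooling_exp = pool_exp,
    individual_exp = ind_exp,
    contributions = rev$pooling + rev$individual,
    expenditures = pool_exp + ind_exp,
    balance = rev$pooling + rev$individual - pool_exp - ind_exp
  ), class = "fund_flow")
}
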