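#' Accumulated-balance recursion
#'
#' A positive balance carried into the year earns the return on
#' investment before the year's flow is added; a zero or negative
#' balance earns nothing: `prev > 0` gives `prev * (1 + i) + flow`,
#' otherwise `prev + flow`.
#'
#' @param prev balance at the end of the previous year.
#' @param i return on investment for the current year (fraction).
#' @param flow current-year balance of contributions and expenditures.
#' @return New accumulated balance.
#' @export
#' @examples
#' accumulate_balance(10, 0.05, -1)   # 9.5
#' accumulate_balance(-10, 0.05, -1)  # -11: deficits earn no interest
accumulate_balance <- function(prev, i, flow) {
  ifelse(prev > 0, prev * (1 + i) + flow, prev + flow)
}

#' Six fund-reserve indicators from a flow series
#'
#' Per year: indicator 1 is expenditures over contributions; indicator 2
#' the balance of contributions and expenditures; indicator 3 the
#' current payment gap (negative balance, else zero) over contributions;
#' indicator 4 the accumulated balance under the
#' [accumulate_balance()] recursion; indicator 5 the fund ratio (the
#' prior-year-end accumulated fund, credited with the year's return,
#' over current expenditures; reported as 0 once reserves are
#' exhausted); indicator 6 the accumulated gap over contributions,
#' defined only while the accumulated balance is negative (`NA`
#' otherwise).
#'
#' @param flows data frame with columns `year`, `contributions`,
#'   `expenditures` (or a list of `fund_flow` rows).
#' @param initial_fund accumulated balance at the end of the year before
#'   the first flow year.
#' @param roi return-on-investment path, one value per flow year.
#' @param unit divisor applied to monetary columns on output (default
#'   `1e12`: report trillions when flows are in yuan).
#' @return Data frame of class `indicator_table`: `year`, `ind1`..`ind6`,
#'   `contributions`, `expenditures` (monetary columns scaled by
#'   `unit`).
#' @export
indicator_table <- function(flows, initial_fund, roi, unit = 1e12) {
  if (inherits(flows, "fund_flow")) flows <- list(flows)
  if (is.list(flows) && !is.data.frame(flows))
    flows <- data.frame(year = vapply(flows, `[[`, 1, "year"),
                        contributions = vapply(flows, `[[`, 1, "contributions"),
                        expenditures = vapply(flows, `[[`, 1, "expenditures"))
  n <- nrow(flows)
  if (length(roi) == 1L) roi <- rep(roi, n)
  if (length(roi) != n) stop("roi path must cover every flow year")
  ctr <- flows$contributions
  exp_ <- flows$expenditures
  ind2 <- ctr - exp_
  ind4 <- numeric(n)
  ind5 <- numeric(n)
  prev <- initial_fund
  for (t in seq_len(n)) {
    credited <- if (prev > 0) prev * (1 + roi[t]) else prev
    ind5[t] <- if (prev > 0 && exp_[t] > 0) credited / exp_[t] else 0
    ind4[t] <- accumulate_balance(prev, roi[t], ind2[t])
    prev <- ind4[t]
  }
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  out <- data.frame(
    year = flows$year,
    ind1 = safe_div(exp_, ctr),
    ind2 = ind2 / unit,
    ind3 = safe_div(pmax(-ind2, 0), ctr),
    ind4 = ind4 / unit,
    ind5 = ind5,
    ind6 = ifelse(ind4 < 0, safe_div(-ind4, ctr), NA_real_),
    contributions = ctr / unit,
    expenditures = exp_ / unit
  )
  class(out) <- c("indicator_table", "data.frame")
  out
}

#' First year the accumulated balance turns negative
#'
#' @param table an [indicator_table()].
#' @return The depletion year, or `NA` if reserves are never exhausted.
#' @export
depletion_year <- function(table) {
  if (nrow(table) == 0L) stop("empty indicator table")
  hit <- which(table$ind4 < 0)
  if (!length(hit)) NA_integer_ else as.integer(table$year[hit[1L]])
}

#' Trend statistics of the indicator series
#'
#' Average annual growth rate of indicator 1 (geometric rate between the
#' first and last year); average annual change of indicators 2 and 4
#' (end minus start, over the number of yearly steps); annual average
#' change rate of indicators 3 and 6 (end value minus the value in the
#' first year the respective gap appears, over the years between).
#'
#' @param table an [indicator_table()] or any data frame with `year` and
#'   indicator columns (e.g. one band of an ensemble summary).
#' @return List with `ind1_growth`, `ind2_change`, `ind4_change`,
#'   `ind3_change_rate`, `ind6_change_rate`, `gap_year`,
#'   `depletion_year` (rates `NA` when the gap never opens).
#' @export
trend_statistics <- function(table) {
  n <- nrow(table)
  if (n < 2L) stop("need at least two years")
  steps <- table$year[n] - table$year[1L]
  first_last <- function(v) c(v[1L], v[n])
  g1 <- first_last(table$ind1)
  gap <- which(table$ind2 < 0)
  dep <- which(table$ind4 < 0)
  rate_from <- function(v, at) {
    if (!length(at)) return(NA_real_)
    a <- at[1L]
    dy <- table$year[n] - table$year[a]
    if (dy <= 0) return(NA_real_)
    (v[n] - v[a]) / dy
  }
  list(
    ind1_growth = (g1[2L] / g1[1L])^(1 / steps) - 1,
    ind2_change = (table$ind2[n] - table$ind2[1L]) / steps,
    ind4_change = (table$ind4[n] - table$ind4[1L]) / steps,
    ind3_change_rate = rate_from(table$ind3, gap),
    ind6_change_rate = rate_from(table$ind6, dep),
    gap_year = if (length(gap)) as.integer(table$year[gap[1L]]) else NA_integer_,
    depletion_year = if (length(dep)) as.integer(table$year[dep[1L]]) else NA_integer_
  )
}
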