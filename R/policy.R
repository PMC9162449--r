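#' Default policy parameters
#'
#' Scalar constants of the pension scheme: entry age, class-specific
#' retirement ages and stipulated payment months, the 1997 reform year,
#' seniority-salary growth, the transition coefficient, the
#' contributory-to-statistical salary ratio, the legacy replacement rate,
#' and the initial fund stock / wage / return on investment.
#'
#' @details
#' Insureds enter employment at age `e` and the scheme distinguishes three
#' retirement classes: male workers (retire at 60, 139 payment months),
#' female workers (50, 195 months) and female cadres (55, 170 months);
#' female insureds split 4:1 into workers and cadres.  `d` is the ratio of
#' contributory salary to statistical salary, `epsilon` the transition
#' pension coefficient (admissible range 1--1.4%), `R_hat` the replacement
#' rate of pre-reform retirees.  Monetary amounts are in yuan.
#'
#' @param ... named overrides of any default field.
#' @return A list of class `pension_policy`.
#' @export
#' @examples
#' p <- default_policy()
#' p$classes
default_policy <- function(...) {
  pol <- list(
    e = 20L,
    omega = 100L,
    z = 1997L,
    classes = data.frame(
      class = c("male_worker", "female_worker", "female_cadre"),
      sex = c("m", "f", "f"),
      r = c(60L, 50L, 55L),
      m_r = c(139L, 195L, 170L),
      share = c(1, 0.8, 0.2),
      stringsAsFactors = FALSE
    ),
    s = 0.01363,                 # seniority salary growth / year
    epsilon = 0.012,             # transition coefficient / pre-reform year
    d = 0.6089,                  # contributory / statistical salary
    R_hat = 0.7163,              # replacement rate of pre-reform retirees
    enterprise_share = 0.9370,
    retiree_share = 0.9440,
    coverage_start = c(year = 2015, rate = 0.85),
    coverage_end = c(year = 2025, rate = 0.95),
    initial_fund = 4440.17e9,    # yuan, end of fund_year
    fund_year = 2020L,
    initial_wage = 63182,        # yuan / year, at base_year
    initial_roi = 0.0689,
    base_year = 2019L,           # year of the initial population pyramid
    start_year = 2022L,          # first reported forecast year
    end_year = 2094L,
    ck_pivot = 84L,              # Coale-Kisker pivot age
    ck_close = 0.8,              # central death rate forced at omega
    index_denominator = "as-printed",  # or "retirement-year"
    fixed_j = "mean"             # or "median"
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(pol))
    if (length(bad)) stop("unknown policy field(s): ", paste(bad, collapse = ", "))
    pol[names(ov)] <- ov
  }
  # tolerate YAML round-trips, which turn vectors/frames into lists
  pol$coverage_start <- unlist(pol$coverage_start)
  pol$coverage_end <- unlist(pol$coverage_end)
  if (!is.data.frame(pol$classes))
    pol$classes <- as.data.frame(pol$classes, stringsAsFactors = FALSE)
  class(pol) <- "pension_policy"
  validate_policy(pol)
  pol
}

validate_policy <- function(pol) {
  cl <- pol$classes
  if (any(pol$e >= cl$r)) stop("policy field 'e': entry age must precede every retirement age")
  if (any(cl$r >= pol$omega)) stop("policy field 'classes$r': retirement age must precede omega")
  if (pol$epsilon < 0.01 || pol$epsilon > 0.014)
    stop("policy field 'epsilon': outside admissible range [0.01, 0.014]")
  if (pol$d <= 0 || pol$d > 1) stop("policy field 'd': must lie in (0, 1]")
  if (pol$start_year >= pol$end_year) stop("policy field 'start_year': must precede end_year")
  if (pol$ck_pivot >= pol$omega) stop("policy field 'ck_pivot': must be below omega")
  if (!pol$index_denominator %in% c("as-printed", "retirement-year"))
    stop("policy field 'index_denominator': must be 'as-printed' or 'retirement-year'")
  if (!pol$fixed_j %in% c("mean", "median"))
    stop("policy field 'fixed_j': must be 'mean' or 'median'")
  sh <- cl$share[cl$sex == "f"]
  if (abs(sum(sh) - 1) > 1e-12) stop("policy field 'classes$share': female shares must sum to 1")
  invisible(pol)
}

#' Pension insurance coverage rate schedule
#'
#' Linear rise of one percentage point per year between the schedule
#' anchors (85% in 2015 to 95% in 2025 by default), clamped outside.
#'
#' @param years integer vector of calendar years.
#' @param policy a [default_policy()] list.
#' @return Numeric vector of coverage rates (fractions).
#' @export
#' @examples
#' coverage_rate(2020)  # 0.90
coverage_rate <- function(years, policy = default_policy()) {
  a <- policy$coverage_start
  b <- policy$coverage_end
  slope <- (b["rate"] - a["rate"]) / (b["year"] - a["year"])
  unname(a["rate"] + slope * (pmin(pmax(years, a["year"]), b["year"]) - a["year"]))
}

#' Load a run configuration from a YAML file
#'
#' The file may override any policy field, any randomization-spec field,
#' and the run controls `n_paths`, `seed`, `bundle_dir`, `out_dir`.
#' An empty (or missing `policy:`/`spec:`) file yields the full defaults.
#' Out-of-range overrides are rejected with the field name.
#'
#' @param file path to a YAML file.
#' @return A list with elements `policy`, `spec`, `n_paths`, `seed`,
#'   `bundle_dir`, `out_dir`.
#' @export
load_config <- function(file) {
  raw <- if (is.null(file)) list() else yaml::read_yaml(file)
  if (is.null(raw)) raw <- list()
  pol <- do.call(default_policy, if (is.null(raw$policy)) list() else raw$policy)
  spec <- default_randomization_spec()
  if (!is.null(raw$spec)) {
    bad <- setdiff(names(raw$spec), names(spec))
    if (length(bad)) stop("unknown spec field(s): ", paste(bad, collapse = ", "))
    for (nm in names(raw$spec)) {
      if (is.list(spec[[nm]])) spec[[nm]] <- utils::modifyList(spec[[nm]], raw$spec[[nm]])
      else spec[[nm]] <- raw$spec[[nm]]
    }
    validate_randomization_spec(spec)
  }
  list(
    policy = pol,
    spec = spec,
    n_paths = if (is.null(raw$n_paths)) 5000L else as.integer(raw$n_paths),
    seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
    bundle_dir = raw$bundle_dir,
    out_dir = raw$out_dir
  )
}

#' Save a run configuration to YAML
#'
#' @param config a list as returned by [load_config()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
save_config <- function(config, file) {
  out <- list(
    policy = unclass(config$policy),
    spec = config$spec,
    n_paths = config$n_paths,
    seed = config$seed,
    bundle_dir = config$bundle_dir,
    out_dir = config$out_dir
  )
  out$policy$classes <- NULL  # structural, not a scalar override
  # keep field names through YAML (named vectors would flatten to lists)
  out$policy$coverage_start <- as.list(out$policy$coverage_start)
  out$policy$coverage_end <- as.list(out$policy$coverage_end)
  yaml::write_yaml(out, file)
  invisible(file)
}
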