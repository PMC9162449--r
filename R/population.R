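#' Cohort-component population projection
#'
#' Advances an age-sex pyramid one calendar year at a time: survivors
#' move up one age, \eqn{P_{t,x} = P_{t-1,x-1}(1 - q_{t,x})}, and births
#' enter age 0 as \eqn{\sum_{x=15}^{49} P^F_{t,x}\,TFR_t\,\bar h_x},
#' split between the sexes by the sex ratio at birth
#' (males get \eqn{SRB/(1+SRB)}).  No migration.  The ultimate age
#' \eqn{\omega} is absorbing (death probability one), so no cohort
#' outlives it.
#'
#' @param initial data frame `age`, `sex` (`"m"`/`"f"`), `count` covering
#'   ages `0..omega` for both sexes (the base-year pyramid).
#' @param fert list with `schedule` (data frame `age`, `coefficient`
#'   over ages 15-49, summing to 1), `tfr` (data frame `year`, `tfr`) and
#'   `srb` (data frame `year`, `srb`).
#' @param q death probabilities: array `[age 0..omega, year, sex]` with
#'   dimnames, covering every projected year.
#' @param years calendar years to project (first year is one step after
#'   the base year).
#' @param omega ultimate age.
#' @return Object of class `population_projection`: list with `years`
#'   and `P`, an array `[age, year, sex]` of counts.
#' @export
project_population <- function(initial, fert, q, years, omega = 100L) {
  if (length(years) < 1L) stop("horizon must be >= 1")
  ages <- 0:omega
  P0 <- matrix(0, length(ages), 2L, dimnames = list(ages, c("m", "f")))
  for (sx in c("m", "f")) {
    sub <- initial[initial$sex == sx, ]
    if (!setequal(sub$age, ages)) stop("initial pyramid must cover ages 0..omega for sex ", sx)
    P0[as.character(sub$age), sx] <- sub$count
  }
  if (any(P0 < 0)) stop("population counts must be >= 0")
  sched <- numeric(length(ages))
  sc <- fert$schedule
  if (any(sc$age < 15 | sc$age > 49)) stop("fertility schedule supported on ages 15-49 only")
  sched[match(sc$age, ages)] <- sc$coefficient
  qdim <- dimnames(q)
  if (!all(as.character(years) %in% qdim[[2L]]))
    stop("mortality forecast must cover every projected year")

  P <- array(0, c(length(ages), length(years), 2L),
             dimnames = list(ages, years, c("m", "f")))
  prev <- P0
  for (ti in seq_along(years)) {
    yr <- as.character(years[ti])
    cur <- matrix(0, length(ages), 2L, dimnames = dimnames(P0))
    for (sx in c("m", "f")) {
      qs <- q[, yr, sx]
      cur[-1L, sx] <- prev[-nrow(prev), sx] * (1 - qs[-1L])
    }
    tfr <- fert$tfr$tfr[match(years[ti], fert$tfr$year)]
    srb <- fert$srb$srb[match(years[ti], fert$srb$year)]
    if (is.na(tfr) || is.na(srb)) stop("fertility inputs missing for year ", years[ti])
    if (srb <= 0) stop("sex ratio at birth must be > 0")
    births <- sum(cur[, "f"] * sched * tfr)
    cur["0", "m"] <- births * srb / (1 + srb)
    cur["0", "f"] <- births * 1 / (1 + srb)
    P[, ti, ] <- cur
    prev <- cur
  }
  structure(list(years = years, P = P), class = "population_projection")
}

#' @export
as.data.frame.population_projection <- function(x, ...) {
  d <- dim(x$P)
  data.frame(
    year = rep(x$years, each = d[1L], times = d[3L]),
    age = rep(as.integer(dimnames(x$P)[[1L]]), times = d[2L] * d[3L]),
    sex = rep(c("m", "f"), each = d[1L] * d[2L]),
    count = as.vector(x$P),
    stringsAsFactors = FALSE
  )
}

# core ledger arithmetic shared by the exported builder and the engine:
# pop_m / pop_f are full age vectors (0..omega); returns per-class vectors
insured_core <- function(pop_by_sex, u, ub, coverage, policy) {
  for (r in c(u, ub, coverage)) if (r < 0 || r > 1) stop("rate outside [0, 1]")
  fac <- (1 - u) * ub * coverage
  cl <- policy$classes
  out <- vector("list", nrow(cl))
  names(out) <- cl$class
  ages <- as.integer(names(pop_by_sex[[1L]]))
  for (ic in seq_len(nrow(cl))) {
    r <- cl$r[ic]
    pop <- pop_by_sex[[cl$sex[ic]]] * cl$share[ic]
    work <- ages >= policy$e & ages < r
    ret <- ages >= r
    out[[ic]] <- list(
      r = r, m_r = cl$m_r[ic], sex = cl$sex[ic],
      in_service = pop[work] * fac * policy$enterprise_share,
      retired = pop[ret] * fac * policy$retiree_share
    )
  }
  out
}

#' Insured counts from a population state
#'
#' In-service insureds at age x are the population at that age times the
#' labor participation rate (one minus unemployment), the urbanization
#' rate, the pension coverage rate, and the enterprise share of urban
#' insured employees; retired insureds are the analogous product with
#' the enterprise share of urban retirees.  Female insureds split 4:1
#' into workers (retiring at 50) and cadres (retiring at 55).
#'
#' @param pop data frame `age`, `sex`, `count` for one year.
#' @param u,ub,coverage unemployment, urbanization and coverage rates
#'   (fractions in `[0,1]`).
#' @param q optional death probabilities (array slice or list of named
#'   vectors per sex) used to add a `deaths` column.
#' @param policy a [default_policy()] list.
#' @return Data frame `age`, `sex`, `class`, `status`
#'   (`"in_service"`/`"retired"`), `count` (and `deaths` when `q` given).
#' @export
insured_counts <- function(pop, u, ub, coverage, q = NULL,
                           policy = default_policy()) {
  pops <- lapply(c(m = "m", f = "f"), function(sx) {
    sub <- pop[pop$sex == sx, ]
    stats::setNames(sub$count, sub$age)[as.character(0:policy$omega)]
  })
  if (anyNA(pops$m) || anyNA(pops$f)) stop("population must cover ages 0..omega")
  core <- insured_core(pops, u, ub, coverage, policy)
  rows <- lapply(names(core), function(cn) {
    cc <- core[[cn]]
    rbind(
      data.frame(age = as.integer(names(cc$in_service)), sex = cc$sex,
                 class = cn, status = "in_service", count = cc$in_service,
                 row.names = NULL),
      data.frame(age = as.integer(names(cc$retired)), sex = cc$sex,
                 class = cn, status = "retired", count = cc$retired,
                 row.names = NULL)
    )
  })
  led <- do.call(rbind, rows)
  if (!is.null(q)) {
    qv <- if (is.list(q)) q else list(m = q[, "m"], f = q[, "f"])
    led$deaths <- led$count *
      mapply(function(a, s) qv[[s]][as.character(a)], led$age, led$sex)
  }
  led
}

#' Classify an insured into the old / middle / new cohort
#'
#' Relative to the reform year `z`: retired before `z` is "old", joined
#' before `z` but retired in `z` or later is "middle", joined in `z` or
#' later is "new".
#'
#' @param join_year,retire_year calendar years (join <= retire).
#' @param z reform year.
#' @return Character vector: `"old"`, `"middle"` or `"new"`.
#' @export
#' @examples
#' classify_cohort(1970, 1996)  # old
classify_cohort <- function(join_year, retire_year, z = 1997L) {
  if (any(join_year > retire_year)) stop("join_year must be <= retire_year")
  ifelse(retire_year < z, "old",
         ifelse(join_year < z, "middle", "new"))
}

#' Retiree age ranges for the three cohorts in a given year
#'
#' Old people occupy ages `[r + t - z, omega]`; retired middle people
#' `[max(r, r + t - z - 1 - l_m), r + t - z - 1]` with
#' `l_m = r - e - 1`; retired new people `[r, t - z + e - 1]`.  From
#' `t = z - e + omega + 1` on, every retiree is a new person.
#'
#' @param t calendar year (must be >= `z`).
#' @param r retirement age.
#' @param e entry age.
#' @param z reform year.
#' @param omega ultimate age.
#' @return List with integer vectors `old`, `middle`, `new` (possibly
#'   empty) partitioning the occupied retiree ages.
#' @export
#' @examples
#' cohort_age_ranges(2000, r = 60)  # middle 60:62, old 63:100
cohort_age_ranges <- function(t, r, e = 20L, z = 1997L, omega = 100L) {
  if (t < z) stop("model starts at the reform year: t must be >= z")
  l_m <- r - e - 1L
  rng <- function(lo, hi) if (lo > hi) integer(0) else seq.int(lo, hi)
  old <- rng(min(r + t - z, omega + 1L), omega)
  middle <- rng(max(r, r + t - z - 1L - l_m), min(r + t - z - 1L, omega))
  new <- rng(r, min(t - z + e - 1L, omega))
  list(old = old, middle = middle, new = new)
}

#' Aging indicators of the insured population
#'
#' Elderly insureds are those aged 60 and above; reported per sex and
#' overall as a count and as a share of all insureds.
#'
#' @param ledger data frame as returned by [insured_counts()], possibly
#'   spanning several years (column `year` optional).
#' @param elderly_age threshold age (default 60).
#' @return Data frame `year` (if present), `sex`, `elderly_count`,
#'   `total`, `elderly_share`.
#' @export
aging_indicators <- function(ledger, elderly_age = 60L) {
  if (nrow(ledger) == 0L) stop("empty ledger")
  if (!"year" %in% names(ledger)) ledger$year <- NA_integer_
  key <- paste(ledger$year, ledger$sex)
  rows <- lapply(split(ledger, key), function(d) {
    data.frame(year = d$year[1L], sex = d$sex[1L],
               elderly_count = sum(d$count[d$age >= elderly_age]),
               total = sum(d$count))
  })
  out <- do.call(rbind, rows)
  out$elderly_share <- ifelse(out$total > 0, out$elderly_count / out$total, 0)
  rownames(out) <- NULL
  out[order(out$year, out$sex, na.last = FALSE), ]
}
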