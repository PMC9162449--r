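flat_pyramid <- function(count = 100) {
  rbind(data.frame(age = 0:100, sex = "m", count = count),
        data.frame(age = 0:100, sex = "f", count = count))
}

make_q <- function(years, qfun, omega = 100L) {
  ages <- 0:omega
  q <- array(rep(qfun(ages), times = length(years) * 2),
             c(length(ages), length(years), 2),
             dimnames = list(ages, years, c("m", "f")))
  q[as.character(omega), , ] <- 1
  q
}

no_fert <- function(years, tfr = 0, srb = 1.1) {
  list(schedule = data.frame(age = 15:49, coefficient = rep(1 / 35, 35)),
       tfr = data.frame(year = years, tfr = tfr),
       srb = data.frame(year = years, srb = srb))
}

test_that("with no births and no deaths the pyramid shifts up one age per year", {
  years <- 2020:2029
  q <- make_q(years, function(a) 0)
  pp <- project_population(flat_pyramid(), no_fert(years), q, years)
  # cohorts exit only at the absorbing ultimate age: one age group per year
  expect_equal(sum(pp$P[, 1, ]), 2 * 100 * 99)
  expect_equal(sum(pp$P[, 10, ]), 2 * 100 * 90)
  # survivorship identity: each age is last year's age below it
  expect_equal(pp$P[2:100, 5, "f"], pp$P[1:99, 4, "f"], ignore_attr = TRUE)
})

test_that("a unit sex ratio splits newborns equally", {
  years <- 2020:2021
  q <- make_q(years, function(a) 0)
  pp <- project_population(flat_pyramid(), no_fert(years, tfr = 1.8, srb = 1),
                           q, years)
  expect_equal(pp$P["0", 1, "m"], pp$P["0", 1, "f"])
  expect_gt(pp$P["0", 1, "m"], 0)
})

test_that("fertility calibrated to a unit Leslie eigenvalue keeps the population constant", {
  omega <- 100L
  ages <- 0:omega
  qv <- 0.002 + 0.0005 * pmax(ages - 50, 0)   # mild senescent mortality
  qv[omega + 1] <- 1
  s <- 1 - qv
  sched <- exp(-0.5 * ((15:49 - 27) / 5)^2)
  sched <- sched / sum(sched)
  srb <- 1.05
  phi <- 1 / (1 + srb)                        # female share of births
  hfull <- numeric(omega + 1)
  hfull[16:50] <- sched                       # hfull[a + 1] = h_a
  # oracle: female Leslie matrix with births taken from the survived
  # population (the projector's convention): newborns at t depend on
  # P_{t-1, a-1} through h_a * (1 - q_a)
  A0 <- matrix(0, omega + 1, omega + 1)
  for (i in 2:(omega + 1)) A0[i, i - 1] <- s[i]
  bvec <- numeric(omega + 1)
  for (a in 15:49) bvec[a] <- phi * hfull[a + 1] * s[a + 1]
  lam1 <- function(tfr) {
    A <- A0
    A[1, ] <- A[1, ] + tfr * bvec
    max(Mod(eigen(A, only.values = TRUE)$values))
  }
  tfr_star <- uniroot(function(tfr) lam1(tfr) - 1, c(1.5, 6))$root
  years <- 2001:2150
  q <- array(rep(qv, times = length(years) * 2),
             c(omega + 1, length(years), 2),
             dimnames = list(ages, years, c("m", "f")))
  fert <- list(schedule = data.frame(age = 15:49, coefficient = sched),
               tfr = data.frame(year = years, tfr = tfr_star),
               srb = data.frame(year = years, srb = srb))
  pp <- project_population(flat_pyramid(1000), fert, q, years)
  tot <- apply(pp$P, 2, sum)
  n <- length(years)
  expect_lt(abs(tot[n] / tot[n - 50] - 1), 0.005)
})

test_that("insured counts are the stated product of participation factors", {
  pol <- default_policy()
  pop <- flat_pyramid(0)
  pop$count[pop$age == 30 & pop$sex == "m"] <- 1000
  led <- insured_counts(pop, u = 0.05, ub = 0.6, coverage = 0.9, policy = pol)
  got <- led$count[led$age == 30 & led$class == "male_worker"]
  expect_equal(got, 1000 * 0.95 * 0.6 * 0.9 * 0.9370, tolerance = 1e-12)
  # retirees carry the retiree share instead
  pop$count[pop$age == 70 & pop$sex == "m"] <- 500
  led <- insured_counts(pop, u = 0.05, ub = 0.6, coverage = 0.9, policy = pol)
  expect_equal(led$count[led$age == 70 & led$class == "male_worker"],
               500 * 0.95 * 0.6 * 0.9 * 0.9440, tolerance = 1e-12)
})

test_that("full unemployment removes every in-service insured", {
  led <- insured_counts(flat_pyramid(), u = 1, ub = 0.6, coverage = 0.9)
  expect_true(all(led$count[led$status == "in_service"] == 0))
  expect_error(insured_counts(flat_pyramid(), u = 1.2, ub = 0.5, coverage = 0.9),
               "outside")
})

test_that("female insureds split four to one between workers and cadres", {
  led <- insured_counts(flat_pyramid(), u = 0, ub = 1, coverage = 1)
  fw <- led$count[led$age == 30 & led$class == "female_worker"]
  fc <- led$count[led$age == 30 & led$class == "female_cadre"]
  expect_equal(fw / fc, 4)
})

test_that("the coverage schedule rises a point a year between its anchors", {
  expect_equal(coverage_rate(2020), 0.90)
  expect_equal(coverage_rate(c(2010, 2015, 2025, 2060)),
               c(0.85, 0.85, 0.95, 0.95))
})

test_that("cohort classification against the reform year", {
  expect_equal(classify_cohort(1970, 1996), "old")
  expect_equal(classify_cohort(1990, 2010), "middle")
  expect_equal(classify_cohort(2000, 2035), "new")
  expect_equal(classify_cohort(1990, 1997), "middle")  # boundary: retires in z
  expect_error(classify_cohort(2000, 1999), "join_year")
})

test_that("printed retiree age ranges: worked examples and boundaries", {
  r1 <- cohort_age_ranges(2000, r = 60)
  expect_equal(r1$middle, 60:62)
  expect_equal(r1$old, 63:100)
  expect_length(r1$new, 0)
  # first post-reform retirees: a single middle age
  r2 <- cohort_age_ranges(1998, r = 60)
  expect_equal(r2$middle, 60L)
  # from z - e + omega + 1 = 2078 on, everyone retired is a new person
  r3 <- cohort_age_ranges(2078, r = 60)
  expect_length(r3$old, 0)
  expect_length(r3$middle, 0)
  expect_equal(r3$new, 60:100)
  expect_error(cohort_age_ranges(1990, r = 60), ">= z")
})

test_that("the three ranges always partition the retiree ages", {
  for (r in c(60L, 50L, 55L)) {
    for (t in c(1997:2005, 2020L, 2036L, 2037L, 2046L, 2077L, 2078L, 2120L)) {
      rng <- cohort_age_ranges(t, r = r)
      all_ages <- sort(c(rng$old, rng$middle, rng$new))
      expect_equal(all_ages, r:100, label = paste("t", t, "r", r))
      expect_equal(anyDuplicated(all_ages), 0L)
    }
  }
})

test_that("aging indicators count the 60-plus insureds", {
  led <- data.frame(age = c(30, 40, 62, 70, 30, 65),
                    sex = c("m", "m", "m", "m", "f", "f"),
                    count = c(400, 300, 200, 100, 700, 300))
  ai <- aging_indicators(led)
  m <- ai[ai$sex == "m", ]
  expect_equal(m$elderly_count, 300)
  expect_equal(m$elderly_share, 0.3)
  f <- ai[ai$sex == "f", ]
  expect_equal(f$elderly_share, 0.3)
  expect_error(aging_indicators(led[0, ]), "empty")
  led0 <- led; led0$count[led0$age >= 60] <- 0
  expect_equal(aging_indicators(led0)$elderly_share, c(0, 0))
  led1 <- led[led$age >= 60, ]
  expect_equal(aging_indicators(led1)$elderly_share, c(1, 1))
})
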