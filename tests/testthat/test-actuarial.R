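test_that("salary profile: flat, two-age, and default seniority cases", {
  p0 <- build_salary_profile(105, c(3, 7), c(25, 40), s = 0)
  expect_equal(p0$salary, c(105, 105))
  # two ages, equal counts, 10% seniority: mean(S, 1.1 S) = 105
  p1 <- build_salary_profile(105, c(1, 1), c(20, 21), s = 0.10)
  expect_equal(p1$salary, c(100, 110), tolerance = 1e-12)
  # default seniority rate on a 40-age uniform ledger: weighted mean holds
  ages <- 20:59
  p2 <- build_salary_profile(63182, rep(1, 40), ages, s = 0.01363)
  expect_equal(sum(p2$salary) / 40, 63182, tolerance = 1e-10)
  expect_error(build_salary_profile(100, numeric(0), integer(0), 0.01), "insureds")
})

test_that("contribution revenue is rate x contributory payroll at lagged salary", {
  ser <- toy_series(d = 0.6089)
  pol <- toy_policy()
  cls <- list(mw = list(r = 60, in_service = c(`30` = 1)))
  rev <- contribution_revenue(2007, cls, ser, pol)
  expect_equal(rev$pooling, 9.7424, tolerance = 1e-12)
  expect_equal(rev$individual, 4.8712, tolerance = 1e-12)
  ser0 <- toy_series(d = 0.6089, b_rate = 0)
  expect_equal(contribution_revenue(2007, cls, ser0, pol)$pooling, 0)
  expect_equal(contribution_revenue(2007, list(mw = list(r = 60, in_service = numeric(0))),
                                    ser, pol)$pooling, 0)
})

test_that("legacy pensions: replacement rate, telescoping indexation, empty range", {
  ser <- toy_series()
  pol <- toy_policy()
  expect_equal(old_people_expenditure(2007, c(`71` = 1), 60, ser, pol),
               71.63, tolerance = 1e-12)
  # constant pension growth telescopes to (1 + rho)^(t - ret)
  ser_r <- toy_series(rho = 0.10)
  expect_equal(pension_index(ser_r, 2000, 1998), 1.21, tolerance = 1e-12)
  expect_equal(pension_index(ser_r, 2000, 2000), 1, tolerance = 1e-12)
  # no old people remain once t exceeds z + omega - r
  expect_equal(old_people_expenditure(2038, c(`100` = 5), 60, ser, pol), 0)
})

test_that("basic pension: full-career collapse and contribution-year cap", {
  pol <- toy_policy()
  ser <- toy_series()              # wage = average, d = 1, no growth
  # full-career new person: B = (S/2)(1 + 1) * 40% = 0.40 * S
  expect_equal(basic_pension_base(2037, 60, ser, pol), 40, tolerance = 1e-12)
  # individual wage twice the average: B = 1.5 * S * n%
  ser2 <- toy_series(Fnorm = 2)
  for (n in c(5, 12)) {
    expect_equal(basic_pension_base(1997 + n, 60, ser2, pol),
                 1.5 * 100 * n / 100, tolerance = 1e-12)
  }
  # middle person retiring 2007 at 60: min(10, 40) = 10 contribution years
  expect_equal(basic_pension_base(2007, 60, ser, pol),
               100 / 2 * 2 * 0.10, tolerance = 1e-12)
})

test_that("transition pension pays epsilon per pre-reform year, zero for new people", {
  pol <- toy_policy()
  ser <- toy_series()
  # ret 2007: 10 post-reform years, 30 pre-reform years, index ratio 1
  expect_equal(transition_pension_base(2007, 60, ser, pol), 100 * 30 * 0.012,
               tolerance = 1e-12)
  expect_equal(transition_pension_base(2037, 60, ser, pol), 0)
  expect_equal(transition_pension_base(2050, 60, ser, pol), 0)
  expect_error(default_policy(epsilon = 0.02), "epsilon")
})

test_that("account annuity and payer split", {
  expect_equal(individual_account_pension(139000, 139), 12000)
  expect_equal(individual_account_pension(0, 195), 0)
  expect_error(individual_account_pension(100, 0), "m_r")
  pol <- default_policy()
  expect_equal(pol$classes$m_r[pol$classes$class == "female_worker"], 195L)
  expect_equal(account_payer(65, 60, 139), "individual")   # 5 < 139/12
  expect_equal(account_payer(72, 60, 139), "pooling")      # 12 > 139/12
  expect_equal(account_payer(71, 60, 139), "individual")   # 11 < 11.58, strict
})

test_that("account conservation: payments plus death refund exhaust the balance", {
  bal <- 53724.88
  for (m_r in c(139, 195, 170)) {
    I <- individual_account_pension(bal, m_r)
    for (K in 0:(floor(m_r / 12) - 1)) {
      refund <- (m_r / 12 - K - 1) * I
      expect_equal((K + 1) * I + refund, bal, tolerance = 1e-9,
                   label = paste("m_r", m_r, "death year", K))
    }
  }
})

test_that("death refunds: printed examples", {
  ser <- toy_series()
  pol <- toy_policy()
  # retiree dies one year into retirement with a 12,000 annuity
  cls <- list(mw = list(r = 60, m_r = 139, deaths_in = numeric(0),
                        deaths_ret = c(`61` = 1),
                        I_by_ret = c(`2006` = 12000)))
  ref <- death_refunds(2007, cls, numeric(0), ser, pol)
  expect_equal(ref$retiree, (139 / 12 - 1 - 1) * 12000, tolerance = 1e-9)
  expect_equal(ref$retiree, 115000, tolerance = 1e-6)
  # in-service decedent refunds last year's balance plus this year's
  # contribution, with no interest in the death year
  cls2 <- list(mw = list(r = 60, m_r = 139, deaths_in = c(`30` = 1),
                         deaths_ret = numeric(0)))
  ref2 <- death_refunds(2007, cls2, c(`29` = 5000 - 0.08 * 100), ser, pol)
  expect_equal(ref2$in_service, 5000, tolerance = 1e-12)
  # zero deaths, zero refunds
  ref3 <- death_refunds(2007, list(mw = list(r = 60, m_r = 139,
                                             deaths_in = numeric(0),
                                             deaths_ret = numeric(0))),
                        numeric(0), ser, pol)
  expect_equal(ref3$total, 0)
})

test_that("one year of a toy economy matches a hand-computed ledger", {
  pol <- toy_policy()
  ser <- toy_series()              # wage 100, rho 0, j 0.1, c 0.08, b 0.16, d 1
  B29 <- 8 * sum(1.1^(1:10))       # worker aged 30 in 2007, insured since 1997
  ins <- list(
    classes = list(male_worker = list(
      r = 60, m_r = 139,
      in_service = c(`30` = 1),
      retired = c(`65` = 1),
      deaths_in = c(`30` = 0.1),
      deaths_ret = c(`65` = 0.2))),
    accounts_prev = c(`29` = B29)
  )
  ff <- yearly_fund_flow(2007, ins, ser, pol)

  # hand ledger (independent arithmetic, flat wages, zero indexation):
  pool_c <- 0.16 * 100             # employer premium on lagged salary
  ind_c <- 0.08 * 100
  B <- 100 / 2 * (1 + 1) * 5 / 100 # 5 contribution years since 1997
  TT <- 100 * 1 * (40 - 5) * 0.012 # 35 pre-reform years at 1.2%
  bal <- 8 * sum(1.1^(1:5))        # contributions 1997..2001 compounded to 2001
  I <- 12 * bal / 139
  ref_in <- 0.1 * (B29 + 8)
  ref_ret <- 0.2 * (139 / 12 - 5 - 1) * I

  expect_equal(ff$pooling_contrib, pool_c, tolerance = 1e-9)
  expect_equal(ff$individual_contrib, ind_c, tolerance = 1e-9)
  expect_equal(ff$middle_basic, B, tolerance = 1e-9)
  expect_equal(ff$middle_transition, TT, tolerance = 1e-9)
  expect_equal(ff$account_individual, I, tolerance = 1e-9)
  expect_equal(ff$middle_account_pool, 0)
  expect_equal(ff$old_basic, 0)
  expect_equal(ff$refund_in_service, ref_in, tolerance = 1e-9)
  expect_equal(ff$refund_retiree, ref_ret, tolerance = 1e-9)
  expect_equal(ff$pooling_exp, B + TT, tolerance = 1e-9)
  expect_equal(ff$individual_exp, I + ref_in + ref_ret, tolerance = 1e-9)
  expect_equal(ff$balance, pool_c + ind_c - (B + TT + I + ref_in + ref_ret),
               tolerance = 1e-9)

  # linearity: doubling every count doubles every component
  ins2 <- ins
  ins2$classes$male_worker$in_service <- 2 * ins$classes$male_worker$in_service
  ins2$classes$male_worker$retired <- 2 * ins$classes$male_worker$retired
  ins2$classes$male_worker$deaths_in <- 2 * ins$classes$male_worker$deaths_in
  ins2$classes$male_worker$deaths_ret <- 2 * ins$classes$male_worker$deaths_ret
  ff2 <- yearly_fund_flow(2007, ins2, ser, pol)
  for (nm in c("pooling_contrib", "individual_contrib", "middle_basic",
               "middle_transition", "account_individual", "refund_in_service",
               "refund_retiree", "expenditures", "contributions"))
    expect_equal(ff2[[nm]], 2 * ff[[nm]], tolerance = 1e-12, label = nm)

  # no retirees, no deaths: expenditures vanish
  ins3 <- list(classes = list(male_worker = list(
    r = 60, m_r = 139, in_service = c(`30` = 1), retired = numeric(0),
    deaths_in = numeric(0), deaths_ret = numeric(0))),
    accounts_prev = c(`29` = B29))
  ff3 <- yearly_fund_flow(2007, ins3, ser, pol)
  expect_equal(ff3$expenditures, 0)
  expect_equal(ff3$balance, ff3$contributions)
})

test_that("account-pension payer switches to pooling after the stipulated months", {
  pol <- toy_policy()
  ser <- toy_series()
  ins <- list(
    classes = list(male_worker = list(
      r = 60, m_r = 139,
      in_service = numeric(0),
      retired = c(`72` = 1),     # 12 years past retirement > 139/12
      deaths_in = numeric(0), deaths_ret = numeric(0))),
    accounts_prev = numeric(0))
  ff <- yearly_fund_flow(2015, ins, ser, pol)
  expect_equal(ff$account_individual, 0)
  expect_gt(ff$middle_account_pool, 0)
})

test_that("flows rise with the contribution rate and with indexation and crediting rates", {
  pol <- toy_policy()
  ins <- list(
    classes = list(male_worker = list(
      r = 60, m_r = 139,
      in_service = c(`30` = 1, `45` = 1),
      retired = c(`63` = 1, `70` = 1),
      deaths_in = numeric(0), deaths_ret = numeric(0))),
    accounts_prev = c(`29` = 100, `44` = 300))
  base <- yearly_fund_flow(2010, ins, toy_series(), pol)
  hi_b <- yearly_fund_flow(2010, ins, toy_series(b_rate = 0.20), pol)
  expect_gt(hi_b$pooling_contrib, base$pooling_contrib)
  expect_equal(hi_b$pooling_contrib / base$pooling_contrib, 0.20 / 0.16,
               tolerance = 1e-12)
  hi_rho <- yearly_fund_flow(2010, ins, toy_series(rho = 0.05), pol)
  expect_gt(hi_rho$expenditures, base$expenditures)
  hi_j <- yearly_fund_flow(2010, ins, toy_series(j = 0.2), pol)
  expect_gt(hi_j$expenditures, base$expenditures)
})
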