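test_that("the vectorized engine agrees with the per-year flow operation", {
  base <- fx_baseline_short()
  prep <- base$prep
  fx <- penfund:::fixed_paths(prep)
  res <- penfund:::run_path(prep, fx$par, fx$kpaths)
  it <- res$internals
  pol <- prep$policy
  for (t in c(2023L, 2031L, 2040L)) {
    ti <- match(t, prep$proj_years)
    classes <- lapply(seq_len(nrow(pol$classes)), function(ic) {
      list(r = pol$classes$r[ic], m_r = pol$classes$m_r[ic],
           in_service = it$W[[ic]][, ti], retired = it$Rt[[ic]][, ti],
           deaths_in = it$Din[[ic]][, ti], deaths_ret = it$Dret[[ic]][, ti])
    })
    names(classes) <- pol$classes$class
    ins <- list(classes = classes,
                accounts_prev = it$B2[, as.character(t - 1L)])
    ff <- yearly_fund_flow(t, ins, res$series, pol)   # reference route
    row <- res$flows[res$flows$year == t, ]
    for (nm in c("pooling_contrib", "individual_contrib", "old_basic",
                 "middle_basic", "middle_transition", "middle_account_pool",
                 "new_basic", "new_account_pool", "account_individual",
                 "refund_in_service", "refund_retiree", "contributions",
                 "expenditures", "balance"))
      expect_equal(row[[nm]], ff[[nm]], tolerance = 1e-9,
                   label = paste(t, nm))
  }
})

test_that("engine account balances match the closed-form accumulation", {
  base <- fx_baseline_short()
  res <- penfund:::run_path(base$prep, base$par, base$kpaths)
  pol <- base$prep$policy
  for (ic in 1:3) {
    r <- pol$classes$r[ic]
    for (ret in c(2005L, 2025L, 2039L)) {
      closed <- individual_account_pension(
        account_balance_at_retirement(ret, r, res$series, pol),
        pol$classes$m_r[ic])
      expect_equal(unname(res$internals$bases[[ic]]$I0[as.character(ret)]),
                   closed, tolerance = 1e-9)
    }
  }
})

test_that("the fixed scenario uses the lognormal mean for the bookkeeping rate", {
  base <- fx_baseline_short()
  expect_equal(unique(base$par$j), lognormal_mean(-3.173, 0.364),
               tolerance = 1e-12)
  expect_lt(abs(lognormal_mean(-3.173, 0.364) - 0.04469), 2e-4)
  base_med <- run_fixed_scenario(fx_bundle(), short_policy(fixed_j = "median"))
  expect_equal(unique(base_med$par$j), exp(-3.173), tolerance = 1e-12)
})

test_that("the baseline expenditure ratio eventually rises with insured aging", {
  base <- fx_baseline_short()
  tab <- base$table
  n <- nrow(tab)
  # once the elderly share of insureds has built up, the ratio of
  # expenditures to contributions climbs
  expect_gt(tab$ind1[n], tab$ind1[1])
  expect_true(all(diff(tab$ind1[(n - 10):n]) > -1e-6))
  ag <- base$aging
  expect_true(all(ag$elderly_share >= 0 & ag$elderly_share <= 1))
})

test_that("a degenerate-noise ensemble collapses onto the fixed scenario", {
  b0 <- fx_bundle_zero()
  pol <- short_policy()
  sp0 <- zero_spec()
  sp0$bookkeeping$log_sd <- 0
  base <- run_fixed_scenario(b0, pol, sp0)
  sim <- run_monte_carlo(b0, pol, sp0, n_paths = 3, seed = 4)
  for (nm in paste0("ind", 1:6)) {
    for (p in 1:3)
      expect_equal(sim$paths[[nm]][, p], stats::setNames(base$table[[nm]], sim$years),
                   tolerance = 1e-12, label = paste(nm, p))
    expect_equal(sim$summary[[nm]]$lower, sim$summary[[nm]]$upper,
                 tolerance = 1e-12)
  }
})

test_that("ensembles are reproducible from the master seed", {
  pol <- short_policy()
  s1 <- run_monte_carlo(fx_bundle(), pol, n_paths = 5, seed = 31)
  s2 <- run_monte_carlo(fx_bundle(), pol, n_paths = 5, seed = 31)
  expect_identical(s1$summary, s2$summary)
  expect_identical(s1$final_balance, s2$final_balance)
  s3 <- run_monte_carlo(fx_bundle(), pol, n_paths = 5, seed = 32)
  expect_false(identical(s1$final_balance, s3$final_balance))
  expect_error(run_monte_carlo(fx_bundle(), pol, n_paths = 1), "n_paths")
})

test_that("ensemble bands are the order statistics of the stored paths", {
  pol <- short_policy()
  sim <- run_monte_carlo(fx_bundle(), pol, n_paths = 40, seed = 8)
  n <- sim$n_paths
  for (yi in c(1, 10, length(sim$years))) {
    srt <- sort(sim$paths$ind4[yi, ])
    expect_identical(unname(sim$summary$ind4$lower[yi]), srt[ceiling(0.025 * n)])
    expect_identical(unname(sim$summary$ind4$upper[yi]), srt[ceiling(0.975 * n)])
    expect_identical(unname(sim$summary$ind4$median[yi]), stats::median(srt))
  }
})

test_that("final-reserve deciles have floor(n/10) members and honest cuts", {
  pol <- short_policy()
  sim <- run_monte_carlo(fx_bundle(), pol, n_paths = 25, seed = 19)
  fr <- final_reserve_distribution(sim)
  expect_equal(fr$k, 2L)
  expect_equal(sum(fr$bottom), 2L)
  expect_equal(sum(fr$top), 2L)
  expect_false(any(fr$bottom & fr$top))
  srt <- sort(sim$final_balance)
  expect_equal(fr$sorted, srt)
  expect_true(all(sim$final_balance[fr$bottom] <= fr$cut_lower))
  expect_true(all(sim$final_balance[fr$top] >= fr$cut_upper))
  # identical paths: both cut values coincide
  fr2 <- final_reserve_distribution(list(final_balance = rep(3.3, 20)))
  expect_equal(fr2$cut_lower, 3.3)
  expect_equal(fr2$cut_upper, 3.3)
})

test_that("with small noise the ensemble mean of the first-year balance tracks the baseline", {
  pol <- short_policy()
  sp <- default_randomization_spec()
  for (nm in c("unemployment", "urbanization", "wage_growth", "roi"))
    sp[[nm]]$sd <- sp[[nm]]$sd * 0.1
  sp$bookkeeping$log_sd <- 0.05
  sp$enterprise_rate$sd <- 0.002
  sp$individual_rate$sd <- 0.0015
  b0 <- fx_bundle_zero()
  base <- run_fixed_scenario(b0, pol, sp)
  sim <- run_monte_carlo(b0, pol, sp, n_paths = 200, seed = 5,
                         fluctuate = setdiff(penfund:::PARAM_NAMES, "mortality"))
  x <- sim$paths$ind2[1, ]
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - base$table$ind2[1]), 3 * se + 1e-9)
})

test_that("simulated parameter bands have predictive coverage near 95 percent", {
  sp <- default_randomization_spec()
  init <- list(u = 4.2, du = 0.1, ub = 62, dub = 1.0, g = 0.08, dg = -0.001,
               i = 0.0689)
  years <- 2022:2041
  mid <- 10
  cover <- numeric(20)
  for (s in 1:20) {
    ps <- simulate_paths(sp, init, years, n_paths = 150, seed = s)
    f <- colMeans(ps$b)                    # linear functional of the path
    band <- quantile(f, c(0.025, 0.975), type = 1)
    fresh <- simulate_paths(sp, init, years, n_paths = 150, seed = 1000 + s)
    ffresh <- colMeans(fresh$b)
    cover[s] <- mean(ffresh >= band[1] & ffresh <= band[2])
  }
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})
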