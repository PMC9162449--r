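---
title: "Stochastic projection of basic pension fund reserves: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic projection of basic pension fund reserves: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`penfund` evaluates the long-term financial sustainability of a
pay-as-you-go basic pension scheme for enterprise employees — the kind
of scheme China operates, with a social pooling account funded by
employer contributions and notional individual accounts funded by
employee contributions.  This vignette is the package's own account of
the model: what is computed, under which assumptions, with which
parameter values, and what the test suite does and does not establish.

## The scheme and its three retiree generations

Insureds enter employment at age $e = 20$ and retire at $r = 60$ (male
workers), $50$ (female workers) or $55$ (female cadres); female insureds
split 4:1 between the worker and cadre classes.  The 1997 reform
($z = 1997$) created today's two-pillar design, which splits retirees
into three generations:

* **old people** retired before $z$ and draw a legacy pension: the
  salary they earned at age $r-1$ in the year before retirement times a
  replacement rate $\hat R = 71.63\%$, indexed to the payment year;
* **middle people** joined before $z$ and retired after it.  They draw
  a basic pension, a transition pension compensating their pre-reform
  years at a coefficient $\varepsilon = 1.2\%$ per year, and an
  individual-account annuity;
* **new people** joined in or after $z$ and draw the basic pension and
  the account annuity only.

The basic pension at retirement is
$$B = \frac{\bar S_{ret-1}}{2}\Big(1 + \overline{m}\Big)\cdot n\% ,$$
where $\bar S$ is the economy-wide average wage, $\overline{m}$ the mean
ratio of the retiree's indexed contribution wage to the average wage
over the $n = \min(ret - z,\ r - e)$ contribution years.  The
individual account is credited every year with $c_t d_t S_{t-1,x-1}$
(individual rate times contributory salary), compounded at the
bookkeeping interest rate $j$, and converted at retirement into a fixed
nominal annuity of $12/m_r$ of the balance per year, with stipulated
payment months $m_r$ = 139/195/170 for retirement ages 60/50/55.  The
individual account pays this annuity while the years in retirement are
(strictly) below $m_r/12$; afterwards the pooling account takes over.
When an insured dies in service, the accumulated balance is refunded;
when a retiree dies within the stipulated months, the remaining
$m_r/12 - (x - r) - 1$ annuity years are refunded.  These rules make
each account exactly self-liquidating up to the stipulated months: the
annuity payments received plus the death refund always sum to the
retirement balance, an identity the test suite checks exactly.

Salaries carry a seniority gradient $S_{t,x} = (1+s)^{x-e} S_{t,e}$ with
$s = 1.363\%$; the entry-age salary is pinned down each year by
requiring the insured-weighted mean salary to equal the average wage.
Only the fraction $d = 60.89\%$ of the statistical salary is
contributory.  Basic, transition and legacy pensions are indexed by the
pension growth rate $\rho_t$ through the product
$\prod_{h=ret}^{t}(1+\rho_h)/(1+\rho_t)$ — implemented exactly as the
scheme formulas state it, although dividing by the retirement-year
factor would be the more conventional reading; a switch
(`index_denominator = "retirement-year"`) provides the alternative.
With constant $\rho$ both variants telescope to $(1+\rho)^{t-ret}$.

## Demography

Mortality follows the Lee–Carter model
$\ln m_{x,t} = \alpha_x + \beta_x k_t + \varepsilon_{x,t}$, fitted by
the singular-value decomposition of the centred log-rate surface (the
least-squares solution; an inverse-residual-variance re-weighting pass
is available) under the usual normalization $\sum_x\beta_x = 1$,
$\sum_t k_t = 0$.  The time index is forecast as a random walk with
drift in which the drift itself is resampled per path from its sampling
distribution — a doubly stochastic forecast, our concrete reading of
index forecasts whose drift is estimated with error.  Rates above the
pivot age (84 by default) are closed out with the Coale–Kisker device:
age-to-age log increments decline linearly until the central rate at
the ultimate age $\omega = 100$ equals 0.8; both closure constants are
configurable since the underlying sources do not print them.  Central
rates convert to death probabilities by the constant-hazard formula
$q = 1 - e^{-m}$, and $\omega$ is absorbing ($q_\omega = 1$).

The population advances by the cohort-component method,
$P_{t,x} = P_{t-1,x-1}(1 - q_{t,x})$, with births
$\sum_{x=15}^{49} P^F_{t,x}\,TFR_t\,\bar h_x$ allocated to the sexes by
the sex ratio at birth, and no migration.  In-service insureds at age
$x$ are $P_{t,x}$ times labor participation ($1-u_t$), urbanization
$ub_t$, scheme coverage, and the enterprise share of urban insured
employees (93.70%); retired insureds use the enterprise retiree share
(94.40%).  The same participation and coverage factors are applied to
both statuses — the sources imply but do not spell this symmetry out.
Coverage rises one percentage point per year from 85% in 2015 to 95% in
2025 and stays flat.

## The nine stochastic parameters

| parameter | process | values (units) | clip |
|---|---|---|---|
| mortality | Lee–Carter index, doubly stochastic walk | fitted drift and innovation sd | $q\in[0,1]$ |
| unemployment $u$ | AR(1) on yearly differences | coef 0.5851, sd 0.2616 (pp) | $u \ge 0$ |
| urbanization $ub$ | AR(1) on differences | intercept 1.0476, coef 0.7042, sd 0.2815 (pp) | $ub \le 80\%$ |
| wage growth $g$ | AR(1) on differences | intercept −0.0010, coef −0.3095, sd 0.0258 | $g\in[0, 9.2\%]$ |
| pension growth $\rho$ | $0.8\,g_t$ | multiplier in $[0.6, 0.8]$ | — |
| ROI $i$ | mean-reverting lag-one recursion | 0.0015002 + 0.95275 $i_{t-1}$, sd 0.0020282 | — |
| bookkeeping $j$ | lognormal, fresh draw per year | $\ln j \sim N(-3.173, 0.364^2)$ | — |
| enterprise rate $b$ | normal, fresh draw per year | $N(0.16, 0.0204^2)$ | — |
| individual rate $c$ | normal, fresh draw per year | $N(0.08, 0.0153^2)$ | — |

The innovation scales of the unemployment and urbanization equations
are read in percentage points and the wage-growth scale in fraction
units: those magnitudes are the only ones consistent with the series
they drive.  Clipping is truncation at the bound, applied to the level
after each step, while the latent difference state keeps evolving;
resampling would distort the stated marginal recursions.  The
contribution rates are independent across years — their sources specify
marginal distributions only — so a path is a sequence of fresh draws,
not a random walk.  The ROI recursion was estimated on trading-day
data; the package applies it per forecast year, as the recursion is
printed, rather than compounding it to an annual persistence.  Its
implied stationary mean is $0.0015002/(1-0.95275) \approx 3.17\%$,
which the simulated paths approach from the 6.89% initial value over
roughly 15 years.

In the fixed-parameter baseline every innovation is set to its mean
(zero) and every distributional draw to its mean — for the lognormal
bookkeeping rate that is $e^{\mu+\sigma^2/2} \approx 4.47\%$, with a
`fixed_j = "median"` switch for $e^{\mu}$.

## Fund accounting and the six indicators

Contributions and expenditures are assembled year by year (both occur
at the beginning of the year) into pooling and individual-account
flows.  The six reserve indicators are: (1) expenditures over
contributions; (2) the current balance of contributions and
expenditures; (3) the current payment gap over contributions; (4) the
accumulated balance, which earns the ROI only while positive —
deficits are carried forward without interest; (5) the fund ratio,
prior-year-end reserves (credited with the year's return, consistent
with the accumulation rule) over current expenditures, reported as 0
once reserves are exhausted; (6) the accumulated gap over
contributions, defined only while the balance is negative.  Trend
statistics follow end-over-start definitions: a geometric average
annual growth rate for indicator 1, arithmetic average annual changes
for indicators 2 and 4 (denominator = number of yearly steps), and
change rates from the first gap year for indicators 3 and 6.

The reported horizon is 2022–2094.  The initial fund stock
(4,440.17 billion yuan) is valued at end-2020 and the initial pyramid
at 2019, so the engine projects from 2020 and rolls the stock through
2021 before the reported table begins; the 2020–2021 steps always use
the zero-innovation parameter values, and stochastic innovations start
in 2022.

## The synthetic pseudo-yearbook bundle

All inputs are synthesized with known ground truth so that every
fitting stage is testable by parameter recovery: a 26-year age–sex
mortality surface generated from a known Lee–Carter truth (a composite
infant/hump/Gompertz level curve, loadings decaying with age, index
drift −1.0 per year, innovation sd 0.6, log-rate residual sd 0.02); 42-
and 40-year unemployment and urbanization histories and a 23-year wage
level history generated from the difference autoregressions above; a
1,650-observation mean-reverting short-rate history; a 26-year
lognormal deposit-rate history; a Gaussian-shaped fertility schedule on
ages 15–49 (peak at 26) scaled by a flat total fertility of 1.70 and a
sex ratio at birth of 1.10 — stand-ins for medium-variant projection
paths that are configurable and claim no correspondence to any official
series; and a smooth piecewise-linear initial pyramid with exponential
old-age decay totalling 1.4 billion people.

Two generator choices deserve emphasis.  First, the pyramid is
deliberately *younger* at old ages than a census pyramid: it represents
the population relevant to the scheme, whose historical coverage of
today's elderly cohorts is incomplete, while the model applies a single
coverage path to workers and retirees alike.  With a full census age
structure the projection starts deep in deficit and the accumulation
phase of the reserves never appears.  Second, the urbanization
*history* is generated with intercept 0.3106 — matching the roughly one
point per year rise actually observed over four decades — rather than
the forecast equation's 1.0476, which implies a steady-state rise of
3.5 points per year and would push a 40-year synthetic history far past
100%; the forecast recursion itself keeps the printed coefficients,
with the 80% cap binding early.

The wage-growth history is generated without the forecast clip: the
0–9.2% band is a forward-looking policy bound, and historical growth
exceeded it.  A zero-noise bundle reproduces every configured truth
exactly (to $10^{-6}$) through the public fitting functions, which is
the package's strongest end-to-end correctness check.  What the bundle
does **not** emulate: cohort effects or age-specific mortality shocks,
business-cycle comovement between unemployment, wages and returns
(parameters are independent, as in the projection model itself),
migration, and policy changes such as delayed retirement.  Passing
tests therefore validate the machinery, not any specific national
forecast.

## Numerical and engineering choices

* The engine computes all years of flows with vectorized age-by-year
  matrices; a per-year reference implementation
  (`yearly_fund_flow()`) built from the individual benefit formulas is
  retained, and the suite asserts the two routes agree to $10^{-9}$,
  alongside a fully hand-computed toy-economy ledger.
* Wage levels before the synthetic history are back-extrapolated at the
  mean historical growth rate, and the salary-profile normalization
  factor before 2020 is held at its 2020 value; both only matter for
  pre-reform retirees' legacy pensions and early middle cohorts, and
  sensitivity to them fades out of the horizon by the 2040s.  The
  historical individual contribution rate and bookkeeping rate are the
  spec means (8%) and the deposit-rate history respectively.
* Account balances follow the recursion "credit interest on the
  running balance plus the current contribution", which reproduces the
  closed-form compounding of each contribution from its own year to the
  year before retirement; decedents earn no interest in the death year.
* One master seed drives everything: it spawns one integer substream
  seed per simulation path, so results are independent of evaluation
  order and reproducible bit-for-bit.
* Ensemble bands are pointwise empirical 2.5%/97.5% order statistics
  (inverse-ECDF quantiles), so they can be checked exactly against an
  independent sort.
* The boundary retiree cohort of the reform year itself is classified
  "old" by the printed age-interval formulas and "middle" by the verbal
  definitions; the engine follows the intervals, and at the
  complementary boundary (entry exactly in the reform year) the middle
  and new formulas give identical amounts, so the choice never changes
  totals.

## Sensitivity, influence, and backtracking

The elasticity scan multiplies one parameter's entire baseline path by
$1+\tau\%$ for $\tau \in \{-25,\dots,-1, 1,\dots,25\}$ (mortality
scales the central rates before conversion; caps stay in force) and
classifies the direction from the end-of-horizon accumulated balance:
non-decreasing in $\tau$ is "same", non-increasing "reverse", anything
else "mixed" (detected by sign changes of successive differences).
The influence index $A$ of a parameter is the mean yearly width of the
95% band of the accumulated balance when only that parameter
fluctuates.  Backtracking sorts the final balances, takes the top and
bottom deciles ($\lfloor n/10\rfloor$ paths each) as the "better" and
"worse" groups, and compares group-mean parameter paths year by year; a
parameter is flagged divergent when the means differ by more than twice
the pooled standard error over at least ten consecutive years — an
explicit stand-in for a judgment the original analysis made visually.

One behaviour is worth flagging because it looks like a bug and is not:
the direction of the *individual* contribution rate is
horizon-dependent.  Each extra yuan contributed is credited at the
bookkeeping rate and later paid out as a lifetime annuity — the
individual account pays the first $m_r/12$ years, the pooling account
pays for life thereafter — while reserves in deficit earn nothing.
Over the first two forecast decades higher $c$ raises the balance
(revenue leads), and the direction tests assert exactly that on a
20-year configuration; by 2094, on the default bundle, the induced
liability dominates and the response turns negative.  The enterprise
rate $b$ has no such liability attached and is unambiguously
"same"-direction; pension growth and the bookkeeping rate are
unambiguously "reverse".

## Problem sizes

The default study configuration is 5,000 Monte Carlo paths over
2022–2094 with 101 ages and two sexes; that full-scale run completes in
about two minutes on one core and is exercised by the test suite.  The
test suite otherwise works on a 20-year reporting horizon with
ensembles of 40–300 paths, 200-seed recovery experiments for the
fitted processes, and exact toy economies.  The acceptance script uses
the full horizon with a 2,000-path main ensemble and 400-path
single-parameter ensembles for the influence ranking — large enough
that the reported band statistics move by well under their own
Monte-Carlo error between seeds.

## Known limitations

Cohort-level accounting with cohort-average wages (no within-cohort
wage heterogeneity); no migration; no delayed-retirement or
state-capital-transfer scenarios; no fiscal subsidies; parameters are
mutually independent, so the bands understate any comovement risk; the
individual-account annuity is fixed in nominal terms after retirement,
as the scheme formulas state, which understates benefit indexation if
account pensions are in practice adjusted; and the legacy-pension
computation depends on back-extrapolated pre-history wages whose
influence, while transient, is not zero in the first forecast decade.
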