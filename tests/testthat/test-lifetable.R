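test_that("overdiagnosis proportion follows the linear-age model with clamping", {
  eff <- screening_effects()
  expect_equal(overdiagnosis_proportion(eff, 55), 0.15, tolerance = 1e-12)
  expect_equal(overdiagnosis_proportion(eff, 69), 0.346, tolerance = 1e-12)
  expect_equal(overdiagnosis_proportion(eff, 44), 0)   # clamped from -0.004
  expect_equal(overdiagnosis_proportion(screening_effects(
    overdiagnosis_intercept = 2), 70), 1)              # ceiling clamp
})

test_that("a rate-free cohort just ages: no cases, full person-time", {
  rates <- flat_table(55:90, cohort = 1000)
  sched <- build_schedule(strategy("none"), rates)
  out <- run_cohort(rates, sched, screening_effects(), 55, 1000)
  expect_equal(out$cases, 0)
  expect_equal(out$pc_deaths, 0)
  expect_equal(out$life_years, 1000 * 35)
  expect_equal(out$alive_end, 1000)
})

test_that("unscreened life table matches an independent spreadsheet recomputation", {
  rates <- rate_table(60:63,
                      pc_incidence = c(0.01, 0.02, 0.03, 0.04),
                      pc_mortality = c(0.004, 0.005, 0.006, 0.007),
                      other_mortality = c(0.02, 0.03, 0.04, 0.05))
  sched <- build_schedule(strategy("none"), rates, end_age = 63L)
  out <- run_cohort(rates, sched, screening_effects(), 60, 1e5)
  ref <- spreadsheet_unscreened(rates, 60, 1e5, end_age = 63)
  expect_equal(out$cases, ref$cases, tolerance = 1e-10)
  expect_equal(out$pc_deaths, ref$pc_deaths, tolerance = 1e-10)
  expect_equal(out$other_deaths, ref$other_deaths, tolerance = 1e-10)
  expect_equal(out$life_years, ref$life_years, tolerance = 1e-10)
})

test_that("a fully screened cohort sees the mortality relative risk exactly in one cycle", {
  rates <- rate_table(88:90,
                      pc_incidence = c(0.05, 0.05, 0.05),
                      pc_mortality = c(0.01, 0.01, 0.01),
                      other_mortality = c(0, 0, 0))
  eff <- screening_effects(rr_mortality = 0.79, rr_incidence = 1,
                           overdiagnosis_intercept = 0,
                           overdiagnosis_slope = 0)
  st <- strategy("age_based", start_age = 88, stop_age = 89, interval = 4)
  s_scr <- build_schedule(st, rates)
  s_none <- build_schedule(strategy("none"), rates)
  scr <- run_cohort(rates, s_scr, eff, 89, 1e4)
  non <- run_cohort(rates, s_none, eff, 89, 1e4)
  expect_equal(scr$pc_deaths, 0.79 * non$pc_deaths, tolerance = 1e-12)
})

test_that("population is conserved at every cycle", {
  rates <- generate_rates()
  for (st in list(strategy("none"), strategy("age_based"),
                  strategy("precision", threshold = 0.04))) {
    sched <- build_schedule(st, rates)
    out <- run_cohort(rates, sched, screening_effects(), 55, 1e6)
    tr <- out$trajectories
    # alive(start of cycle i) + deaths up to cycle i-1 = cohort
    lhs <- tr$alive + c(0, cumsum(tr$pc_deaths + tr$other_deaths))[
      seq_len(nrow(tr))]
    expect_lt(max(abs(lhs - 1e6)), 1e-6 * 1e6)
    expect_true(all(cumsum(tr$overdiagnosed) <= cumsum(tr$cases) + 1e-9))
    expect_true(all(unlist(tr) >= -1e-9))
  }
})

test_that("neutral screening effects leave every scenario epidemiologically equal", {
  rates <- generate_rates()
  eff <- screening_effects(rr_mortality = 1, rr_incidence = 1,
                           overdiagnosis_intercept = 0,
                           overdiagnosis_slope = 0)
  outs <- lapply(list(strategy("none"), strategy("age_based"),
                      strategy("precision", threshold = 0.04)),
                 function(st) run_scenario(rates, st, effects = eff))
  cases <- vapply(outs, `[[`, numeric(1), "cases")
  deaths <- vapply(outs, `[[`, numeric(1), "pc_deaths")
  # with per-cycle renormalisation of the stratum hazards, stratification
  # redistributes but never creates events, so all three agree exactly
  expect_equal(cases[2], cases[1], tolerance = 1e-9)
  expect_equal(deaths[2], deaths[1], tolerance = 1e-9)
  expect_equal(cases[3], cases[1], tolerance = 1e-9)
  expect_equal(deaths[3], deaths[1], tolerance = 1e-9)
})

test_that("mortality inputs move outcomes in the right direction", {
  rates <- generate_rates()
  st <- strategy("age_based")
  pcd <- vapply(c(0.6, 0.79, 1.0), function(rr) {
    run_scenario(rates, st,
                 effects = screening_effects(rr_mortality = rr))$pc_deaths
  }, numeric(1))
  expect_true(all(diff(pcd) > 0))
  # life-years fall when any mortality rate rises
  set.seed(42)
  base_ly <- run_scenario(rates, strategy("none"))$life_years
  for (k in 1:5) {
    bumped <- rates
    i <- sample(nrow(bumped), 1)
    col <- sample(c("pc_mortality", "other_mortality"), 1)
    bumped[[col]][i] <- min(bumped[[col]][i] * 1.5 + 0.001, 0.99)
    expect_lt(run_scenario(bumped, strategy("none"))$life_years, base_ly)
  }
})

test_that("the life table agrees with a per-individual Monte-Carlo oracle", {
  rates <- toy_table5()
  sched <- build_schedule(strategy("none"), rates)
  n <- 1e5
  det <- run_cohort(rates, sched, screening_effects(), 85, n)
  mc <- mc_unscreened(rates, 85, n, seed = 2024)
  se_cases <- sqrt(det$cases * (1 - det$cases / n))
  se_pcd <- sqrt(det$pc_deaths * (1 - det$pc_deaths / n))
  expect_lt(abs(det$cases - mc$cases), 3 * se_cases)
  expect_lt(abs(det$pc_deaths - mc$pc_deaths), 3 * se_pcd)
})
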