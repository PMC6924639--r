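params <- econ_params()

test_that("utilities decline linearly with age and with diagnosis", {
  expect_equal(utility_at(params, 55), 0.8639, tolerance = 1e-12)
  expect_equal(utility_at(params, 65), 0.8159, tolerance = 1e-12)
  expect_equal(utility_at(params, 55, pc_diagnosed = TRUE), 0.8639 * 0.93,
               tolerance = 1e-12)
  # floor at zero far beyond the table range
  expect_equal(utility_at(params, 1000), 0)
})

test_that("discounting follows the 3.5% closed form", {
  expect_equal(discount_factor(params, 0), 1)
  expect_equal(discount_factor(params, 10), 1.035^-10, tolerance = 1e-12)
  expect_equal(discount_factor(params, 10), 0.7089, tolerance = 1e-4)
  p0 <- econ_params(discount_rate = 0)
  expect_equal(discount_factor(p0, 37), 1)
  expect_error(discount_factor(params, -1))
})

test_that("costing the cascade matches unit-cost arithmetic", {
  rates <- flat_table(88:90, h_inc = 0.1, cohort = 1)
  sched <- build_schedule(strategy("none"), rates)
  eff <- screening_effects()
  # one early-stage clinical case, prostatectomy-only mix, no discounting
  mix <- matrix(c(1, 1), nrow = 2,
                dimnames = list(c("early", "advanced"), "prostatectomy"))
  p <- econ_params(discount_rate = 0, advanced_share = 0, treatment_mix = mix)
  out <- run_cohort(rates, sched, eff, 89, 1)
  ct <- cost_trajectory(out, p, rr_advanced = eff$rr_advanced)
  cases <- out$cases
  # every clinical case: one biopsy + staging + prostatectomy
  expect_equal(sum(ct$cost), cases * (388 + 770 + 8173), tolerance = 1e-9)
  # per-case lump: staging + prostatectomy = 8943
  expect_equal(770 + 8173, 8943)
  # no screening scenario carries no PSA or genotyping cost
  expect_equal(sum(out$trajectories$screens), 0)
  expect_equal(sum(out$trajectories$genotyped), 0)
})

test_that("palliation is charged once per prostate-cancer death", {
  rates <- rate_table(88:90, pc_incidence = c(0.5, 0.5, 0.5),
                      pc_mortality = c(0.1, 0.1, 0.1),
                      other_mortality = c(0, 0, 0))
  sched <- build_schedule(strategy("none"), rates)
  p <- econ_params(discount_rate = 0)
  out <- run_cohort(rates, sched, screening_effects(), 88, 1)
  ct <- cost_trajectory(out, p)
  qt <- qaly_trajectory(out, p)
  palliation_part <- sum(out$trajectories$pc_deaths) * 6837
  stage_free <- econ_params(discount_rate = 0,
                            costs = modifyList(p$costs,
                                               list(palliation = 0)))
  ct0 <- cost_trajectory(out, stage_free)
  expect_equal(sum(ct$cost) - sum(ct0$cost), palliation_part,
               tolerance = 1e-9)
  expect_true(all(qt$qaly >= 0))
})

test_that("ICER and NMB reproduce the published incremental arithmetic", {
  # age-based vs no screening from the published outcome table
  expect_equal(icer(574e6, 16416), 34952, tolerance = 5e-3)
  # 2% threshold row
  expect_equal(icer(597e6, 19709), 30297, tolerance = 5e-3)
  expect_equal(icer(0, 123), 0)
  expect_error(icer(1, 0), "undefined")
  expect_equal(nmb(16416, 574e6, 20000), -245.68e6, tolerance = 1e-6)
  expect_equal(nmb(21109, 463e6, 30000), 170.27e6, tolerance = 1e-6)
  expect_equal(nmb(100, 55, 0), -55)
})

test_that("discounting and utilities bound the aggregates", {
  rates <- generate_rates()
  out <- run_scenario(rates, strategy("age_based"))
  expect_lte(out$qalys, out$qalys_undiscounted)
  expect_lte(out$costs, out$costs_undiscounted)
  expect_lte(out$qalys_undiscounted, out$life_years)
})

test_that("NMB ranking agrees with ICER-versus-WTP classification pairwise", {
  rates <- generate_rates()
  outs <- lapply(list(strategy("none"), strategy("age_based"),
                      strategy("precision", threshold = 0.05)),
                 function(st) run_scenario(rates, st))
  for (w in c(20000, 30000)) {
    for (i in 2:3) {
      dq <- outs[[i]]$qalys - outs[[1]]$qalys
      dc <- outs[[i]]$costs - outs[[1]]$costs
      inc_nmb <- nmb(dq, dc, w)
      cost_effective <- dq > 0 && icer(dc, dq) <= w
      expect_equal(inc_nmb > 0, cost_effective)
    }
  }
})
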