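test_that("parameter draws respect their distributions' moments and supports", {
  d <- sample_draws(2e5, seed = 11)
  expect_true(all(d$rr_mortality > 0))
  expect_true(all(d$base_utility <= 1 & d$base_utility >= 0.83))
  expect_true(all(d$pc_utility_multiplier <= 1))
  expect_true(all(unlist(d[c("psa_test", "biopsy", "palliation")]) >= 0))
  # log-normal RR around the point estimate (mean of the log-normal is
  # exp(mu + s^2/2); with s = 0.06 that is within a third of a percent)
  se_m <- sd(d$rr_mortality) / sqrt(nrow(d))
  expect_lt(abs(mean(d$rr_mortality) - 0.79 * exp(0.06^2 / 2)), 3 * se_m)
  # incidence RR percentiles match the log-normal(log 1.23, 0.18) closed form
  q <- quantile(d$rr_incidence, c(0.025, 0.975))
  expect_equal(unname(q), 1.23 * exp(qnorm(c(0.025, 0.975)) * 0.18),
               tolerance = 5e-3)
  # mortality RR interval sits close to the published (0.69, 0.91)
  qm <- quantile(d$rr_mortality, c(0.025, 0.975))
  expect_equal(unname(qm), c(0.69, 0.91), tolerance = 0.03)
  # PSA-test cost mean: Gamma(33.9, 0.3) has mean 10.17
  se_c <- sd(d$psa_test) / sqrt(nrow(d))
  expect_lt(abs(mean(d$psa_test) - 33.9 * 0.3), 3 * se_c)
  # overdiagnosis perturbation: mean 1, SD giving 0.001 at the central age
  expect_equal(mean(d$od_multiplier), 1, tolerance = 1e-3)
  expect_equal(sd(d$od_multiplier), 0.001 / 0.248, tolerance = 0.05)
  expect_error(sample_draws(0), "positive count")
})

rates <- generate_rates()
strats <- list(strategy("none"), strategy("age_based"),
               strategy("precision", threshold = 0.04))

test_that("degenerate draws collapse the PSA onto the deterministic run", {
  d0 <- sample_draws(3, degenerate = TRUE)
  ps <- run_psa(strats, rates, draws = d0)
  det <- lapply(strats, function(st) run_scenario(rates, st))
  for (j in seq_along(strats)) {
    for (f in c("cases", "overdiagnosed", "pc_deaths", "qalys", "costs")) {
      expect_equal(unname(ps$draws_by_strategy[1, j, f]), det[[j]][[f]],
                   tolerance = 1e-9)
    }
    # every draw identical
    expect_equal(ps$draws_by_strategy[1, j, ], ps$draws_by_strategy[3, j, ],
                 tolerance = 1e-12)
  }
})

test_that("a fixed seed makes PSA summaries bit-identical", {
  a <- run_psa(strats, rates, n = 25, seed = 99)
  b <- run_psa(strats, rates, n = 25, seed = 99)
  expect_identical(a$summary, b$summary)
  expect_identical(a$ceac, b$ceac)
  expect_identical(a$icer, b$icer)
  c <- run_psa(strats, rates, n = 25, seed = 100)
  expect_false(identical(a$summary, c$summary))
})

test_that("CEACs are monotone in willingness to pay and frontier sums to one", {
  ps <- run_psa(strats, rates, n = 60, seed = 5,
                wtp_grid = seq(0, 60000, by = 5000))
  for (s in unique(ps$ceac$strategy)) {
    p <- ps$ceac$probability[ps$ceac$strategy == s]
    if (all(is.na(p))) next  # referent
    expect_true(all(diff(p) >= 0))
  }
  tot <- tapply(ps$frontier$probability, ps$frontier$wtp, sum)
  expect_equal(as.numeric(tot), rep(1, length(tot)), tolerance = 1e-12)
})

test_that("PSA intervals bracket the deterministic point estimate", {
  ps <- run_psa(strats, rates, n = 120, seed = 17)
  det <- run_scenario(rates, strategy("age_based"))
  s <- ps$summary[ps$summary$strategy == format(strategy("age_based")), ]
  for (f in c("pc_deaths", "qalys", "costs")) {
    row <- s[s$field == f, ]
    expect_gte(det[[f]], row$lo)
    expect_lte(det[[f]], row$hi)
  }
})

test_that("mean incremental QALYs stabilise as draws accumulate", {
  d <- sample_draws(800, seed = 31)
  ps <- run_psa(strats, rates, draws = d)
  dq <- ps$draws_by_strategy[, 2, "qalys"] - ps$draws_by_strategy[, 1, "qalys"]
  m200 <- mean(dq[1:200])
  m800 <- mean(dq)
  se200 <- sd(dq[1:200]) / sqrt(200)
  expect_lt(abs(m200 - m800), 4 * se200)
})

test_that("run_psa validates its strategy list", {
  expect_error(run_psa(list(strategy("age_based")), rates), "at least two")
  expect_error(run_psa(list(strategy("age_based"),
                            strategy("precision", threshold = 0.05)),
                       rates, n = 2), "referent")
})
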