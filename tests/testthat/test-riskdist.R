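m <- risk_model()

test_that("the population mean relative risk is exactly 1", {
  # closed form
  expect_equal(exp(m$mu + m$variance / 2), 1, tolerance = 1e-12)
  # quadrature over the log-normal density, independent of the closed form
  Er <- integrate(function(x) exp(x) * dnorm(x, m$mu, m$sigma),
                  -30, 30, abs.tol = 1e-10)$value
  expect_lt(abs(Er - 1), 1e-9)
})

test_that("percentile relative risks match closed forms and are log-symmetric", {
  expect_equal(percentile_rr(m, 0.5), exp(-0.34), tolerance = 1e-12)
  expect_equal(percentile_rr(m, 0.99), 4.847, tolerance = 1e-4)
  # degenerate distribution: any percentile gives RR 1
  m0 <- risk_model(variance = 1e-12)
  expect_equal(percentile_rr(m0, 0.123), 1, tolerance = 1e-5)
  # strictly increasing in p
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(percentile_rr(m, p)) > 0))
  # log-symmetry: rr(p) * rr(1-p) = exp(2 mu)
  expect_equal(percentile_rr(m, p) * percentile_rr(m, 1 - p),
               rep(exp(2 * m$mu), length(p)), tolerance = 1e-10)
  expect_error(percentile_rr(m, 0), "\\(0, 1\\)")
  expect_error(percentile_rr(m, 1.2), "\\(0, 1\\)")
})

test_that("case enrichment above a percentile matches quadrature and Monte Carlo", {
  # quadrature oracle: integral of r dF(r) above the threshold, divided by
  # E(r) = 1 (the size-biased mass above the population percentile)
  frac_oracle <- function(q) {
    thr <- m$mu + qnorm(q) * m$sigma
    integrate(function(x) exp(x) * dnorm(x, m$mu, m$sigma), thr, 40,
              abs.tol = 1e-10)$value
  }
  for (q in c(0.2, 0.5, 0.8, 0.95)) {
    expect_equal(fraction_cases_above_percentile(m, q), frac_oracle(q),
                 tolerance = 1e-8)
  }
  expect_equal(fraction_cases_above_percentile(m, 0.80), 0.4932,
               tolerance = 1e-4)
  # q -> 0 limit: all cases above the minimum
  expect_equal(fraction_cases_above_percentile(m, 1e-12), 1, tolerance = 1e-9)
  # strictly decreasing in q and always >= 1 - q
  q <- seq(0.05, 0.95, by = 0.05)
  fr <- fraction_cases_above_percentile(m, q)
  expect_true(all(diff(fr) < 0))
  expect_true(all(fr >= 1 - q))
  # brute-force Monte Carlo: size-biased sampling by weighting draws by r
  set.seed(101)
  r <- rlnorm(1e7, m$mu, m$sigma)
  w <- r / sum(r)
  above <- r > percentile_rr(m, 0.8)
  mc <- sum(w[above])
  se <- sqrt(sum((w * (above - mc))^2))
  expect_lt(abs(mc - fraction_cases_above_percentile(m, 0.8)), 3 * se + 1e-4)
})

test_that("eligibility fractions reproduce the printed anchors", {
  expect_equal(eligible_fraction(m, 0.026, 0.05), 0.114, tolerance = 5e-3)
  expect_equal(eligible_fraction(m, 0.071, 0.05), 0.505, tolerance = 5e-3)
  # the median man sits exactly at baseline * exp(mu)
  expect_equal(eligible_fraction(m, 0.03, 0.03 * exp(m$mu)), 0.5,
               tolerance = 1e-12)
  # monotone: decreasing in threshold, increasing in baseline
  thr <- seq(0.02, 0.2, by = 0.01)
  expect_true(all(diff(eligible_fraction(m, 0.05, thr)) < 0))
  base <- seq(0.01, 0.2, by = 0.01)
  expect_true(all(diff(eligible_fraction(m, base, 0.05)) > 0))
  expect_error(eligible_fraction(m, -0.1, 0.05), "baseline_risk")
  expect_error(eligible_fraction(m, 0.05, 0), "threshold")
})

test_that("stratum relative risks match numerical integration and conserve incidence", {
  s <- stratum_relative_risks(m, 0.026, 0.05)
  # oracle: truncated size-biased means by quadrature
  thr <- log(0.05 / 0.026)
  f_or <- integrate(function(x) dnorm(x, m$mu, m$sigma), thr, 40,
                    abs.tol = 1e-10)$value
  mean_above <- integrate(function(x) exp(x) * dnorm(x, m$mu, m$sigma),
                          thr, 40, abs.tol = 1e-10)$value / f_or
  expect_equal(s$rr_screened, mean_above, tolerance = 1e-8)
  expect_equal(s$rr_screened, 3.084, tolerance = 1e-3)
  expect_equal(s$rr_unscreened, 0.732, tolerance = 1e-3)
  expect_equal(s$eligible_fraction, 0.114, tolerance = 5e-3)
  # conservation identity on a grid of (baseline, threshold) pairs
  grid <- expand.grid(b = seq(0.01, 0.15, length.out = 10),
                      t = seq(0.015, 0.2, length.out = 10))
  for (i in seq_len(nrow(grid))) {
    s <- stratum_relative_risks(m, grid$b[i], grid$t[i])
    f <- s$eligible_fraction
    expect_equal(f * s$rr_screened + (1 - f) * s$rr_unscreened, 1,
                 tolerance = 1e-9)
  }
  # whole-population limit: rr_screened -> 1 as the threshold vanishes
  s <- stratum_relative_risks(m, 0.05, 2.5e-4)
  expect_equal(s$rr_screened, 1, tolerance = 1e-6)
  expect_gt(s$eligible_fraction, 1 - 1e-8)
  expect_error(stratum_relative_risks(risk_model(1e-10), 0.05, 0.9),
               "degenerate")
})
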