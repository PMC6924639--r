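#' Polygenic relative-risk model
#'
#' Constructs the population distribution of prostate-cancer relative risk
#' implied by common susceptibility variants. On the relative-risk scale the
#' distribution is log-normal; its log-scale variance summarises how strongly
#' the known variants spread risk across the population. The location is fixed
#' at `mu = -variance/2` so that the population mean relative risk is exactly 1,
#' which makes total incidence invariant to stratification: splitting a cohort
#' by polygenic risk redistributes cases without creating or destroying them.
#'
#' @param variance Variance of the log relative risk (dimensionless, > 0).
#'   The default 0.68 corresponds to the known prostate-cancer susceptibility
#'   variants.
#' @return An object of class `risk_model` with elements `variance`, `mu`
#'   (location of log relative risk) and `sigma` (its standard deviation).
#' @examples
#' m <- risk_model()
#' percentile_rr(m, c(0.01, 0.5, 0.99))
#' @export
risk_model <- function(variance = 0.68) {
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance <= 0) {
    stop("`variance` must be a single positive number", call. = FALSE)
  }
  structure(
    list(variance = variance, mu = -variance / 2, sigma = sqrt(variance)),
    class = "risk_model"
  )
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Log-normal polygenic relative-risk model\n")
  cat(sprintf("  log-scale variance: %.4g (sd %.4g)\n", x$variance, x$sigma))
  cat(sprintf("  location mu = -variance/2 = %.4g (mean relative risk = 1)\n",
              x$mu))
  cat(sprintf("  median RR %.3f; 1st/99th percentile RR %.3f / %.3f\n",
              percentile_rr(x, 0.5), percentile_rr(x, 0.01),
              percentile_rr(x, 0.99)))
  invisible(x)
}

#' Relative risk at a population percentile
#'
#' Quantile function of the polygenic relative-risk distribution:
#' `exp(mu + qnorm(p) * sigma)`.
#'
#' @param model A [risk_model()].
#' @param p Population percentile(s), each strictly in (0, 1).
#' @return Relative risk(s), dimensionless; strictly increasing in `p`.
#' @export
percentile_rr <- function(model, p) {
  stopifnot(inherits(model, "risk_model"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("percentile `p` must lie strictly in (0, 1)", call. = FALSE)
  }
  exp(model$mu + stats::qnorm(p) * model$sigma)
}

#' Fraction of all cases above a population risk percentile
#'
#' Among men who develop prostate cancer, polygenic risk follows the
#' size-biased version of the population distribution: on the log scale the
#' case distribution is Normal(mu + variance, variance), its mean shifted up
#' by one log-variance. This returns the probability mass of that case
#' distribution above the population `q`-th percentile, i.e. the fraction of
#' all cases arising in the top `100*(1-q)%` of the population.
#'
#' @param model A [risk_model()].
#' @param q Population percentile(s) defining the stratum boundary, in (0, 1).
#' @return Fraction(s) of all cases above the boundary; always at least
#'   `1 - q` because cases are enriched at high risk.
#' @examples
#' # share of cases in the top 20% of the risk distribution
#' fraction_cases_above_percentile(risk_model(), 0.8)
#' @export
fraction_cases_above_percentile <- function(model, q) {
  stopifnot(inherits(model, "risk_model"))
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("percentile `q` must lie strictly in (0, 1)", call. = FALSE)
  }
  # boundary on log scale is mu + z_q*sigma; case distribution has mean
  # mu + sigma^2, so the standardised boundary is z_q - sigma
  stats::pnorm(stats::qnorm(q) - model$sigma, lower.tail = FALSE)
}

#' Population fraction eligible at an absolute-risk threshold
#'
#' Individual 10-year absolute risk is modelled as `baseline_risk * r` where
#' `r` is the polygenic relative risk, so a man is at or above the threshold
#' when `log r >= log(threshold / baseline_risk)`. Returns the population
#' probability of that event.
#'
#' @param model A [risk_model()].
#' @param baseline_risk Background 10-year absolute risk (population average,
#'   in (0, 1)); may be a vector.
#' @param threshold 10-year absolute-risk threshold (in (0, 1\]).
#' @return Fraction(s) of the population whose individual risk meets the
#'   threshold; decreasing in `threshold`, increasing in `baseline_risk`.
#' @examples
#' # eligibility at a 5% threshold for a 2.6% background risk
#' eligible_fraction(risk_model(), 0.026, 0.05)
#' @export
eligible_fraction <- function(model, baseline_risk, threshold) {
  stopifnot(inherits(model, "risk_model"))
  if (any(!is.finite(baseline_risk)) || any(baseline_risk <= 0) ||
      any(baseline_risk >= 1)) {
    stop("`baseline_risk` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(threshold)) || any(threshold <= 0) ||
      any(threshold > 1)) {
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  }
  crit <- log(threshold / baseline_risk)
  stats::pnorm((crit - model$mu) / model$sigma, lower.tail = FALSE)
}

#' Relative risks in the screened and unscreened strata
#'
#' Splits the population at an absolute-risk threshold and returns the mean
#' relative risk of developing prostate cancer in each stratum. With `f` the
#' eligible (screened) fraction and `C` the fraction of all cases arising above
#' the threshold, the stratum means are `C / f` and `(1 - C) / (1 - f)`; they
#' satisfy the conservation identity `f * rr_screened + (1 - f) * rr_unscreened
#' = 1`, so stratification never changes total incidence.
#'
#' @inheritParams eligible_fraction
#' @return A list with elements `rr_screened`, `rr_unscreened` and
#'   `eligible_fraction`.
#' @examples
#' stratum_relative_risks(risk_model(), 0.026, 0.05)
#' @export
stratum_relative_risks <- function(model, baseline_risk, threshold) {
  f <- eligible_fraction(model, baseline_risk, threshold)
  if (any(f <= 0) || any(f >= 1)) {
    stop("degenerate stratum: eligible fraction is numerically 0 or 1 at ",
         "this threshold; use an all-or-none strategy instead", call. = FALSE)
  }
  crit <- log(threshold / baseline_risk)
  z <- (crit - model$mu) / model$sigma
  cases_above <- stats::pnorm(z - model$sigma, lower.tail = FALSE)
  list(
    rr_screened = cases_above / f,
    rr_unscreened = (1 - cases_above) / (1 - f),
    eligible_fraction = f
  )
}
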