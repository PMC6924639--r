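#' Screening strategy definition
#'
#' A screening strategy is one of: `none` (no organised screening),
#' `age_based` (PSA testing every `interval` years from `start_age` to
#' `stop_age` for everyone), or `precision` (each man starts quadrennial PSA
#' testing at the age his individual 10-year absolute risk — baseline risk
#' times his polygenic relative risk — first reaches `threshold`; once
#' eligible, always eligible).
#'
#' @param kind `"none"`, `"age_based"` or `"precision"`.
#' @param start_age,stop_age Screening window (defaults 55 and 69).
#' @param interval Years between PSA tests (default 4).
#' @param psa_cutoff PSA referral cutoff in ng/mL (default 3.0; drives the
#'   biopsy cascade costing, not the hazards).
#' @param threshold 10-year absolute-risk threshold for precision screening,
#'   in (0, 1\].
#' @param uptake Fraction of eligible men attending screening (default 1).
#' @return A list of class `strategy`.
#' @examples
#' strategy("precision", threshold = 0.04)
#' @export
strategy <- function(kind = c("none", "age_based", "precision"),
                     start_age = 55L, stop_age = 69L, interval = 4L,
                     psa_cutoff = 3.0, threshold = NULL, uptake = 1.0) {
  kind <- match.arg(kind)
  stopifnot(start_age < stop_age, stop_age <= 90, interval >= 1,
            uptake >= 0, uptake <= 1)
  if (kind == "precision") {
    if (is.null(threshold) || !is.numeric(threshold) ||
        threshold <= 0 || threshold > 1) {
      stop("precision screening needs `threshold` in (0, 1]; ",
           "use kind = \"age_based\" to screen everyone", call. = FALSE)
    }
  }
  structure(list(kind = kind, start_age = as.integer(start_age),
                 stop_age = as.integer(stop_age),
                 interval = as.integer(interval), psa_cutoff = psa_cutoff,
                 threshold = threshold, uptake = uptake),
            class = "strategy")
}

#' @export
format.strategy <- function(x, ...) {
  switch(x$kind,
         none = "no screening",
         age_based = sprintf("age-based %d-%d q%dy", x$start_age, x$stop_age,
                             x$interval),
         precision = sprintf("precision %.1f%% threshold %d-%d q%dy",
                             100 * x$threshold, x$start_age, x$stop_age,
                             x$interval))
}

#' @export
print.strategy <- function(x, ...) {
  cat("Screening strategy:", format(x), "\n")
  if (x$uptake < 1) cat(sprintf("  uptake %.0f%%\n", 100 * x$uptake))
  invisible(x)
}

#' Build the per-age schedule the life table consumes
#'
#' Translates a [strategy()] into per-age columns: the cumulative
#' ever-screened fraction of the population, the polygenic stratum relative
#' risks of the screened and unscreened strata, the fraction of the screened
#' stratum receiving a PSA test that year, whether the screening window is
#' active, and the newly genotyped fraction.
#'
#' For precision strategies the eligible fraction at age `a` is
#' `eligible_fraction(model, ten_year_absolute_risk(rates, a), threshold)`,
#' forced non-decreasing in age (once a man's risk crosses the threshold he
#' stays eligible). The screened stratum at age `a` is therefore the top
#' `f(a)` of the polygenic distribution and its mean relative risk comes from
#' the size-biased case distribution over that upper tail, so the identity
#' `f * rr_screened + (1 - f) * rr_unscreened = 1` holds at every age.
#' Non-attenders (uptake < 1) are a random subset of the eligible: they dilute
#' the screened fraction but not the screened stratum's relative risk.
#'
#' @param strategy A [strategy()].
#' @param rates A [rate_table()] covering the schedule ages (plus the 10-year
#'   risk window beyond `stop_age` for precision strategies).
#' @param model A [risk_model()].
#' @param biopsy_positivity Per-screen probability that PSA meets the referral
#'   cutoff; a single number or a data.frame with columns `age`, `positivity`
#'   (default flat 0.12, a synthetic placeholder).
#' @param end_age Age at which follow-up stops (default 90).
#' @return A `data.frame` of class `screen_schedule` with one row per cycle
#'   age.
#' @export
build_schedule <- function(strategy, rates, model = risk_model(),
                           biopsy_positivity = 0.12, end_age = 90L) {
  stopifnot(inherits(strategy, "strategy"))
  validate_rate_table(rates)
  ages <- min(rates$age):(end_age - 1L)
  n <- length(ages)
  st <- strategy
  f <- rep(0, n); rr_s <- rep(1, n); rr_u <- rep(1, n)
  screen_frac <- rep(0, n); active <- rep(0, n); genotype_frac <- rep(0, n)

  if (st$kind != "none") {
    win <- ages >= st$start_age & ages <= st$stop_age
    active[win] <- 1
    if (st$kind == "age_based") {
      f_elig <- as.numeric(ages >= st$start_age)
      screen_ages <- seq(st$start_age, st$stop_age, by = st$interval)
      mass <- as.numeric(ages %in% screen_ages)
    } else {
      if (max(rates$age) < st$stop_age + 9L) {
        stop("precision scheduling needs rates to age ", st$stop_age + 9L,
             " for the 10-year risk window", call. = FALSE)
      }
      f_elig <- rep(0, n)
      base_risk <- ten_year_absolute_risk(rates, st$start_age:st$stop_age)
      raw <- eligible_fraction(model, base_risk, st$threshold)
      raw <- cummax(raw)                      # absorbing eligibility
      idx <- match(st$start_age:st$stop_age, ages)
      f_elig[idx] <- raw
      f_elig[ages > st$stop_age] <- raw[length(raw)]
      # crossing increments: each crossing cohort screens every `interval`
      # years from its crossing age until stop_age
      inc <- diff(c(0, raw))
      cross_ages <- st$start_age:st$stop_age
      mass <- rep(0, n)
      for (k in seq_along(cross_ages)) {
        if (inc[k] <= 0) next
        sa <- seq(cross_ages[k], st$stop_age, by = st$interval)
        mass[match(sa, ages)] <- mass[match(sa, ages)] + inc[k]
      }
      genotype_frac[ages == st$start_age] <- 1
    }
    stopifnot(all(diff(f_elig) >= -1e-12))    # monotonisation post-condition
    f <- st$uptake * f_elig
    tiny <- 1e-12
    strat_idx <- f_elig > tiny & f_elig < 1 - tiny
    if (st$kind == "precision" && any(strat_idx)) {
      fe <- f_elig[strat_idx]
      cases_above <- fraction_cases_above_percentile(model, 1 - fe)
      rr_s[strat_idx] <- cases_above / fe
    }
    fu <- f
    has_u <- fu < 1 - tiny
    rr_u[has_u] <- (1 - fu[has_u] * rr_s[has_u]) / (1 - fu[has_u])
    rr_u[!has_u] <- 1
    # per-attending-man test indicator; uptake cancels between mass and f
    screen_frac <- ifelse(f_elig > tiny, mass / f_elig, 0)
  }

  pos <- if (is.data.frame(biopsy_positivity)) {
    p <- biopsy_positivity$positivity[match(ages, biopsy_positivity$age)]
    if (anyNA(p)) stop("biopsy positivity does not cover all schedule ages",
                       call. = FALSE)
    p
  } else rep(biopsy_positivity, n)

  out <- data.frame(age = ages, screened_fraction = f, rr_screened = rr_s,
                    rr_unscreened = rr_u, screen_frac = screen_frac,
                    active = active, genotype_frac = genotype_frac)
  class(out) <- c("screen_schedule", "data.frame")
  attr(out, "strategy") <- st
  attr(out, "end_age") <- as.integer(end_age)
  attr(out, "positivity") <- pos
  out
}
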