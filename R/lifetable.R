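#' Screening-effect parameters
#'
#' Collects the relative effects of PSA screening applied inside the life
#' table: the mortality reduction in screened men, the incidence inflation
#' while screening is active (lead time plus overdiagnosis), the shift away
#' from advanced stage among screen-detected cancers, the age-dependent
#' proportion of screen-detected cases that are overdiagnosed, and the share
#' of registry incidence attributable to pre-existing opportunistic testing.
#'
#' @param rr_mortality Relative risk of prostate-cancer death with screening
#'   (default 0.79).
#' @param rr_incidence Relative increase in incidence while actively screened
#'   (default 1.23).
#' @param rr_advanced Relative risk of advanced stage at diagnosis if
#'   screen-detected (default 0.85).
#' @param overdiagnosis_intercept,overdiagnosis_slope Linear-in-age model of
#'   the proportion of screen-detected cases overdiagnosed, clamped to
#'   \[0, 1\] after evaluation (defaults -0.62 and 0.014 per year).
#' @param opportunistic_fraction Share of registry incidence attributed to
#'   opportunistic PSA testing; background clinical incidence is registry
#'   incidence times `1 - opportunistic_fraction` (default 0.10).
#' @param screen_detected Which incident cases count as screen-detected (the
#'   overdiagnosis multiplicand): `"active_stratum"` (all incident cases in
#'   the actively screened stratum) or `"excess_incidence"` (only the excess
#'   over the unscreened incidence level).
#' @param overdiagnosis_multiplier Multiplicative perturbation of the
#'   overdiagnosis proportion, used by the probabilistic sensitivity engine
#'   (default 1).
#' @return A list of class `screening_effects`.
#' @export
screening_effects <- function(rr_mortality = 0.79,
                              rr_incidence = 1.23,
                              rr_advanced = 0.85,
                              overdiagnosis_intercept = -0.62,
                              overdiagnosis_slope = 0.014,
                              opportunistic_fraction = 0.10,
                              screen_detected = c("active_stratum",
                                                  "excess_incidence"),
                              overdiagnosis_multiplier = 1) {
  screen_detected <- match.arg(screen_detected)
  stopifnot(rr_mortality > 0, rr_incidence > 0, rr_advanced > 0,
            opportunistic_fraction >= 0, opportunistic_fraction < 1,
            overdiagnosis_multiplier >= 0)
  structure(as.list(environment()), class = "screening_effects")
}

#' Proportion of screen-detected cases overdiagnosed at a given age
#'
#' Evaluates the linear-in-age overdiagnosis model
#' `intercept + slope * age`, clamped to \[0, 1\]. With the defaults this
#' gives 0.15 at age 55 and 0.346 at age 69.
#'
#' @param effects A [screening_effects()].
#' @param age Attained age(s) in years.
#' @return Proportion(s) in \[0, 1\].
#' @export
overdiagnosis_proportion <- function(effects, age) {
  stopifnot(inherits(effects, "screening_effects"))
  p <- effects$overdiagnosis_intercept + effects$overdiagnosis_slope * age
  pmin(pmax(p * effects$overdiagnosis_multiplier, 0), 1)
}

# Annual-cycle engine for one single-entry-age cohort.
#
# Transitions within a cycle, in order: stratum migration (newly eligible men
# move from the unscreened to the ever-screened stratum), screening tests,
# incidence, prostate-cancer death, other-cause death. Life-years count men
# alive at the start of the cycle; deaths fall at year end (no half-cycle
# correction).
#
# `sched` is the strategy schedule matrix restricted to ages entry..89 with
# columns f, rr_s, rr_u, screen_frac, active. Returns per-age streams.
cohort_engine <- function(h_inc, h_pcm, h_oth, sched, od_p, effects,
                          entry_age, cohort_size, positivity,
                          genotype_age = NA_integer_) {
  n <- length(h_inc)
  ages <- entry_age + seq_len(n) - 1L
  rr_mort <- effects$rr_mortality
  rr_inc <- effects$rr_incidence
  opp <- effects$opportunistic_fraction
  excess_mode <- identical(effects$screen_detected, "excess_incidence")

  f_col <- sched[, 1L]; rrs_col <- sched[, 2L]; rru_col <- sched[, 3L]
  scr_col <- sched[, 4L]; act_col <- sched[, 5L]

  hu <- cohort_size; hs <- 0; du <- 0; ds <- 0; ovd <- 0
  f_prev <- 0
  rec <- numeric(9)  # survivors diagnosed 1..9 years ago (10-year window)

  alive_v <- cases_v <- sd_v <- clin_v <- ovd_v <- pcd_v <- othd_v <-
    scr_v <- pos_v <- gen_v <- rec_v <- numeric(n)

  for (i in seq_len(n)) {
    a <- ages[i]
    alive0 <- hu + hs + du + ds + ovd
    alive_v[i] <- alive0

    # migration of newly eligible healthy men into the screened stratum
    f_new <- f_col[i]
    if (f_new > f_prev && f_prev < 1) {
      mv <- hu * (f_new - f_prev) / (1 - f_prev)
      hu <- hu - mv; hs <- hs + mv
    }
    f_prev <- max(f_prev, f_new)

    if (!is.na(genotype_age) && a == genotype_age) gen_v[i] <- hu + hs + du + ds + ovd

    # screening tests among healthy men of the screened stratum
    scr_n <- hs * scr_col[i]
    scr_v[i] <- scr_n
    pos_v[i] <- scr_n * positivity[i]

    # incidence (background clinical incidence excludes the opportunistic
    # share already embedded in registry rates); the stratum RRs are
    # renormalised against the surviving healthy pools so stratification
    # redistributes cases without changing the population total
    base <- h_inc[i] * (1 - opp)
    act <- act_col[i] > 0
    ru <- rru_col[i]; rs <- rrs_col[i]
    den <- hu * ru + hs * rs
    lam <- if (den > 0) (hu + hs) / den else 1
    cu <- hu * base * ru * lam
    cs_base <- hs * base * rs * lam
    cs <- cs_base * (if (act) rr_inc else 1)
    sd <- if (!act) 0 else if (excess_mode) {
      max(cs_base * (rr_inc - 1), 0)
    } else cs
    new_ovd <- sd * od_p[i]
    hu <- hu - cu; hs <- hs - cs
    du <- du + cu
    ds <- ds + (cs - new_ovd)
    ovd <- ovd + new_ovd
    cases_v[i] <- cu + cs
    sd_v[i] <- sd
    clin_v[i] <- cu + cs - sd
    ovd_v[i] <- new_ovd
    rec_v[i] <- sum(rec) + cu + cs  # within 10 years of diagnosis this cycle

    # prostate-cancer death: population-rate hazard scaled by the stratum's
    # polygenic RR (renormalised as above) and by rr_mortality for the
    # ever-screened stratum; overdiagnosed men are exempt by definition
    dx_pool <- du + ds
    nu <- hu + du; ns <- hs + ds
    den2 <- nu * ru + ns * rs
    lam2 <- if (den2 > 0) (nu + ns) / den2 else 1
    pd_u <- nu * h_pcm[i] * ru * lam2
    pd_s <- ns * h_pcm[i] * rs * lam2 * (if (f_prev > 0) rr_mort else 1)
    # deduct from the diagnosed pool first; residual from healthy
    take_du <- if (pd_u < du) pd_u else du
    du <- du - take_du; hu <- hu - (pd_u - take_du)
    take_ds <- if (pd_s < ds) pd_s else ds
    ds <- ds - take_ds; hs <- hs - (pd_s - take_ds)
    pcd <- pd_u + pd_s
    pcd_v[i] <- pcd
    pc_rate_dx <- if (dx_pool > 0) {
      r <- pcd / dx_pool; if (r > 1) 1 else r
    } else 0

    # other-cause death, identical across strata and states
    ho <- h_oth[i]
    othd_v[i] <- (hu + hs + du + ds + ovd) * ho
    surv <- 1 - ho
    hu <- hu * surv; hs <- hs * surv; du <- du * surv; ds <- ds * surv
    ovd <- ovd * surv

    # age the 10-year post-diagnosis window
    dx_surv <- surv * (1 - pc_rate_dx)
    rec[2:9] <- rec[1:8] * dx_surv
    rec[1] <- (cu + cs) * dx_surv
  }

  list(age = ages, alive = alive_v, cases = cases_v, screen_detected = sd_v,
       clinical = clin_v, overdiagnosed = ovd_v, pc_deaths = pcd_v,
       other_deaths = othd_v, screens = scr_v, positives = pos_v,
       genotyped = gen_v, recent_dx = rec_v,
       alive_end = unname(hu + hs + du + ds + ovd), entry_age = entry_age,
       cohort_size = unname(cohort_size))
}

#' Run the life table for one single-entry-age cohort
#'
#' Simulates a cohort of men entering prostate-cancer-free at `entry_age` and
#' followed to age 90 in annual cycles. Each cycle the cohort is split into an
#' ever-screened stratum (cumulative eligible fraction from the schedule, with
#' its polygenic stratum relative risk) and an unscreened stratum; incidence,
#' prostate-cancer death (scaled by `rr_mortality` in the screened stratum)
#' and other-cause death compete in that order. Screen-detected cases are
#' overdiagnosed in the age-specific proportion; overdiagnosed men can only
#' die of other causes but keep the post-diagnosis utility decrement and
#' treatment costs.
#'
#' @param rates A [rate_table()].
#' @param schedule A schedule from [build_schedule()].
#' @param effects A [screening_effects()].
#' @param entry_age Entry age (years); follow-up runs to age 90.
#' @param cohort_size Men entering at `entry_age` (default 1, i.e. per-man
#'   rates).
#' @param econ Optional [econ_params()]; when supplied, discounted QALYs and
#'   costs are attached (discounting clock starts at entry).
#' @return A `scenario_outcome`: totals (`cases`, `overdiagnosed`,
#'   `pc_deaths`, `other_deaths`, `life_years`, `screens`, `biopsies`, and
#'   with `econ` also `qalys`, `costs`, undiscounted variants) plus per-age
#'   `trajectories`.
#' @export
run_cohort <- function(rates, schedule, effects = screening_effects(),
                       entry_age, cohort_size = 1, econ = NULL) {
  validate_rate_table(rates)
  stopifnot(inherits(schedule, "screen_schedule"))
  end_age <- attr(schedule, "end_age")
  if (entry_age >= end_age) stop("entry_age must be below ", end_age,
                                 call. = FALSE)
  ages <- entry_age:(end_age - 1L)
  i_r <- match(ages, rates$age)
  if (anyNA(i_r)) stop("rate table does not cover ages ", entry_age, "..",
                       end_age - 1L, call. = FALSE)
  i_s <- match(ages, schedule$age)
  if (anyNA(i_s)) stop("schedule does not cover ages ", entry_age, "..",
                       end_age - 1L, " - rebuild it for this rate table",
                       call. = FALSE)
  sched <- as.matrix(schedule[i_s, c("screened_fraction", "rr_screened",
                                     "rr_unscreened", "screen_frac",
                                     "active")])
  od_p <- overdiagnosis_proportion(effects, ages)
  kind <- attr(schedule, "strategy")$kind
  genotype_age <- if (identical(kind, "precision")) {
    max(attr(schedule, "strategy")$start_age, entry_age)
  } else NA_integer_
  positivity <- attr(schedule, "positivity")[i_s]
  streams <- cohort_engine(rates$pc_incidence[i_r], rates$pc_mortality[i_r],
                           rates$other_mortality[i_r], sched, od_p, effects,
                           entry_age, cohort_size, positivity, genotype_age)
  out <- outcome_from_streams(streams)
  if (!is.null(econ)) out <- attach_economics(out, econ, effects$rr_advanced)
  out
}

outcome_from_streams <- function(s) {
  structure(list(
    cases = sum(s$cases),
    overdiagnosed = sum(s$overdiagnosed),
    pc_deaths = sum(s$pc_deaths),
    other_deaths = sum(s$other_deaths),
    life_years = sum(s$alive),
    screens = sum(s$screens),
    biopsies = sum(s$positives) + sum(s$clinical),
    genotyped = sum(s$genotyped),
    alive_end = s$alive_end,
    cohort_size = s$cohort_size,
    entry_age = s$entry_age,
    trajectories = data.frame(
      age = s$age, alive = s$alive, cases = s$cases,
      screen_detected = s$screen_detected, clinical = s$clinical,
      overdiagnosed = s$overdiagnosed, pc_deaths = s$pc_deaths,
      other_deaths = s$other_deaths, screens = s$screens,
      positives = s$positives, genotyped = s$genotyped,
      recent_dx = s$recent_dx
    )
  ), class = "scenario_outcome")
}

#' Run a screening scenario for the full multi-age cohort
#'
#' Runs [run_cohort()] for every entry age carrying population weight in the
#' rate table (by default a cohort of men aged 55--69, each sub-cohort
#' followed to 90) and sums the outcomes. Discounting restarts at each
#' sub-cohort's entry.
#'
#' @inheritParams run_cohort
#' @param strategy A [strategy()]; the schedule is built internally.
#' @param model A [risk_model()] (used by precision strategies).
#' @return A `scenario_outcome` with the same fields as [run_cohort()];
#'   trajectories are aggregated on the attained-age axis.
#' @examples
#' rates <- generate_rates()
#' out <- run_scenario(rates, strategy("age_based"))
#' summary(out)
#' @export
run_scenario <- function(rates, strategy, model = risk_model(),
                         effects = screening_effects(), econ = econ_params()) {
  sched <- build_schedule(strategy, rates, model)
  entry <- rates$age[rates$population_weight > 0]
  if (!length(entry)) stop("rate table carries no population weights",
                           call. = FALSE)
  w <- rates$population_weight[rates$population_weight > 0]
  outs <- mapply(function(a, n) {
    run_cohort(rates, sched, effects, a, n, econ)
  }, entry, w, SIMPLIFY = FALSE)
  out <- Reduce(combine_outcomes, outs)
  out$entry_age <- range(entry)
  attr(out, "strategy") <- strategy
  out
}

combine_outcomes <- function(a, b) {
  tot <- lapply(c("cases", "overdiagnosed", "pc_deaths", "other_deaths",
                  "life_years", "screens", "biopsies", "genotyped",
                  "alive_end", "cohort_size", "qalys", "costs",
                  "qalys_undiscounted", "costs_undiscounted"),
                function(f) {
                  if (is.null(a[[f]]) || is.null(b[[f]])) NULL
                  else a[[f]] + b[[f]]
                })
  names(tot) <- c("cases", "overdiagnosed", "pc_deaths", "other_deaths",
                  "life_years", "screens", "biopsies", "genotyped",
                  "alive_end", "cohort_size", "qalys", "costs",
                  "qalys_undiscounted", "costs_undiscounted")
  tot <- tot[!vapply(tot, is.null, logical(1))]
  tr <- merge_trajectories(a$trajectories, b$trajectories)
  structure(c(tot, list(entry_age = a$entry_age, trajectories = tr)),
            class = "scenario_outcome")
}

merge_trajectories <- function(x, y) {
  all_age <- sort(union(x$age, y$age))
  pick <- function(d) {
    i <- match(all_age, d$age)
    z <- d[i, , drop = FALSE]
    z[is.na(i), ] <- 0
    z
  }
  xs <- pick(x); ys <- pick(y)
  out <- xs + ys
  out$age <- all_age
  out
}

#' @export
print.scenario_outcome <- function(x, ...) {
  strat <- attr(x, "strategy")
  cat("Screening scenario outcome")
  if (!is.null(strat)) cat(" [", format(strat), "]", sep = "")
  cat("\n")
  fmt <- function(v) format(round(v), big.mark = ",", scientific = FALSE)
  cat("  cohort size:   ", fmt(x$cohort_size), "\n")
  cat("  cases:         ", fmt(x$cases),
      " (overdiagnosed ", fmt(x$overdiagnosed), ")\n", sep = "")
  cat("  PC deaths:     ", fmt(x$pc_deaths), "\n")
  cat("  life-years:    ", fmt(x$life_years), "\n")
  if (!is.null(x$qalys)) {
    cat("  QALYs (disc.): ", fmt(x$qalys), "\n")
    cat(sprintf("  costs (disc.):  GBP %s\n", fmt(x$costs)))
  }
  invisible(x)
}

#' @export
summary.scenario_outcome <- function(object, ...) {
  flds <- c("cohort_size", "cases", "overdiagnosed", "pc_deaths",
            "other_deaths", "life_years", "screens", "biopsies", "genotyped",
            "qalys", "costs", "qalys_undiscounted", "costs_undiscounted")
  v <- unlist(object[intersect(flds, names(object))])
  v
}

#' @export
plot.scenario_outcome <- function(x, what = "cases", ...) {
  tr <- x$trajectories
  if (!what %in% names(tr)) stop("no trajectory column `", what, "`",
                                 call. = FALSE)
  graphics::plot(tr$age, tr[[what]], type = "h", xlab = "age",
                 ylab = paste(what, "per year"), ...)
  invisible(x)
}
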