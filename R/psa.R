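#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter from its assigned distribution: the three
#' screening relative risks log-normally around their point estimates (SEs
#' 0.06, 0.18 and 0.07 on the log scale), unit costs from Gamma distributions
#' (shape, scale) whose means sit at (or within ~7% of) the point costs, the
#' general-population utility as `0.83 + Gamma(4, 0.06) * 0.167`, the
#' prostate-cancer utility multiplier as `0.88 + Gamma(5, 0.05) * 0.2` clamped
#' to 1, and a tight Beta-distributed multiplicative perturbation of the
#' age-specific overdiagnosis proportion (moment-matched to mean equal to the
#' point value with SD 0.001 at the cohort's central age).
#'
#' @param n Number of draws (>= 1).
#' @param seed Integer seed; a fixed seed reproduces the draws exactly.
#' @param degenerate If `TRUE`, return the point estimates in every row
#'   (zero-variance check).
#' @return A data.frame of class `parameter_draws`, one row per draw.
#' @export
sample_draws <- function(n, seed = 42L, degenerate = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count", call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  n <- as.integer(n)
  gamma_cost <- list(  # Gamma(shape, scale) per unit cost
    psa_test = c(33.9, 0.3), genotyping = c(33.9, 0.7),
    biopsy = c(33.9, 11.5), declined_biopsy = c(33.9, 3.1),
    staging = c(33.9, 22.7), active_surveillance = c(33.9, 128.1),
    prostatectomy = c(33.9, 241.2), radiotherapy = c(33.9, 158.9),
    brachytherapy = c(33.9, 45.1), chemotherapy = c(33.9, 219.2),
    adt = c(33.9, 16.5), palliation = c(1.8, 3854.9))
  if (degenerate) {
    pt <- econ_params()
    d <- data.frame(draw = seq_len(n), rr_mortality = 0.79,
                    rr_incidence = 1.23, rr_advanced = 0.85,
                    base_utility = pt$base_utility,
                    pc_utility_multiplier = pt$pc_utility_multiplier,
                    od_multiplier = 1)
    for (nm in names(gamma_cost)) d[[nm]] <- pt$costs[[nm]]
  } else {
    set.seed(as.integer(seed))
    d <- data.frame(
      draw = seq_len(n),
      rr_mortality = stats::rlnorm(n, log(0.79), 0.06),
      rr_incidence = stats::rlnorm(n, log(1.23), 0.18),
      rr_advanced = stats::rlnorm(n, log(0.85), 0.07),
      base_utility = pmin(0.83 + stats::rgamma(n, 4, scale = 0.06) * 0.167, 1),
      pc_utility_multiplier =
        pmin(0.88 + stats::rgamma(n, 5, scale = 0.05) * 0.2, 1)
    )
    # multiplicative Beta perturbation, mean 1; SD chosen so the overdiagnosis
    # proportion at the cohort's central age (0.248 at 62) has SD 0.001
    s <- 0.001 / 0.248
    alpha <- (1 / s^2 - 1) / 2
    d$od_multiplier <- 2 * stats::rbeta(n, alpha, alpha)
    for (nm in names(gamma_cost)) {
      g <- gamma_cost[[nm]]
      d[[nm]] <- stats::rgamma(n, shape = g[1], scale = g[2])
    }
  }
  structure(d, class = c("parameter_draws", "data.frame"), seed = seed)
}

# Precompute everything about one strategy that does not change across draws.
strategy_context <- function(strat, rates, model, econ, end_age = 90L) {
  sched <- build_schedule(strat, rates, model, end_age = end_age)
  entries <- rates$age[rates$population_weight > 0]
  weights <- rates$population_weight[rates$population_weight > 0]
  ages_all <- sched$age
  pos_all <- attr(sched, "positivity")
  per_entry <- lapply(seq_along(entries), function(k) {
    a0 <- entries[k]
    ages <- a0:(end_age - 1L)
    i_r <- match(ages, rates$age)
    i_s <- match(ages, ages_all)
    list(entry = a0, weight = weights[k], ages = ages,
         h_inc = rates$pc_incidence[i_r], h_pcm = rates$pc_mortality[i_r],
         h_oth = rates$other_mortality[i_r],
         sched = as.matrix(sched[i_s, c("screened_fraction", "rr_screened",
                                        "rr_unscreened", "screen_frac",
                                        "active")]),
         positivity = pos_all[i_s],
         od_raw = NA,  # filled below
         disc = discount_factor(econ, ages - a0),
         age_c = ages - econ$utility_anchor_age,
         genotype_age = if (identical(strat$kind, "precision")) {
           max(strat$start_age, a0)
         } else NA_integer_)
  })
  list(strategy = strat, sched = sched, per_entry = per_entry)
}

scenario_totals_draw <- function(ctx, effects, econ_base, pars) {
  eff <- effects
  eff$rr_mortality <- pars$rr_mortality
  eff$rr_incidence <- pars$rr_incidence
  eff$overdiagnosis_multiplier <- pars$od_multiplier
  mix <- econ_base$treatment_mix
  uc <- unlist(pars[colnames(mix)])
  sc <- as.numeric(mix %*% uc)
  adv0 <- econ_base$advanced_share
  adv_sd <- min(adv0 * pars$rr_advanced, 1)
  ccl <- pars$staging + adv0 * sc[2] + (1 - adv0) * sc[1]
  csd <- pars$staging + adv_sd * sc[2] + (1 - adv_sd) * sc[1]
  comp <- econ_base$biopsy_compliance
  bunit <- comp * pars$biopsy + (1 - comp) * pars$declined_biopsy
  u0 <- pars$base_utility
  dcl <- econ_base$utility_decline
  mult <- pars$pc_utility_multiplier
  tot <- c(cases = 0, overdiagnosed = 0, pc_deaths = 0, qalys = 0, costs = 0,
           life_years = 0)
  for (pe in ctx$per_entry) {
    od_p <- overdiagnosis_proportion(eff, pe$ages)
    s <- cohort_engine(pe$h_inc, pe$h_pcm, pe$h_oth, pe$sched, od_p, eff,
                       pe$entry, pe$weight, pe$positivity, pe$genotype_age)
    u <- pmax(0, u0 - dcl * pe$age_c)
    recent <- pmin(s$recent_dx, s$alive)
    qaly <- sum(pe$disc * u * (s$alive - (1 - mult) * recent))
    cost <- sum(pe$disc * (s$screens * pars$psa_test +
                             s$genotyped * pars$genotyping +
                             (s$positives + s$clinical) * bunit +
                             s$screen_detected * csd + s$clinical * ccl +
                             s$pc_deaths * pars$palliation))
    tot <- tot + c(sum(s$cases), sum(s$overdiagnosed), sum(s$pc_deaths),
                   qaly, cost, sum(s$alive))
  }
  tot
}

#' Run the probabilistic sensitivity analysis
#'
#' Reruns every strategy for each parameter draw with common random numbers
#' (one coherent parameter set per draw, reused across strategies, so
#' incrementals are within-draw differences), then summarises: per-strategy
#' means and percentile 95% uncertainty intervals, ICERs from mean increments
#' versus no screening, the probability each strategy is cost-effective
#' against no screening at each willingness-to-pay value, the pairwise CEAC
#' over a WTP grid, the frontier CEAC (probability of having the highest net
#' monetary benefit among all strategies, which sums to 1 across strategies),
#' and the NMB ranking.
#'
#' @param strategies A list of [strategy()] objects; must include a
#'   no-screening strategy as referent.
#' @param rates A [rate_table()].
#' @param model A [risk_model()].
#' @param econ An [econ_params()] (non-sampled structure: discount rate,
#'   utility slope, treatment mix, compliance).
#' @param effects A [screening_effects()] carrying the non-sampled switches.
#' @param n Number of draws (default 10,000).
#' @param seed Seed for [sample_draws()] (default 42).
#' @param wtp_grid WTP grid for the CEACs (default 0 to 50,000 by 2,500).
#' @param draws Optional pre-sampled [sample_draws()] table overriding `n`
#'   and `seed`.
#' @return An object of class `psa_result`.
#' @export
run_psa <- function(strategies, rates, model = risk_model(),
                    econ = econ_params(), effects = screening_effects(),
                    n = 10000, seed = 42L,
                    wtp_grid = seq(0, 50000, by = 2500), draws = NULL) {
  if (!is.list(strategies) || length(strategies) < 2L ||
      !all(vapply(strategies, inherits, logical(1), "strategy"))) {
    stop("`strategies` must be a list of at least two strategy objects",
         call. = FALSE)
  }
  kinds <- vapply(strategies, `[[`, character(1), "kind")
  ref <- which(kinds == "none")
  if (length(ref) != 1L) {
    stop("strategies must include exactly one no-screening referent",
         call. = FALSE)
  }
  labels <- vapply(strategies, format, character(1))
  if (is.null(draws)) draws <- sample_draws(n, seed)
  n <- nrow(draws)
  ctxs <- lapply(strategies, strategy_context, rates = rates, model = model,
                 econ = econ)
  flds <- c("cases", "overdiagnosed", "pc_deaths", "qalys", "costs",
            "life_years")
  res <- array(NA_real_, dim = c(n, length(strategies), length(flds)),
               dimnames = list(NULL, labels, flds))
  for (i in seq_len(n)) {
    pars <- as.list(draws[i, ])
    for (j in seq_along(ctxs)) {
      tot <- tryCatch(
        scenario_totals_draw(ctxs[[j]], effects, econ, pars),
        error = function(e) {
          stop("draw ", i, " failed for strategy `", labels[j], "`: ",
               conditionMessage(e), call. = FALSE)
        })
      res[i, j, ] <- tot
    }
  }
  summarise_psa(res, ref, labels, wtp_grid, econ$wtp, seed)
}

summarise_psa <- function(res, ref, labels, wtp_grid, wtp_main, seed) {
  n <- dim(res)[1]
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE,
                                    type = 7)
  summ <- do.call(rbind, lapply(seq_along(labels), function(j) {
    do.call(rbind, lapply(dimnames(res)[[3]], function(f) {
      x <- res[, j, f]
      data.frame(strategy = labels[j], field = f, mean = mean(x),
                 lo = qs(x)[1], hi = qs(x)[2])
    }))
  }))
  dq <- res[, , "qalys"] - res[, ref, "qalys"]
  dc <- res[, , "costs"] - res[, ref, "costs"]
  mean_dq <- colMeans(dq)
  mean_dc <- colMeans(dc)
  icers <- ifelse(seq_along(labels) == ref, NA_real_, mean_dc / mean_dq)
  ceac <- do.call(rbind, lapply(wtp_grid, function(w) {
    data.frame(wtp = w, strategy = labels,
               probability = colMeans(dq * w - dc > 0))
  }))
  ceac$probability[ceac$strategy == labels[ref]] <- NA_real_
  frontier <- do.call(rbind, lapply(wtp_grid, function(w) {
    nmb_d <- res[, , "qalys"] * w - res[, , "costs"]
    best <- max.col(nmb_d, ties.method = "first")
    data.frame(wtp = w, strategy = labels,
               probability = tabulate(best, length(labels)) / n)
  }))
  ranking <- lapply(wtp_main, function(w) {
    nmb_mean <- colMeans(res[, , "qalys"] * w - res[, , "costs"])
    inc <- nmb_mean - nmb_mean[ref]
    data.frame(strategy = labels, wtp = w, nmb = nmb_mean,
               incremental_nmb = inc)[order(-nmb_mean), ]
  })
  structure(list(summary = summ, icer = data.frame(strategy = labels,
                                                   mean_dqaly = mean_dq,
                                                   mean_dcost = mean_dc,
                                                   icer_vs_none = icers),
                 ceac = ceac, frontier = frontier,
                 ranking = do.call(rbind, ranking),
                 referent = labels[ref], n_draws = n, seed = seed,
                 draws_by_strategy = res),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d draws, %d strategies\n",
              x$n_draws, length(unique(x$icer$strategy))))
  cat("ICER vs", x$referent, "(from mean increments):\n")
  print(transform(x$icer, icer_vs_none = round(icer_vs_none)),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.psa_result <- function(object, ...) object$summary

#' Plot cost-effectiveness acceptability curves
#'
#' @param x A `psa_result`.
#' @param frontier Plot the frontier version (probabilities summing to 1
#'   across strategies) instead of the pairwise-versus-no-screening curves.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.psa_result <- function(x, frontier = FALSE, ...) {
  d <- if (frontier) x$frontier else x$ceac
  wide <- stats::reshape(d, idvar = "wtp", timevar = "strategy",
                         direction = "wide")
  graphics::matplot(wide$wtp, as.matrix(wide[, -1]), type = "l", lty = 1,
                    xlab = "willingness to pay (GBP/QALY)",
                    ylab = "probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = sub("^probability\\.", "",
                                           names(wide)[-1]),
                   col = seq_len(ncol(wide) - 1), lty = 1, cex = 0.7,
                   bty = "n")
  invisible(x)
}
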