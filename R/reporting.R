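#' Deterministic strategy-grid report
#'
#' Runs every strategy in the grid through the life table with point-estimate
#' parameters and tabulates, one row per strategy: prostate-cancer cases,
#' overdiagnosed cases, prostate-cancer deaths, discounted QALYs and costs,
#' differences versus no screening, the ICER versus no screening, and the
#' cumulative percentage of the population ever eligible for screening by the
#' stop age.
#'
#' @param rates A [rate_table()] carrying population weights.
#' @param strategies List of [strategy()] objects including a no-screening
#'   referent; the default grid is no screening, age-based screening, and
#'   precision screening at 10-year risk thresholds 2% to 10% in 0.5% steps.
#' @param model A [risk_model()].
#' @param effects A [screening_effects()].
#' @param econ An [econ_params()].
#' @return A data.frame of class `strategy_comparison`.
#' @examples
#' \donttest{
#' rates <- generate_rates()
#' cmp <- compare_strategies(rates,
#'   strategies = strategy_grid(thresholds = c(0.02, 0.05, 0.10)))
#' cmp
#' }
#' @export
compare_strategies <- function(rates, strategies = strategy_grid(),
                               model = risk_model(),
                               effects = screening_effects(),
                               econ = econ_params()) {
  kinds <- vapply(strategies, `[[`, character(1), "kind")
  if (!any(kinds == "none")) {
    stop("the strategy grid must include the no-screening referent",
         call. = FALSE)
  }
  rows <- lapply(strategies, function(st) {
    out <- run_scenario(rates, st, model, effects, econ)
    sched <- build_schedule(st, rates, model)
    cum_f <- max(sched$screened_fraction) / max(st$uptake, 1e-12)
    if (st$kind == "none") cum_f <- 0
    data.frame(strategy = format(st), kind = st$kind,
               threshold = if (is.null(st$threshold)) NA_real_ else
                 st$threshold,
               cases = out$cases, overdiagnosed = out$overdiagnosed,
               pc_deaths = out$pc_deaths, qalys = out$qalys,
               costs = out$costs, screens = out$screens,
               biopsies = out$biopsies,
               cumulative_percent_screened = 100 * cum_f)
  })
  tbl <- do.call(rbind, rows)
  ref <- which(tbl$kind == "none")[1]
  tbl$cases_diff <- tbl$cases - tbl$cases[ref]
  tbl$pc_deaths_diff <- tbl$pc_deaths - tbl$pc_deaths[ref]
  tbl$qalys_diff <- tbl$qalys - tbl$qalys[ref]
  tbl$costs_diff <- tbl$costs - tbl$costs[ref]
  tbl$icer_vs_none <- ifelse(seq_len(nrow(tbl)) == ref, NA_real_,
                             tbl$costs_diff / tbl$qalys_diff)
  class(tbl) <- c("strategy_comparison", "data.frame")
  attr(tbl, "referent") <- tbl$strategy[ref]
  tbl
}

#' Default strategy grid
#'
#' No screening, age-based screening, and precision screening at 10-year
#' absolute-risk thresholds from 2% to 10% in 0.5% steps (19 strategies).
#'
#' @param thresholds Precision thresholds to include.
#' @param ... Passed to every [strategy()] (e.g. `start_age`, `uptake`).
#' @return A list of [strategy()] objects.
#' @export
strategy_grid <- function(thresholds = seq(0.02, 0.10, by = 0.005), ...) {
  c(list(strategy("none"), strategy("age_based", ...)),
    lapply(thresholds, function(t) strategy("precision", threshold = t, ...)))
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("Strategy comparison vs", attr(x, "referent"), "\n")
  show <- data.frame(
    strategy = x$strategy,
    cases = round(x$cases), overdx = round(x$overdiagnosed),
    pc_deaths = round(x$pc_deaths),
    d_qalys = round(x$qalys_diff),
    d_cost_M = round(x$costs_diff / 1e6),
    icer = round(x$icer_vs_none),
    pct_screened = round(x$cumulative_percent_screened, 1))
  print(show, row.names = FALSE)
  invisible(x)
}

#' Benefit-harm summary of a strategy comparison
#'
#' Derives, for every screening strategy in an outcome table, the deaths
#' averted versus no screening, overdiagnoses per death averted, the
#' percentage reduction in overdiagnosis versus age-based screening, and the
#' shortfall in deaths averted versus age-based screening expressed as the
#' percentage increase in prostate-cancer deaths relative to the age-based
#' count. Works on any table with columns `strategy`, `cases`,
#' `overdiagnosed`, `pc_deaths` (and optionally `qalys`) containing a
#' no-screening and an age-based row, including published outcome tables.
#'
#' @param tbl A `strategy_comparison` or compatible data.frame.
#' @param cohort_size Cohort size used for QALYs-per-10,000-men (default
#'   4,480,000).
#' @return A data.frame with one row per screening strategy.
#' @export
benefit_harm <- function(tbl, cohort_size = 4480000) {
  need <- c("strategy", "cases", "overdiagnosed", "pc_deaths")
  stopifnot(all(need %in% names(tbl)))
  ref <- grep("no.?screening|^none$", tbl$strategy, ignore.case = TRUE)[1]
  agb <- grep("age.?based", tbl$strategy, ignore.case = TRUE)[1]
  if (is.na(ref) || is.na(agb)) {
    stop("table must contain a no-screening and an age-based row",
         call. = FALSE)
  }
  averted <- tbl$pc_deaths[ref] - tbl$pc_deaths
  out <- data.frame(
    strategy = tbl$strategy,
    deaths_averted = averted,
    overdiagnosed = tbl$overdiagnosed,
    overdiagnoses_per_death_averted = tbl$overdiagnosed / averted,
    overdiagnosis_reduction_vs_age_pct =
      100 * (tbl$overdiagnosed[agb] - tbl$overdiagnosed) /
      tbl$overdiagnosed[agb],
    deaths_averted_shortfall_vs_age_pct =
      100 * (tbl$pc_deaths - tbl$pc_deaths[agb]) / tbl$pc_deaths[agb])
  if ("qalys" %in% names(tbl)) {
    out$qalys_gained_per_10k_men <-
      (tbl$qalys - tbl$qalys[ref]) / cohort_size * 1e4
  }
  out[-ref, , drop = FALSE]
}

#' Published reference outcomes for the UK screening cohort
#'
#' Published deterministic outcome table for a cohort of 4.48 million men
#' aged 55--69 in England followed to age 90 under no screening, age-based
#' screening, and precision screening at 10-year risk thresholds 2--10%:
#' cases, overdiagnoses, prostate-cancer deaths, QALYs, costs (millions GBP),
#' ICERs versus no screening, and cumulative percentage screened. Bundled as
#' a benchmark input for benefit-harm arithmetic; the package's own life
#' table does not reproduce these absolute counts because the underlying
#' national rate inputs are not redistributable.
#'
#' @return A data.frame with one row per published strategy.
#' @export
reference_outcomes <- function() {
  path <- system.file("extdata", "reference-strategy-outcomes.csv",
                      package = "polyscreen", mustWork = TRUE)
  utils::read.csv(path, check.names = TRUE)
}

#' Default model configuration
#'
#' The full configuration tree with every parameter at its default, suitable
#' for serialising to YAML, editing, and feeding back through
#' [read_config()].
#'
#' @return A nested list with components `risk_model`, `strategy`, `effects`,
#'   `economics`, `synth` and `psa`.
#' @export
default_config <- function() {
  econ <- econ_params()
  eff <- screening_effects()
  st <- strategy("age_based")
  list(
    risk_model = list(variance = 0.68),
    strategy = st[c("kind", "start_age", "stop_age", "interval", "psa_cutoff",
                    "uptake")],
    effects = eff[c("rr_mortality", "rr_incidence", "rr_advanced",
                    "overdiagnosis_intercept", "overdiagnosis_slope",
                    "opportunistic_fraction", "screen_detected")],
    economics = c(econ[c("base_utility", "utility_decline",
                         "utility_anchor_age", "pc_utility_multiplier",
                         "pc_utility_years", "discount_rate", "wtp",
                         "advanced_share", "biopsy_compliance")],
                  list(costs = econ$costs)),
    synth = unclass(synth_config())[c("seed", "age_min", "age_max",
                                      "gompertz_level", "gompertz_slope",
                                      "incidence_midpoint", "incidence_scale",
                                      "mortality_fraction", "mortality_lag",
                                      "cohort_size", "entry_min",
                                      "entry_max")],
    psa = list(draws = 10000, seed = 42)
  )
}

modify_defaults <- function(base, new) {
  for (nm in names(new)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]])) {
      modify_defaults(base[[nm]], new[[nm]])
    } else new[[nm]]
  }
  base
}

#' Read / write a model configuration as YAML
#'
#' `read_config()` loads a YAML file and merges it over [default_config()],
#' so a config file only needs to state departures from the defaults.
#'
#' @param path Path to a YAML file.
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

#' @rdname read_config
#' @param config A configuration list as from [default_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build model objects from a configuration list
#'
#' @param config A configuration list from [read_config()] or
#'   [default_config()].
#' @return A list with `model`, `strategy`, `effects`, `econ` and
#'   `synth` objects.
#' @export
config_objects <- function(config) {
  st <- config$strategy
  list(
    model = risk_model(config$risk_model$variance),
    strategy = strategy(st$kind, start_age = st$start_age,
                        stop_age = st$stop_age, interval = st$interval,
                        psa_cutoff = st$psa_cutoff,
                        threshold = st$threshold, uptake = st$uptake),
    effects = do.call(screening_effects, config$effects),
    econ = do.call(econ_params, config$economics),
    synth = do.call(synth_config, config$synth)
  )
}

#' Write a strategy-comparison report with a reproducibility manifest
#'
#' Writes the comparison table as CSV alongside a JSON manifest recording the
#' seed, the MD5 hash of the configuration, and the package version.
#'
#' @param tbl A `strategy_comparison`.
#' @param dir Output directory (created if missing).
#' @param seed Seed recorded in the manifest.
#' @param config Configuration list recorded (hashed) in the manifest.
#' @param name Base name for the output files.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(tbl, dir, seed = NA_integer_,
                         config = default_config(), name = "table2") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(name, ".csv"))
  utils::write.csv(as.data.frame(tbl), csv, row.names = FALSE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  manifest <- list(
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    package_version = as.character(utils::packageVersion("polyscreen")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  json <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, json, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv = csv, manifest = json))
}
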