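#' Configuration for the synthetic rate-table generator
#'
#' Describes a stylised male population with the statistical structure the
#' life table assumes: Gompertz (exponentially rising) other-cause mortality,
#' prostate-cancer incidence rising with age towards a plateau (logistic in
#' age), and prostate-cancer mortality proportional to the incidence hazard a
#' fixed lag earlier — cancer deaths trail diagnoses. The incidence plateau is
#' calibrated so the background 10-year absolute risk at `anchor_age` equals
#' `anchor_risk`; a second anchor at `check_age` is verified, not fitted.
#'
#' @param seed Integer seed; the generator is deterministic given the config.
#' @param age_min,age_max Age range of the table (attained years).
#' @param gompertz_level Other-cause mortality hazard at `age_min` (per
#'   person-year).
#' @param gompertz_slope Log-hazard increase per year of age.
#' @param incidence_midpoint,incidence_scale Logistic midpoint (years) and
#'   scale (years) of the incidence curve.
#' @param incidence_plateau Upper asymptote of the incidence hazard; `NA`
#'   (default) means "calibrate to the age-55 anchor".
#' @param mortality_fraction Prostate-cancer mortality hazard as a fraction of
#'   the lagged incidence hazard.
#' @param mortality_lag Years by which the mortality hazard trails incidence.
#' @param cohort_size Total men entering the cohort (spread over the entry
#'   ages).
#' @param entry_min,entry_max Entry-age window carrying population weights.
#' @param anchor_age,anchor_risk Calibration anchor for the 10-year absolute
#'   risk (defaults: 2.6% at age 55).
#' @param check_age,check_risk,check_tol Verification anchor (defaults: 7.1%
#'   at age 69, tolerance 0.005 absolute).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         age_min = 45L, age_max = 90L,
                         gompertz_level = 0.0025,
                         gompertz_slope = 0.085,
                         incidence_midpoint = 71,
                         incidence_scale = 8,
                         incidence_plateau = NA_real_,
                         mortality_fraction = 0.45,
                         mortality_lag = 8L,
                         cohort_size = 4480000,
                         entry_min = 55L, entry_max = 69L,
                         anchor_age = 55L, anchor_risk = 0.026,
                         check_age = 69L, check_risk = 0.071,
                         check_tol = 0.005) {
  cfg <- as.list(environment())
  stopifnot(age_min < age_max, entry_min <= entry_max,
            entry_min >= age_min, entry_max <= age_max,
            gompertz_level >= 0, mortality_fraction >= 0, cohort_size >= 0)
  structure(cfg, class = "synth_config")
}

logistic_hazard <- function(age, plateau, midpoint, scale) {
  plateau / (1 + exp(-(age - midpoint) / scale))
}

build_synth_table <- function(cfg, plateau) {
  age <- seq(cfg$age_min, cfg$age_max)
  h_oth <- cfg$gompertz_level * exp(cfg$gompertz_slope * (age - cfg$age_min))
  h_inc <- logistic_hazard(age, plateau, cfg$incidence_midpoint,
                           cfg$incidence_scale)
  # PC mortality trails incidence by the lag; before the lag window use the
  # earliest available incidence so the hazard stays positive and small
  lagged <- logistic_hazard(pmax(age - cfg$mortality_lag, cfg$age_min),
                            plateau, cfg$incidence_midpoint,
                            cfg$incidence_scale)
  h_pcm <- cfg$mortality_fraction * lagged
  w <- numeric(length(age))
  entry <- age >= cfg$entry_min & age <= cfg$entry_max
  # mildly decreasing population by single year of age, as in a real pyramid
  shape <- exp(-0.01 * (age[entry] - cfg$entry_min))
  w[entry] <- cfg$cohort_size * shape / sum(shape)
  rate_table(age, h_inc, h_pcm, h_oth, w)
}

#' Generate a synthetic rate table
#'
#' Builds a [rate_table()] from a [synth_config()], calibrating the incidence
#' plateau by bisection so the background 10-year absolute risk at the anchor
#' age matches the anchor value (default 2.6% at 55), then verifying — not
#' fitting — the second anchor (default 7.1% at 69). The table is entirely
#' synthetic: it reproduces the qualitative age structure of registry rates,
#' not any registry's numbers.
#'
#' @param config A [synth_config()] (default configuration if omitted).
#' @return A calibrated [rate_table()].
#' @examples
#' rates <- generate_rates()
#' ten_year_absolute_risk(rates, c(55, 69))
#' @export
generate_rates <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  if (is.na(config$incidence_plateau)) {
    target <- config$anchor_risk
    f <- function(p) {
      ten_year_absolute_risk(build_synth_table(config, p),
                             config$anchor_age) - target
    }
    lo <- 0
    hi <- 0.5
    if (f(hi) < 0) {
      stop("calibration infeasible: anchor 10-year risk ", target,
           " at age ", config$anchor_age,
           " unreachable with incidence plateau <= 0.5", call. = FALSE)
    }
    plateau <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    rates <- build_synth_table(config, plateau)
    chk <- ten_year_absolute_risk(rates, config$check_age)
    if (abs(chk - config$check_risk) > config$check_tol) {
      stop(sprintf(paste0("calibration check failed: 10-year risk at age %d ",
                          "is %.4f, outside %.4f +/- %.4f"),
                   config$check_age, chk, config$check_risk, config$check_tol),
           call. = FALSE)
    }
  } else {
    plateau <- config$incidence_plateau
    rates <- build_synth_table(config, plateau)
  }
  attr(rates, "incidence_plateau") <- plateau
  rates
}

#' Synthetic stage-by-treatment shares
#'
#' Plausible shares of primary treatment by stage at diagnosis: early-stage
#' mass on active surveillance, prostatectomy, radiotherapy and brachytherapy;
#' advanced-stage mass on androgen deprivation, chemotherapy and radiotherapy.
#' Rows sum to 1. These shares are synthetic placeholders with the right
#' structure, not audit data.
#'
#' @param config A [synth_config()]; the seed perturbs the shares slightly so
#'   tests can exercise renormalisation.
#' @param perturb Standard deviation of the log-scale perturbation (0 = the
#'   fixed default mix).
#' @return A matrix with rows `early`, `advanced` and one column per
#'   treatment.
#' @export
generate_treatment_mix <- function(config = synth_config(), perturb = 0) {
  treatments <- c("active_surveillance", "prostatectomy", "radiotherapy",
                  "brachytherapy", "chemotherapy", "adt")
  early <- c(0.35, 0.30, 0.25, 0.10, 0, 0)
  advanced <- c(0, 0.05, 0.30, 0, 0.25, 0.40)
  mix <- rbind(early = early, advanced = advanced)
  colnames(mix) <- treatments
  if (perturb > 0) {
    set.seed(config$seed)
    noise <- matrix(exp(stats::rnorm(length(mix), 0, perturb)), nrow = 2)
    mix <- mix * noise
  }
  sweep(mix, 1, rowSums(mix), "/")
}

#' Synthetic per-screen biopsy-referral probability
#'
#' Probability that a screening PSA test meets the referral cutoff, by age.
#' The default is flat at 0.12 across ages — a synthetic placeholder, since
#' observed age-specific positivity is not bundled with the package.
#'
#' @param config A [synth_config()].
#' @param level Flat positivity level.
#' @return A data.frame with columns `age` and `positivity`.
#' @export
generate_biopsy_positivity <- function(config = synth_config(), level = 0.12) {
  data.frame(age = seq(config$age_min, config$age_max), positivity = level)
}
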