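#' Health-economic parameters
#'
#' Utilities, unit costs and discounting for the screening model, from the
#' perspective of the health system in 2016 GBP. Utilities decline linearly
#' with age from an anchor at 55; men within 10 years of a prostate-cancer
#' diagnosis carry a multiplicative utility decrement. Diagnosis-related costs
#' (staging plus a stage-weighted treatment mix) are charged as a lump sum in
#' the diagnosis year, palliation in the year of prostate-cancer death, and
#' both costs and QALYs are discounted from cohort entry at 3.5% per year.
#'
#' @param base_utility General-population utility at the anchor age
#'   (default 0.8639).
#' @param utility_decline Utility lost per year of age (default 0.0048).
#' @param utility_anchor_age Age at which `base_utility` applies (default 55).
#' @param pc_utility_multiplier Relative utility for men within
#'   `pc_utility_years` of a prostate-cancer diagnosis (default 0.93).
#' @param pc_utility_years Duration of the post-diagnosis decrement
#'   (default 10).
#' @param discount_rate Annual discount rate for costs and benefits
#'   (default 0.035).
#' @param wtp Willingness-to-pay thresholds, GBP per QALY (defaults 20,000
#'   and 30,000).
#' @param costs Named list of unit costs in 2016 GBP: `psa_test` 11,
#'   `genotyping` 25, `biopsy` 388, `declined_biopsy` 105, `staging` 770,
#'   `active_surveillance` 4341, `prostatectomy` 8173, `radiotherapy` 5385,
#'   `brachytherapy` 1527, `chemotherapy` 7426, `adt` 559, `palliation` 6837.
#' @param treatment_mix Stage-by-treatment share matrix (rows `early`,
#'   `advanced`, summing to 1; default [generate_treatment_mix()]).
#' @param advanced_share Share of clinically detected cancers that are
#'   advanced stage (synthetic default 0.25; screen-detected cancers get this
#'   share multiplied by the `rr_advanced` screening effect).
#' @param biopsy_compliance Fraction of referred men accepting biopsy
#'   (default 1; decliners incur the `declined_biopsy` cost instead).
#' @return A list of class `econ_params`.
#' @export
econ_params <- function(base_utility = 0.8639,
                        utility_decline = 0.0048,
                        utility_anchor_age = 55,
                        pc_utility_multiplier = 0.93,
                        pc_utility_years = 10,
                        discount_rate = 0.035,
                        wtp = c(20000, 30000),
                        costs = list(
                          psa_test = 11, genotyping = 25, biopsy = 388,
                          declined_biopsy = 105, staging = 770,
                          active_surveillance = 4341, prostatectomy = 8173,
                          radiotherapy = 5385, brachytherapy = 1527,
                          chemotherapy = 7426, adt = 559, palliation = 6837),
                        treatment_mix = generate_treatment_mix(),
                        advanced_share = 0.25,
                        biopsy_compliance = 1) {
  stopifnot(base_utility >= 0, base_utility <= 1,
            pc_utility_multiplier >= 0, pc_utility_multiplier <= 1,
            discount_rate >= 0, all(wtp >= 0),
            all(unlist(costs) >= 0),
            advanced_share >= 0, advanced_share <= 1,
            biopsy_compliance >= 0, biopsy_compliance <= 1)
  if (any(abs(rowSums(treatment_mix) - 1) > 1e-9)) {
    stop("treatment mix rows must each sum to 1", call. = FALSE)
  }
  miss <- setdiff(colnames(treatment_mix), names(costs))
  if (length(miss)) {
    stop("no unit cost for treatment(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(as.list(environment()), class = "econ_params")
}

#' General-population utility at an age
#'
#' `max(0, base_utility - utility_decline * (age - anchor))`, multiplied by
#' the prostate-cancer decrement when `pc_diagnosed` is `TRUE`.
#'
#' @param params An [econ_params()].
#' @param age Attained age(s).
#' @param pc_diagnosed Whether the man is within the post-diagnosis decrement
#'   window.
#' @return Utility value(s) in \[0, 1\].
#' @export
utility_at <- function(params, age, pc_diagnosed = FALSE) {
  u <- pmax(0, params$base_utility -
              params$utility_decline * (age - params$utility_anchor_age))
  if (pc_diagnosed) u <- u * params$pc_utility_multiplier
  u
}

#' Discount factor
#'
#' `(1 + discount_rate)^(-years_since_entry)`; equals 1 at entry.
#'
#' @param params An [econ_params()].
#' @param years_since_entry Years since cohort entry (>= 0).
#' @return Dimensionless factor(s) in (0, 1\].
#' @export
discount_factor <- function(params, years_since_entry) {
  stopifnot(all(years_since_entry >= 0))
  (1 + params$discount_rate)^(-years_since_entry)
}

stage_costs <- function(params) {
  mix <- params$treatment_mix
  uc <- unlist(params$costs)[colnames(mix)]
  as.numeric(mix %*% uc)  # early, advanced
}

#' Per-age discounted cost stream for a scenario outcome
#'
#' Prices a single-entry-age outcome: PSA tests, one-off genotyping,
#' the biopsy cascade (all referred men biopsied, or a `declined_biopsy`
#' appointment for non-compliers), staging plus a stage-mix treatment lump
#' sum per diagnosed case (screen-detected cases get an advanced-stage share
#' shifted by `rr_advanced`; overdiagnosed cases are costed like other
#' screen-detected cases), and palliation per prostate-cancer death.
#'
#' @param outcome A single-cohort `scenario_outcome` from [run_cohort()].
#' @param params An [econ_params()].
#' @param rr_advanced Stage-shift relative risk applied to screen-detected
#'   cases (default 0.85, matching [screening_effects()]).
#' @return A data.frame with columns `age`, `cost` (undiscounted) and
#'   `cost_discounted`.
#' @export
cost_trajectory <- function(outcome, params, rr_advanced = 0.85) {
  tr <- outcome$trajectories
  entry <- outcome$entry_age
  if (length(entry) != 1L) {
    stop("cost_trajectory needs a single-entry-age outcome; price each ",
         "sub-cohort before combining", call. = FALSE)
  }
  sc <- stage_costs(params)
  adv_clin <- params$advanced_share
  adv_sd <- min(adv_clin * rr_advanced, 1)
  case_cost_clin <- params$costs$staging + adv_clin * sc[2] +
    (1 - adv_clin) * sc[1]
  case_cost_sd <- params$costs$staging + adv_sd * sc[2] + (1 - adv_sd) * sc[1]
  comp <- params$biopsy_compliance
  biopsy_unit <- comp * params$costs$biopsy +
    (1 - comp) * params$costs$declined_biopsy
  cost <- tr$screens * params$costs$psa_test +
    tr$genotyped * params$costs$genotyping +
    (tr$positives + tr$clinical) * biopsy_unit +
    tr$screen_detected * case_cost_sd +
    tr$clinical * case_cost_clin +
    tr$pc_deaths * params$costs$palliation
  disc <- discount_factor(params, tr$age - entry)
  data.frame(age = tr$age, cost = cost, cost_discounted = cost * disc)
}

#' Per-age QALY stream for a scenario outcome
#'
#' Person-years alive weighted by the age-specific utility, with the
#' prostate-cancer multiplier applied to men within the post-diagnosis
#' window (overdiagnosed men included).
#'
#' @inheritParams cost_trajectory
#' @return A data.frame with columns `age`, `qaly` and `qaly_discounted`.
#' @export
qaly_trajectory <- function(outcome, params) {
  tr <- outcome$trajectories
  entry <- outcome$entry_age
  if (length(entry) != 1L) {
    stop("qaly_trajectory needs a single-entry-age outcome", call. = FALSE)
  }
  u <- utility_at(params, tr$age)
  recent <- pmin(tr$recent_dx, tr$alive)
  q <- u * (tr$alive - (1 - params$pc_utility_multiplier) * recent)
  disc <- discount_factor(params, tr$age - entry)
  data.frame(age = tr$age, qaly = q, qaly_discounted = q * disc)
}

attach_economics <- function(outcome, params, rr_advanced = 0.85) {
  ct <- cost_trajectory(outcome, params, rr_advanced)
  qt <- qaly_trajectory(outcome, params)
  outcome$costs <- sum(ct$cost_discounted)
  outcome$costs_undiscounted <- sum(ct$cost)
  outcome$qalys <- sum(qt$qaly_discounted)
  outcome$qalys_undiscounted <- sum(qt$qaly)
  outcome$trajectories$cost_discounted <- ct$cost_discounted
  outcome$trajectories$qaly_discounted <- qt$qaly_discounted
  outcome
}

#' Incremental cost-effectiveness ratio
#'
#' Difference in mean costs divided by difference in mean QALYs between two
#' strategies. The ratio alone does not distinguish dominance; inspect the
#' signs of the increments (a negative `delta_cost` with positive
#' `delta_qaly` means the comparator is dominated).
#'
#' @param delta_cost Incremental cost (currency).
#' @param delta_qaly Incremental QALYs.
#' @return Cost per QALY gained.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (any(delta_qaly == 0)) {
    stop("undefined ICER: zero QALY difference between strategies",
         call. = FALSE)
  }
  delta_cost / delta_qaly
}

#' Net monetary benefit
#'
#' `qalys * wtp - cost`.
#'
#' @param qalys QALYs (absolute or incremental).
#' @param cost Cost on the same footing as `qalys`.
#' @param wtp Willingness to pay per QALY.
#' @return Net monetary benefit in currency units.
#' @export
nmb <- function(qalys, cost, wtp) {
  stopifnot(all(wtp >= 0))
  qalys * wtp - cost
}
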