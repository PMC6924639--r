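# Shared fixtures, built in code.

# Flat-hazard table over a given age span; weight the whole cohort at entry.
flat_table <- function(ages, h_inc = 0, h_pcm = 0, h_oth = 0,
                       entry = ages[1], cohort = 1) {
  w <- ifelse(ages == entry, cohort, 0)
  rate_table(ages, rep(h_inc, length(ages)), rep(h_pcm, length(ages)),
             rep(h_oth, length(ages)), w)
}

# Small 5-age toy table with age-varying hazards for oracle comparisons.
toy_table5 <- function(entry = 85, cohort = 1) {
  ages <- 85:90
  rate_table(ages,
             pc_incidence = c(0.020, 0.024, 0.028, 0.032, 0.036, 0.040),
             pc_mortality = c(0.008, 0.009, 0.010, 0.011, 0.012, 0.013),
             other_mortality = c(0.050, 0.060, 0.070, 0.080, 0.090, 0.100),
             population_weight = ifelse(ages == entry, cohort, 0))
}

# Per-individual Monte-Carlo oracle for the unscreened annual-cycle process:
# each year a healthy man is diagnosed with probability h_inc; prostate-cancer
# deaths occur among the diagnosed at the per-diagnosed hazard implied by the
# population rate (alive * h_pcm deaths spread over the diagnosed pool); every
# survivor then faces other-cause death h_oth. Independent of the life-table
# implementation.
mc_unscreened <- function(rates, entry, n_men, end_age = 90, seed = 1,
                          opportunistic = 0.10) {
  set.seed(seed)
  ages <- entry:(end_age - 1L)
  healthy <- rep(TRUE, n_men)
  alive <- rep(TRUE, n_men)
  cases <- 0
  pc_deaths <- 0
  for (a in ages) {
    i <- match(a, rates$age)
    hi <- rates$pc_incidence[i] * (1 - opportunistic)
    hp <- rates$pc_mortality[i]
    ho <- rates$other_mortality[i]
    dx <- alive & healthy & (stats::runif(n_men) < hi)
    cases <- cases + sum(dx)
    healthy[dx] <- FALSE
    ndx <- sum(alive & !healthy)
    if (ndx > 0) {
      p_case <- min(sum(alive) * hp / ndx, 1)
      pcd <- alive & !healthy & (stats::runif(n_men) < p_case)
      pc_deaths <- pc_deaths + sum(pcd)
      alive[pcd] <- FALSE
    }
    od <- alive & (stats::runif(n_men) < ho)
    alive[od] <- FALSE
  }
  list(cases = cases, pc_deaths = pc_deaths, n = n_men)
}

# Independent spreadsheet-style recomputation of the unscreened life table:
# survival products only, no stratum machinery. Valid while the diagnosed
# pool covers the prostate-cancer death toll (true for these fixtures).
spreadsheet_unscreened <- function(rates, entry, cohort, end_age = 90,
                                   opportunistic = 0.10) {
  ages <- entry:(end_age - 1L)
  alive <- cohort
  healthy <- cohort
  cases <- 0; pcd <- 0; othd <- 0; ly <- 0
  for (a in ages) {
    i <- match(a, rates$age)
    hi <- rates$pc_incidence[i] * (1 - opportunistic)
    hp <- rates$pc_mortality[i]
    ho <- rates$other_mortality[i]
    ly <- ly + alive
    new_cases <- healthy * hi
    cases <- cases + new_cases
    d_pc <- alive * hp          # drawn from the diagnosed pool
    pcd <- pcd + d_pc
    d_ot <- (alive - d_pc) * ho
    othd <- othd + d_ot
    alive <- alive - d_pc - d_ot
    healthy <- (healthy - new_cases) * (1 - ho)
  }
  list(cases = cases, pc_deaths = pcd, other_deaths = othd, life_years = ly)
}
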