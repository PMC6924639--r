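---
title: "Modelling polygenic risk-tailored prostate cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polygenic risk-tailored prostate cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyscreen)
```

polyscreen estimates the benefits (prostate-cancer deaths averted,
quality-adjusted life-years), harms (overdiagnosed cancers, biopsies) and
costs of three prostate-cancer screening policies for a cohort of men aged
55–69 followed to age 90: no organised screening, age-based screening (a PSA
test every 4 years from 55 to 69 for everyone), and precision screening,
where each man starts quadrennial PSA testing at the age his individual
10-year absolute risk — background risk times his polygenic relative risk —
first crosses a chosen threshold. This vignette records the model, its
assumptions, and the numerical and design choices behind the implementation.

## The polygenic relative-risk distribution

Common susceptibility variants jointly imply a distribution of relative risk
$r$ across the population. On the log scale this is Normal:
$\log r \sim N(\mu, \sigma^2)$ with $\sigma^2 = 0.68$ by default and
$\mu = -\sigma^2/2$, so that $E[r] = 1$: stratifying the population by
polygenic risk redistributes cases but leaves total incidence unchanged.
Three consequences drive everything else:

* **Case enrichment.** Among men who develop the disease, $\log r$ follows
  the size-biased distribution $N(\mu + \sigma^2, \sigma^2)$. The share of
  all cases above the population $q$-th percentile is
  $\Phi(\sigma - z_q)$ — about 49% of cases arise in the top 20% of the
  distribution.
* **Eligibility.** Modelling individual 10-year risk as
  $b \times r$ for background risk $b$, the fraction of the population at or
  above threshold $t$ is $\Phi\big((\mu - \log(t/b))/\sigma\big)$. With the
  published background risks (2.6% at 55, 7.1% at 69), a 5% threshold admits
  11.4% of 55-year-olds and 50.5% of 69-year-olds.
* **Stratum relative risks.** If a fraction $f$ (the top of the
  distribution) is screened and a fraction $C$ of cases arises there, the
  screened and unscreened strata have mean relative risks $C/f$ and
  $(1-C)/(1-f)$, satisfying $f \cdot RR_s + (1-f) \cdot RR_u = 1$.

Production code uses these closed forms; the tests check them against
adaptive quadrature of the density (absolute tolerance $10^{-10}$) and
weighted Monte-Carlo sampling. One known caveat: published first/99th
percentile relative risks of 0.09 and 5.52, and the "7% of cases in the
bottom 20%", derive from an empirical SNP distribution and do not follow
from the pure log-normal model (which gives 0.105, 4.85 and 4.8%). We make
no attempt to force agreement; the log-normal with variance 0.68 is the
model everywhere.

Individual absolute risk is assumed to scale linearly in $r$
($\text{risk} = b \times r$), ignoring competing-risk nonlinearity at the
individual level; competing risks are handled at the stratum level by the
life table. This choice reproduces the published eligibility fractions
exactly from the published background risks.

## The cohort life table

The life table is an annual-cycle, multi-state cohort model. The mixed-age
cohort (default 4.48 million men, a population snapshot aged 55–69) is run
as 15 single-entry-age sub-cohorts weighted by population, each followed to
age 90 and summed. Inputs are a rate table of age-specific hazards per
person-year: prostate-cancer incidence, prostate-cancer mortality and
other-cause mortality, in 1-year attained-age bands.

Within a cycle, transitions occur in a fixed order: stratum migration
(newly eligible men join the ever-screened stratum), screening tests,
incidence, prostate-cancer death, other-cause death. There is no half-cycle
correction; life-years count men alive at the start of the cycle and deaths
fall at year end. This is the simplest auditable convention, and the tests
pin it down against an independent spreadsheet-style recomputation and a
per-individual Monte-Carlo simulation of the same process
($10^5$ men, agreement within 3 Monte-Carlo standard errors).

Key structural assumptions:

* **Opportunistic testing.** Registry incidence already contains cancers
  detected by ad-hoc PSA testing. Background *clinical* incidence is
  registry incidence × 0.90, and screening effects multiply this adjusted
  baseline, in every scenario.
* **Screening effects.** While actively screened, incidence in the screened
  stratum is inflated by RR 1.23 (lead time plus overdiagnosis).
  Ever-screened men retain a prostate-cancer mortality RR of 0.79 with no
  onset lag, persisting after screening stops at 69. Screen-detected cancers
  are advanced-stage at 0.85 times the clinical rate (this feeds only the
  treatment-mix costing).
* **Risk-dependent mortality.** The prostate-cancer mortality hazard is
  scaled by the polygenic stratum RR as well as by the screening RR:
  mortality follows incidence risk. Without this, screening a high-risk
  minority could not capture a proportionate share of preventable deaths.
* **Conservation by renormalisation.** Stratum hazards are renormalised
  every cycle by $\lambda = N / \sum_s N_s RR_s$ (over healthy pools for
  incidence, over alive pools for mortality). The stratum RRs come from the
  static population distribution; as high-risk men are diagnosed or die
  faster, the raw hazards would otherwise create events a homogeneous
  cohort would not have — a frailty artifact of order 2% over 35 years that
  would contaminate every incremental comparison. With renormalisation,
  setting all screening effects to neutral makes every strategy's case and
  death counts identical to machine precision, which the tests assert.
* **Overdiagnosis.** The proportion of screen-detected cases overdiagnosed
  is linear in age, $-0.62 + 0.014 \times \text{age}$ clamped to $[0,1]$
  (0.15 at 55, 0.346 at 69). "Screen-detected" defaults to all incident
  cases in the actively screened stratum during screening ages — the
  broadest internally consistent reading — with an `excess_incidence`
  alternative (only the incidence excess over the unscreened level) exposed
  as a switch on `screening_effects()`. Overdiagnosed men never die of
  prostate cancer but keep the post-diagnosis utility decrement and the
  full diagnosis and treatment costs.
* **Prostate-cancer deaths** are generated by the population-level mortality
  rate and drawn from the diagnosed pool (falling back to the healthy pool
  only if the diagnosed pool is exhausted, which does not occur under any
  table used here).

The schedule translates a strategy into per-age columns. For precision
screening the eligible fraction at each age is forced non-decreasing (a man
who crosses the threshold stays eligible), and the screened stratum at age
$a$ is treated as the top $f(a)$ of the risk distribution, so its RR comes
from the case distribution over that upper tail; this is where the nested
structure of eligible sets (the threshold on $r$ falls as background risk
rises) makes per-crossing-age bookkeeping unnecessary. Screening uptake
below 1 dilutes attendance but not the stratum's risk profile, since
non-attendance is assumed independent of risk. Sub-cohorts entering above
the start age inherit the global screening phase (screens at
$\text{start} + k \times \text{interval}$); screens dated before a man's
entry do not occur. Per-entry phasing is below the model's resolution.

## Economics

Utilities decline linearly with age from 0.8639 at 55 by 0.0048 per year;
men within 10 years of diagnosis (overdiagnosed included) carry a
multiplicative decrement of 0.93. Unit costs are 2016 GBP: PSA test 11,
genotyping 25 (charged once per man in precision arms — the whole cohort
must be genotyped to assess risk, at the first decision age), biopsy 388
(every screen positive at the default flat 12% positivity, plus one per
clinically detected case), staging 770, stage-mix treatment lump sum in the
diagnosis year (the published costs already bundle 5–10 years of
follow-up), palliation 6,837 per prostate-cancer death. Costs and QALYs are
discounted at 3.5% per year from each sub-cohort's entry, end-of-year
convention. A declined-biopsy path (105 per decliner) activates only when
`biopsy_compliance < 1`.

Two cost inputs have no published values in the main text and are synthetic
placeholders, clearly labelled: the flat 12% biopsy positivity and the
stage-by-treatment shares (early-stage mass on surveillance, prostatectomy,
radiotherapy, brachytherapy; advanced-stage mass on ADT, chemotherapy,
radiotherapy; clinical advanced-stage share 0.25). Overdiagnosed cases
receive the screen-detected (early-shifted) stage mix, the less arbitrary of
the two candidate conventions since they are by construction
screen-detected.

ICERs divide the difference in mean costs by the difference in mean QALYs;
net monetary benefit is QALYs × willingness-to-pay − cost. The two are
asserted to classify cost-effectiveness identically for any pair of
strategies.

## Probabilistic sensitivity analysis

Every uncertain parameter is drawn from its assigned distribution: the three
screening RRs log-normally around their point estimates with log-SEs 0.06,
0.18 and 0.07; unit costs from Gamma(shape, scale) pairs; the general
utility as $0.83 + \Gamma(4, 0.06) \times 0.167$ and the prostate-cancer
multiplier as $0.88 + \Gamma(5, 0.05) \times 0.2$ clamped at 1; and the
overdiagnosis proportion perturbed multiplicatively by a Beta variable
moment-matched to mean 1 with SD 0.001 at the cohort's central age. Two
published inconsistencies are retained verbatim rather than re-fitted and
simply documented: several Gamma means sit ~7% below the printed point
costs (e.g. the PSA test: $33.9 \times 0.3 = 10.17$ against a printed 11),
and the incidence-RR log-SE of 0.18 implies a wider 95% interval
(0.86–1.75) than the printed confidence interval (1.03–1.48).

One draw is one coherent parameter set reused across all strategies (common
random numbers), so incrementals are within-draw differences — standard
practice for variance reduction in cost-effectiveness analysis. Summaries
are percentile-based 95% uncertainty intervals, ICERs from mean increments,
the pairwise probability of cost-effectiveness against no screening (which
need not sum to 1 across strategies), and a frontier CEAC (probability of
having the highest NMB, which does sum to 1). A fixed seed makes all
summaries bit-identical across runs; any failing draw aborts with its index.
The default is 10,000 draws; the test suite exercises the full 19-strategy
grid at 2,000 draws, which completes in a few minutes on one CPU, and the
convergence of mean incremental QALYs is checked against its own
Monte-Carlo standard error.

## Synthetic rate tables

No national rate table ships with the package, so a generator produces one
with the structure the model assumes: Gompertz other-cause mortality
($2.5 \times 10^{-3}$ at age 45, log-slope 0.085/year — roughly 0.6% at 55
rising to 7.5% at 85), prostate-cancer incidence logistic in age (midpoint
71, scale 8 years, rising to a plateau), and prostate-cancer mortality at
0.45 times the incidence hazard lagged 8 years, giving lifetime
deaths-per-case around 0.34, realistic for a pre-screening-era UK cohort.
The incidence plateau is the one free parameter, calibrated by bisection so
the background 10-year risk at 55 equals 2.6%; the 7.1% anchor at 69 is then
*checked* (the default lands at 6.8%, within the ±0.005 acceptance window),
never fitted. Population weights decline mildly with entry age and sum to
4.48 million.

What passing tests on synthetic tables do show: the mechanics — competing
risks, conservation, stratification, limit equivalences, discounting — are
correct. What they do not show: agreement with published absolute counts
(cases, deaths, ICERs), which depend on the actual national rates; with the
synthetic table the model's ICERs are several-fold lower than published
because the synthetic cohort accrues more preventable deaths per pound.
Users with access to real registry rates can supply them as a CSV and every
downstream number flows unchanged.

## Numerical choices and degenerate inputs

* Closed forms (`pnorm`/`qnorm`) in all production risk-distribution paths;
  quadrature only as a test oracle.
* Calibration bisection tolerance $10^{-12}$ on the plateau; an infeasible
  anchor fails with the violated anchor named.
* Eligible fractions numerically 0 or 1 short-circuit to RR 1 (tolerance
  $10^{-12}$); `stratum_relative_risks` refuses degenerate strata with an
  explicit error.
* A threshold of 1 (an impossible 10-year risk) is allowed and collapses
  precision screening onto no screening; a vanishing threshold collapses it
  onto age-based screening. Both limits are asserted in the tests.
* The overdiagnosis proportion is clamped to $[0,1]$ after the linear-age
  evaluation and after any probabilistic perturbation.
* All-zero rate tables are valid inputs (a rate-free cohort just ages).

## Known limitations

The model is cohort-based: it carries no natural history (onset to
progression), no PSA-growth dynamics, and no stage-specific survival, so it
cannot vary screening intervals by risk or model lead time explicitly. The
10-year utility decrement is stage-blind. The stratum renormalisation keeps
totals exact but is itself an approximation to full frailty dynamics within
strata. Mortality benefit is assumed independent of polygenic risk beyond
the stratum scaling; if high-risk cancers benefit disproportionately from
screening, precision screening's benefit–harm profile is underestimated
here.
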