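---
title: "Methods: decision-tree cost-effectiveness of short-course antibiotics for VAP"
author: "vapcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree cost-effectiveness of short-course antibiotics for VAP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vapcea)
```

## The decision problem

Ventilator-associated pneumonia (VAP) is treated with antibiotics whose
optimal duration is uncertain. An individualised short-course strategy
(stopping antibiotics once fitness criteria are met, as early as day 3–5)
reduces antibiotic exposure; the economic question is whether adopting it —
versus usual care of at least 8 days — is cost-effective from the health
system perspective in three very different settings: Nepal (low income),
Thailand (middle income), and Singapore (high income).

Because a composite trial endpoint (death or recurrence) is unsuitable for
economic evaluation, the package disaggregates outcomes through a decision
tree and values a death averted in discounted life-years.

## The decision tree

Each country is modelled as a hypothetical cohort of average individuals.
Two strategies enter the tree at VAP diagnosis. The short-course strategy
first passes an **adherence** chance node: with probability
$p_{\text{nonadh}}$ the full short-course regimen is not received and the
patient's disease progression, stay, and costs follow usual-care
parameters. Both strategies then branch on carbapenem-resistant
Gram-negative infection, pneumonia recurrence, and the terminal outcome
(death / discharged alive): 8 pathways for usual care, 16 for short course
(`enumerate_pathways()`).

Two structural decisions were genuinely open:

* **Stratum resolution.** Published inputs exist only at arm × terminal
  outcome resolution, so stays and daily costs are stratified by arm and
  terminal outcome; the carbapenem-resistance and recurrence nodes are
  structural (they partition probability without changing downstream
  parameters) unless stratum-specific estimates are supplied. A
  consequence is that those two probabilities do not move the deterministic
  increments, which is visible in the value-of-information output.
* **Stay models.** Time to death and time to discharge are fitted as
  *separate* Tobit regressions rather than one joint model: the two stay
  distributions have different scales and only the discharge arm is
  materially censored at the 60-day horizon.

Pathway cost is $(\sum_k c_k^{\text{arm}}) \times
\text{stay}(\text{arm}, \text{terminal})$ over the four cost categories
$k$ (bed stay, pharmaceuticals, diagnostics, consumables); pathway effect
is $u \cdot \frac{1 - (1+r)^{-L}}{r}$ discounted life-years for a
discharged-alive terminal node and $0$ for death, with
$L = \text{life expectancy} - \text{mean age}$, annual discount rate
$r = 0.03$ and utility weight $u = 1$ in the base case. Annual-annuity
discounting is used with non-integer $L$ permitted; costs are not
discounted because they accrue within a single admission.

Incremental results are summarised as the ICER $\Delta c / \Delta e$
(undefined, not an error, at $\Delta e = 0$) and the incremental net
monetary benefit $\lambda \Delta e - \Delta c$ at the per-country
willingness-to-pay $\lambda$ (Nepal \$1,339 = 1× GDP per capita; Singapore
\$34,615 = 45,000 SGD at 1.3 SGD/USD; Thailand \$4,751 = 160,000 THB at 35
THB/USD, all 2022 USD). A negative ICER is reported exactly as computed,
but the authoritative interpretation is the dominance class
(`classify_dominance()`), since negative ratios conflate dominant and
dominated quadrants.

## Input estimation

* **Event probabilities** — logistic regression of death, recurrence, and
  carbapenem-resistant infection on arm + country indicators, with
  predicted probabilities at each country × arm profile. The covariate set
  is deliberately minimal (the design goal is country adjustment, not
  prognostic modelling) and configurable.
* **Stays** — Tobit (censored-normal) regression on arm + country,
  right-censored at 60 days, fitted with `survival::survreg(dist =
  "gaussian")`, which maximises exactly the censored-normal likelihood and
  reduces to the ordinary normal MLE when nothing is censored. Predicted
  means are clipped to (0, 60].
* **Daily costs** — each patient's per-category total divided by
  min(stay, 60) days, averaged per category × country × arm.
* **Nonadherence** — $(n_{\text{ITT}} - n_{\text{PP}})/n_{\text{ITT}}$ in
  the short-course arm. Event and stay models are estimated on the
  per-protocol subset; nonadherent short-course patients are represented
  structurally by the adherence node.
* **Demographics** — mean age is taken from the cohort; life expectancy
  enters as a per-country constant (`country_constants()`), shipped as
  representative 2022 period values (70.5 / 83.5 / 77.0 years) that users
  should replace with their preferred source.

## Missing costs

Roughly 10% of cost cells are missing (at random, explainable by observed
covariates). The primary analysis imputes them by chained equations with
predictive mean matching (`mice_pmm()`): each cost column is regressed on
country, arm, age, vital status, recurrence, stay, and the other three
cost columns; regression parameters are drawn from their approximate
posterior; and each missing cell receives the observed value of one of the
$k = 5$ nearest predicted-value donors. PMM is used precisely because
imputed values stay within the observed, skewed, non-negative cost
support. Defaults of 5 donors and 10 chained sweeps are conventional PMM
settings; $m = 10$ imputed datasets matches the ~10% missingness rule of
thumb. Alternatives used by the scenario analyses: chained random forests
(terminal-node donor sampling), within-cell mean substitution, and
complete-case deletion.

Downstream, the cost-effectiveness analysis is run per imputed dataset and
*results* are pooled by Rubin's rule (`rubins_pool()`): pooling model
outputs rather than inputs keeps the nonlinear tree outside the pooling
step. Pooled intervals use the normal approximation on the total variance
$\bar W + (1 + 1/m)B$; with $m = 10$ and hundreds of patients the
Barnard–Rubin small-sample correction changes nothing material, and it is
therefore not applied.

## Probabilistic sensitivity analysis

The PSA distribution families are conventional choices (they are not
dictated by the estimation output): beta(events, non-events) for every
probability — including adherence, from the ITT/PP counts — gamma
moment-matched to the mean and its standard error for daily costs, and
normal truncated to (0, 60] for mean stays (and to (18, life expectancy]
for age). Parameters are sampled independently; no correlation structure
is imposed. Each of the default 1,000 iterations rolls the full tree back
(`run_psa()`); invalid draws are rejection-resampled and counted.
Uncertainty intervals are 2.5th/97.5th percentiles with the
linear-interpolation convention (`stats::quantile` type 7), so results are
bit-reproducible under a fixed seed. The cost-effectiveness acceptability
curve evaluates $P(\lambda \Delta e - \Delta c > 0)$ on a 501-point grid,
\$0–\$50,000 in steps of \$100. Degenerate (zero-variance) distributions
collapse the PSA exactly onto the deterministic base case, which is used
as an identity check in the test suite.

## Value of information

EVPI is computed directly from the PSA NMB matrix: mean of the row-wise
best NMB minus the best column mean. EVPPI for the eight parameter groups
(adherence, recurrence, carbapenem resistance, mortality, stays, bed-day
costs, variable costs, age) uses the single-loop regression estimator:
each strategy's NMB is smoothed on the group's draws, with an additive
thin-plate-spline GAM (REML) for groups of up to four parameters and a
second-order polynomial-interaction regression for larger groups, where a
multidimensional smooth on 1,000 draws would be impractical. Negative raw
estimates — pure estimator noise near zero — are clipped to 0 and flagged;
standard errors come from a bootstrap over draws with refitting. A nested
two-level Monte Carlo estimator (`evppi_nested_mc()`) exists purely as an
independent reference: the two estimators are checked against each other
(and a closed-form normal oracle) in the test suite.

## The synthetic cohort generator

No patient-level data are distributed, so `generate_cohort()` emulates the
trial's statistical structure; its defaults are the package's fixed study
conditions. Per-arm sizes 60/50/120 across Nepal/Singapore/Thailand (460
patients, matching the trial's scale); nonadherence 9%; per-protocol-style
60-day mortality near 36% (short course) vs 39% (usual care) with
country-specific levels; recurrence 13–14%; carbapenem-resistant infection
20–35% by country. Ages are truncated-normal (means 63/63/66 y, SD 13,
range 18–90), giving discounted life-year gains of roughly 6.5/15/9 years
per death averted — the magnitudes a three-country comparison of this kind
exhibits. Stays are gamma (shape 2.5) truncated below at 1 day, equal
between arms (the trial found no material stay difference), shorter for
Thailand (early discharge practice) and for deaths; stays beyond 60 days
are censored in-hospital. Death stays are drawn within the horizon, so
`censored` implies alive at day 60. Daily costs per category are gamma
with shape 1 (heavily right-skewed, as hospital cost data are), scaled so
that total per-episode costs are of order \$1,500 / \$16,000 / \$4,500 by
country; the short-course arm differs only in cheaper pharmaceuticals,
with a large saving in Singapore and small savings elsewhere — encoding
the mechanism by which short course can be cost-saving in a high-price
setting while mortality differences drive cost *increases* (survivors stay
longer) in the others. Costs are generated as daily rate × observed stay,
so `estimate_daily_costs()` recovers the generating rates exactly for
uncensored patients. Missingness is logistic in country, arm, and vital
status with the intercept calibrated numerically to the target rate
(missing at random, explainable by observables).

What the generator does *not* emulate: longitudinal within-stay cost
trajectories (only per-episode totals existed), correlation between cost
categories beyond their shared stay, competing-risk structure in time to
death vs discharge, and site-level clustering. Passing tests therefore
demonstrate that the *methods* recover known generating truths under the
stated structure, not that the published point estimates are reproduced —
those depend on unavailable trial data.

## Scenario analyses

Nine one-way scenarios (`apply_scenario()`), each changing exactly one
input group (diff-checked in the tests): full adherence; pooled (not
country-adjusted) outcomes, implemented by refitting the outcome
regressions without country terms; excluding bed-day cost, implemented by
zeroing the bed category — treating it as a sunk cost in both arms would
change absolute costs but not increments, so the two readings coincide for
every incremental quantity; QALY outcomes via a utility weight (default
0.77, an explicit placeholder — the package does not ship an elicited
value); reduced life expectancy in survivors via a multiplier on
$L$ (default 0.73, likewise a placeholder to be set from sepsis long-term
survival data); random-forest, simple-mean, and complete-case handling of
missing costs; and 5% discounting. Identity checks: utility 1 and
multiplier 1 reproduce the base case exactly.

## Numerical and reproducibility choices

Every stochastic stage takes an explicit integer seed, and the pipeline
derives per-stage seeds from one master seed; identical configurations
yield byte-identical artifact bundles, each stamped with an MD5 hash of
the configuration. Truncated distributions are sampled by inverse-CDF, so
draws are exact and vectorised. Probability hyperparameters for the beta
distributions are floored at 0.5 events to avoid degenerate shapes in
empty cells. Tobit fitting uses a log-scale parameterisation internally
(via `survreg`), avoiding $\sigma \le 0$; an all-censored sample is an
error. PMM donor ties are broken by a random permutation before the
$k$-nearest selection.

Problem sizes used by the test suite and acceptance script are the
package's own verification choices: parameter-recovery checks use 100
replications at 5,000 patients per arm (logistic) and 10,000 observations
(Tobit, simulated from the censored-normal model itself, since the
likelihood — not gamma-robustness — is the object under test); imputation
coverage uses 100 replications of a 300-patient cohort with $m = 10$ and 5
sweeps; the EVPI oracle uses $10^5$ draws; pipeline-level checks run 1,000
PSA iterations (500 per scenario row). The imputation coverage check is
one-sided (coverage at least the binomial 99% lower bound of nominal 95%):
its reference value is the pre-masking complete-data mean, against which
Rubin intervals are conservative, so an upper bound would be
mis-specified.

## Known limitations

Daily costs assume uniform accrual over the stay; front-loaded resource
use means savings from shortened stays are, if anything, overestimated.
The tree covers a single VAP episode (no readmission or Markov
extension), ignores antimicrobial-resistance spill-over benefits of
reduced antibiotic use, and prices bed days at accounting rather than
opportunity cost. Life expectancy, utility weights, and the
life-expectancy reduction factor are configuration constants, not
estimates. EVPPI for structural-only parameters (recurrence, carbapenem
resistance) is identically near zero at the default stratum resolution —
an artefact of the published input granularity, not evidence those
quantities are decision-irrelevant.
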