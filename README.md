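# vapcea

Trial-based economic evaluation of an **individualised short-course
antibiotic strategy for ventilator-associated pneumonia (VAP)** versus usual
care, from the health-system perspective in Nepal, Singapore, and Thailand.

The package is aimed at health economists and trialists who want a fully
reproducible, tested pipeline for a decision-tree cost-effectiveness
analysis run alongside a multi-country randomised trial: synthetic
patient-level data generation, multiple imputation of missing costs,
country-adjusted outcome models, probabilistic sensitivity analysis,
scenario analyses, and value-of-information analysis.

## The model

Patients enter a decision tree at VAP diagnosis under one of two
strategies: individualised short-course antibiotics or usual care. The
short-course branch first splits on **adherence** — patients who do not
receive the complete short-course regimen progress under usual-care
parameters. Both strategies then branch on infection with
**carbapenem-resistant Gram-negative bacilli**, then **pneumonia
recurrence**, ending in **death** or **discharged alive** (8 pathways for
usual care, 16 for short course).

For strategies *i* with expected cost *C·i·* and expected effect *E·i·* (in
discounted life-years):

- **ICER** = Δc / Δe, where Δc = C·sc· − C·uc· and Δe = E·sc· − E·uc·
- **INMB**(λ) = λ·Δe − Δc, at willingness-to-pay λ per life-year
  (Nepal $1,339; Singapore $34,615; Thailand $4,751, all 2022 USD)
- A death averted gains L = (life expectancy − age at admission) years,
  discounted as the annuity (1 − (1+r)^−L)/r at r = 3% per year.

Pathway costs are (per-category daily cost) × (mean stay for the stratum),
with daily costs derived by dividing each patient's per-category total by
min(stay, 60) days. Model inputs are estimated from patient-level data:
logistic regression (arm + country) for event probabilities, Tobit
regression (censored-normal likelihood, right-censored at 60 days) for mean
stay to death or discharge, and the ITT/per-protocol shortfall for
nonadherence. Missing cost cells (~10%) are multiply imputed by chained
equations with predictive mean matching (m = 10) and results pooled by
Rubin's rule.

Uncertainty is propagated by Monte Carlo probabilistic sensitivity analysis
(beta distributions for probabilities, gamma for daily costs, truncated
normal for stays), summarised as 95% uncertainty intervals,
cost-effectiveness acceptability curves over λ ∈ [$0, $50,000], and
per-patient EVPI / regression-based EVPPI for eight parameter groups.

## Worked example

```r
library(vapcea)

cfg    <- trial_config()                      # synthetic study conditions
cohort <- generate_cohort(cfg)                # 460 patients, 3 countries
masked <- apply_missingness(cohort, 0.10, seed = 2)
imp    <- mice_pmm(masked, imputation_config(m = 5, seed = 3))
ests   <- estimate_country_inputs(imp[[1]])

run_cea(ests$Singapore)
#> Cost-effectiveness analysis: Singapore (WTP $34,615/LY)
#>   short course: cost $12830, effect 11.72 LY
#>   usual care:   cost $15951, effect 11.20 LY
#>   incremental:  $-3121, 0.52 LY | ICER $-6044 | INMB $20995 | dominant
```

Short course costs $3,121 less per patient and gains 0.52 discounted
life-years, so it *dominates* usual care in this realisation (the negative
ICER is reported as computed but interpreted through the dominance class).
Propagating parameter uncertainty:

```r
psa <- run_psa(ests$Singapore, n = 1000, seed = 4)
psa
#> PSA: Singapore, 1000 iterations (WTP $34,615/LY, 0 rejected draws)
#>   incremental cost $-3130 (95% UI -7436 to 654)
#>   incremental effect 0.49 LY (95% UI -2.03 to 2.88)
#>   INMB $20037 (95% UI -65663 to 103225); P(cost-effective) 67.5%

voi_analysis(psa)
#> Value of information: Singapore (n = 1000 PSA draws)
#>   EVPI: $9241 per patient
#>   EVPPI mortality      $9242
#>   EVPPI variable_cost  $82
#>   ...
```

The wide INMB interval and an EVPI of ~$9,000 per patient say the adoption
decision is genuinely uncertain, and almost all of that decision
uncertainty is attributable to the mortality probabilities — the same
qualitative conclusion the value-of-information analysis is designed to
surface. `run_pipeline(pipeline_config())` chains all stages (including
Rubin pooling across imputations and the nine one-way scenario analyses)
and `export_pipeline()` writes plot-ready CSV/JSON artifacts.

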