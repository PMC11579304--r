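# Small deterministic fixtures built in code.

small_trial_config <- function(seed = 42L, ...) {
  trial_config(n_per_arm = c(Nepal = 40L, Singapore = 40L, Thailand = 60L),
               seed = seed, ...)
}

# A hand-specified parameter set for decision-tree tests (no estimation).
toy_estimates <- function(p_nonadherence = 0.09,
                          p_death_sc = 0.36, p_death_uc = 0.39,
                          lambda = 1339, discount_rate = 0.03,
                          utility_weight = 1, ...) {
  stay <- matrix(c(16, 16, 28, 30), nrow = 2,
                 dimnames = list(c("short_course", "usual_care"),
                                 c("death", "discharged_alive")))
  cost <- matrix(c(24, 14, 7, 5, 24, 16, 7, 5), ncol = 2,
                 dimnames = list(c("bed", "pharma", "diagnostics", "consumables"),
                                 c("short_course", "usual_care")))
  country_estimates(
    country = "Nepal", p_nonadherence = p_nonadherence,
    p_crgnb = c(short_course = 0.3, usual_care = 0.3),
    p_recurrence = c(short_course = 0.14, usual_care = 0.13),
    p_death = c(short_course = p_death_sc, usual_care = p_death_uc),
    mean_stay = stay, daily_cost = cost, mean_age = 60,
    life_expectancy = 70, discount_rate = discount_rate, lambda = lambda,
    utility_weight = utility_weight, ...)
}

# Attach a consistent uncertainty block so toy estimates can drive a PSA.
with_uncertainty <- function(est, n = c(short_course = 200, usual_care = 200),
                             stay_se = 1.5, cost_se_frac = 0.1,
                             n_itt = 231, n_pp = 211, age_se = 1) {
  arms <- c("short_course", "usual_care")
  ev <- function(p) setNames(p[arms] * n[arms], arms)
  est$uncertainty <- list(
    events = list(died = ev(est$p_death), recurrence = ev(est$p_recurrence),
                  crgnb_infection = ev(est$p_crgnb)),
    n = n,
    stay_se = matrix(stay_se, 2, 2, dimnames = dimnames(est$mean_stay)),
    cost_se = est$daily_cost * cost_se_frac,
    n_itt_short = n_itt, n_pp_short = n_pp,
    age_mean = est$mean_age, age_se = age_se, bound = 60)
  est
}

# Minimal valid cohort data.frame built by hand.
manual_cohort <- function(n = 6, country = "Nepal", arm = "usual_care",
                          died = FALSE, los = 30, costs = 600) {
  data.frame(
    patient_id = sprintf("M%03d", seq_len(n)),
    country = factor(rep_len(country, n), levels = c("Nepal", "Singapore", "Thailand")),
    arm = factor(rep_len(arm, n), levels = c("short_course", "usual_care")),
    age = rep_len(60, n),
    adhered = ifelse(rep_len(arm, n) == "short_course", TRUE, NA),
    crgnb_infection = rep_len(FALSE, n),
    recurrence = rep_len(FALSE, n),
    died = rep_len(died, n),
    los_days = rep_len(los, n),
    censored = rep_len(FALSE, n),
    cost_bed = rep_len(costs, n),
    cost_pharma = rep_len(costs, n),
    cost_diagnostics = rep_len(costs, n),
    cost_consumables = rep_len(costs, n),
    stringsAsFactors = FALSE)
}
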