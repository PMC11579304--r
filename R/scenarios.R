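SCENARIO_NAMES <- c("full_adherence", "pooled_outcomes", "exclude_bed_cost",
                    "qaly_outcome", "reduced_life_expectancy", "rf_imputation",
                    "simple_imputation", "complete_case", "discount_5pct")

#' Analysis settings (base case and one-way scenario switches)
#'
#' A flat record of every input group a scenario may change. The base case
#' uses country-adjusted outcomes, all four cost categories, life-years as
#' the outcome (utility weight 1), full general-population life expectancy,
#' MICE-PMM imputation, 3\% annual discounting, and the trial-observed
#' nonadherence.
#'
#' @param full_adherence if `TRUE`, all short-course patients adhere
#'   (nonadherence probability forced to 0).
#' @param pooled_outcomes if `TRUE`, outcome regressions drop country terms.
#' @param exclude_bed_cost if `TRUE`, bed-day cost is treated as a
#'   non-recoverable fixed cost and zeroed in both arms.
#' @param utility_weight utility applied to life-years (1 = base case).
#' @param le_factor multiplier on remaining life expectancy (1 = base case).
#' @param imputation_method method passed to [imputation_config()].
#' @param discount_rate annual discount rate for life-years.
#' @return An `analysis_settings` list.
#' @export
analysis_settings <- function(full_adherence = FALSE, pooled_outcomes = FALSE,
                              exclude_bed_cost = FALSE, utility_weight = 1,
                              le_factor = 1, imputation_method = "pmm",
                              discount_rate = 0.03) {
  structure(list(full_adherence = full_adherence,
                 pooled_outcomes = pooled_outcomes,
                 exclude_bed_cost = exclude_bed_cost,
                 utility_weight = utility_weight, le_factor = le_factor,
                 imputation_method = imputation_method,
                 discount_rate = discount_rate),
            class = "analysis_settings")
}

#' Apply a one-way scenario to the base-case settings
#'
#' Each of the nine named scenarios modifies exactly one input group of
#' [analysis_settings()]: (1) full adherence in the short-course arm,
#' (2) pooled (not country-adjusted) outcomes, (3) excluding bed-stay cost,
#' (4) QALYs instead of life-years via a utility weight, (5) reduced life
#' expectancy in survivors, (6) random-forest imputation, (7) simple mean
#' imputation, (8) complete-case analysis, (9) a 5\% discount rate.
#'
#' @param settings base-case [analysis_settings()].
#' @param scenario one of the nine scenario names (see `SCENARIO_NAMES` in
#'   the package source), or `"base_case"` for no change.
#' @param utility_weight utility used by the `qaly_outcome` scenario.
#' @param le_factor life-expectancy multiplier used by the
#'   `reduced_life_expectancy` scenario.
#' @return Modified `analysis_settings`.
#' @export
apply_scenario <- function(settings, scenario, utility_weight = 0.77,
                           le_factor = 0.73) {
  if (scenario == "base_case") return(settings)
  if (!scenario %in% SCENARIO_NAMES)
    config_error(paste("unknown scenario:", scenario))
  switch(scenario,
         full_adherence = { settings$full_adherence <- TRUE },
         pooled_outcomes = { settings$pooled_outcomes <- TRUE },
         exclude_bed_cost = { settings$exclude_bed_cost <- TRUE },
         qaly_outcome = { settings$utility_weight <- utility_weight },
         reduced_life_expectancy = { settings$le_factor <- le_factor },
         rf_imputation = { settings$imputation_method <- "random_forest" },
         simple_imputation = { settings$imputation_method <- "simple_mean" },
         complete_case = { settings$imputation_method <- "complete_case" },
         discount_5pct = { settings$discount_rate <- 0.05 })
  settings
}

#' Modify estimated decision-tree inputs according to analysis settings
#'
#' Applies the estimate-level scenario switches (adherence, bed cost,
#' utility, life expectancy, discount rate) to a [country_estimates()]
#' object. Imputation-method and pooling switches act earlier in the
#' pipeline and are not handled here.
#'
#' @param est a [country_estimates()].
#' @param settings an [analysis_settings()].
#' @return The modified `country_estimates`.
#' @export
apply_settings_to_estimates <- function(est, settings) {
  if (settings$full_adherence) est$p_nonadherence <- 0
  if (settings$exclude_bed_cost) est$daily_cost["bed", ] <- 0
  est$utility_weight <- settings$utility_weight
  est$discount_rate <- settings$discount_rate
  if (settings$le_factor != 1)
    est$life_expectancy <- est$mean_age +
      settings$le_factor * (est$life_expectancy - est$mean_age)
  validate_country_estimates(est)
  est
}

# Run one configured analysis (imputation -> estimation -> scenario
# transform -> deterministic CEA + PSA) for every country, Rubin-pooling
# across imputed datasets. Shared by the scenario runner and the pipeline.
run_configured_analysis <- function(masked, settings, constants, imp_config,
                                    psa_n = 1000L, seed = 1L, bound = 60) {
  imp_config$method <- settings$imputation_method
  completed <- impute_costs(masked, imp_config)
  m <- length(completed)
  per_dataset <- lapply(seq_len(m), function(d) {
    ests <- estimate_country_inputs(completed[[d]], constants, bound = bound,
                                    pooled = settings$pooled_outcomes)
    lapply(ests, apply_settings_to_estimates, settings = settings)
  })
  countries <- names(per_dataset[[1]])
  out <- lapply(stats::setNames(nm = countries), function(co) {
    ceas <- lapply(per_dataset, function(e) run_cea(e[[co]]))
    psa_per <- ceiling(psa_n / m)
    psas <- lapply(seq_len(m), function(d)
      run_psa(per_dataset[[d]][[co]], n = psa_per, seed = seed + 1000L * d))
    stacked <- psas[[1]]
    stacked$results <- do.call(rbind, lapply(psas, function(p) p$results))
    stacked$draws <- do.call(rbind, lapply(psas, function(p) p$draws))
    stacked$n_rejected <- sum(vapply(psas, function(p) p$n_rejected, integer(1)))
    pool_of <- function(stat, psa_col) rubins_pool(
      vapply(ceas, function(x) x[[stat]], numeric(1)),
      vapply(psas, function(p) stats::var(p$results[[psa_col]]), numeric(1)))
    list(country = co,
         cea = ceas[[1]],
         pooled_delta_cost = pool_of("delta_cost", "delta_cost"),
         pooled_delta_effect = pool_of("delta_effect", "delta_effect"),
         pooled_inmb = pool_of("inmb", "inmb"),
         psa = stacked)
  })
  out
}

#' Run the nine one-way scenario analyses
#'
#' Produces a summary table with one row per scenario and country:
#' Rubin-pooled incremental cost and incremental life-years with 95\%
#' uncertainty intervals from the stacked PSA draws, the incremental net
#' monetary benefit, the ICER of the pooled increments, and the percentage
#' of PSA draws that are cost-effective at the country's willingness-to-pay
#' threshold.
#'
#' @param masked cohort with missing cost cells (pre-imputation).
#' @param constants per-country constants list (see
#'   [estimate_country_inputs()]).
#' @param base_settings base-case [analysis_settings()].
#' @param imp_config base [imputation_config()].
#' @param psa_n total PSA iterations per scenario and country.
#' @param seed RNG seed.
#' @param scenarios scenario names to run.
#' @param include_base also prepend the base case.
#' @return A `data.frame` with columns `scenario`, `country`, `delta_cost`,
#'   `delta_cost_lo`, `delta_cost_hi`, `delta_effect`, `delta_effect_lo`,
#'   `delta_effect_hi`, `inmb`, `inmb_lo`, `inmb_hi`, `icer`,
#'   `pct_cost_effective`.
#' @export
run_all_scenarios <- function(masked,
                              constants = lapply(stats::setNames(nm = COUNTRIES),
                                                 country_constants),
                              base_settings = analysis_settings(),
                              imp_config = imputation_config(),
                              psa_n = 1000L, seed = 1L,
                              scenarios = SCENARIO_NAMES,
                              include_base = FALSE) {
  names_run <- c(if (include_base) "base_case", scenarios)
  rows <- list()
  for (sc in names_run) {
    konst1 <- constants[[1]]
    settings <- apply_scenario(base_settings, sc,
                               utility_weight = konst1$utility_weight,
                               le_factor = konst1$le_reduction_factor)
    res <- run_configured_analysis(masked, settings, constants, imp_config,
                                   psa_n = psa_n, seed = seed)
    for (co in names(res)) {
      r <- res[[co]]
      ui <- summarize_ui(r$psa)
      dc <- r$pooled_delta_cost$estimate
      de <- r$pooled_delta_effect$estimate
      rows[[paste(sc, co)]] <- data.frame(
        scenario = sc, country = co,
        delta_cost = dc, delta_cost_lo = ui$delta_cost[["lo"]],
        delta_cost_hi = ui$delta_cost[["hi"]],
        delta_effect = de, delta_effect_lo = ui$delta_effect[["lo"]],
        delta_effect_hi = ui$delta_effect[["hi"]],
        inmb = r$pooled_inmb$estimate, inmb_lo = ui$inmb[["lo"]],
        inmb_hi = ui$inmb[["hi"]],
        icer = compute_icer(dc, de),
        pct_cost_effective = 100 * mean(r$psa$results$inmb > 0),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
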