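#' Estimate all decision-tree inputs from a completed cohort
#'
#' Runs the full input-estimation stage on one completed (imputed) cohort:
#' country-adjusted logistic regressions for death, recurrence, and
#' carbapenem-resistant infection; separate Tobit fits for time to death
#' and time to discharge (the latter right-censored at the horizon);
#' per-category daily costs; and the adherence probability from the ITT /
#' per-protocol shortfall. Event probabilities and stays are estimated on
#' the per-protocol subset (nonadherence is handled structurally by the
#' tree's adherence node). Each country's [country_estimates()] carries an
#' `uncertainty` block with the count, standard-error, and sample-size
#' hyperparameters that [parameter_distributions()] turns into PSA
#' distributions.
#'
#' @param records a completed cohort (no missing cost cells).
#' @param constants list of per-country constants, as produced by
#'   [country_constants()] per country; must cover every country present.
#' @param bound censoring horizon in days.
#' @param pooled if `TRUE`, drop country terms from the outcome regressions
#'   so all countries share pooled event probabilities and stays (the
#'   "pooled outcomes" scenario).
#' @return Named list of [country_estimates()], one per country present.
#' @export
estimate_country_inputs <- function(records,
                                    constants = lapply(stats::setNames(nm = COUNTRIES),
                                                       country_constants),
                                    bound = 60, pooled = FALSE) {
  validate_cohort(records)
  pp <- per_protocol_subset(records)
  covars <- if (pooled) "arm" else c("arm", "country")

  n_itt_short <- sum(records$arm == "short_course")
  n_pp_short <- sum(pp$arm == "short_course")
  p_nonadh <- estimate_adherence(n_itt_short, n_pp_short)

  fits <- lapply(stats::setNames(nm = c("died", "recurrence", "crgnb_infection")),
                 function(o) fit_logistic_outcome(pp, o, covars))

  died_rows <- pp[pp$died, , drop = FALSE]
  alive_rows <- pp[!pp$died, , drop = FALSE]
  tob_death <- fit_tobit_los(died_rows, covars, bound)
  tob_alive <- fit_tobit_los(alive_rows, covars, bound)

  costs <- estimate_daily_costs(records, bound)

  countries <- levels(droplevels(records$country))
  out <- lapply(stats::setNames(nm = countries), function(co) {
    konst <- constants[[co]]
    if (is.null(konst)) config_error(paste("no constants supplied for", co))
    nd <- data.frame(arm = factor(ARMS, levels = ARMS),
                     country = factor(co, levels = levels(records$country)))
    prob_of <- function(fit) fit$probabilities[co, ]
    stay <- cbind(death = tob_death$predict(nd),
                  discharged_alive = tob_alive$predict(nd))
    rownames(stay) <- ARMS
    stay_se <- cbind(death = tobit_pred_se(tob_death, nd),
                     discharged_alive = tobit_pred_se(tob_alive, nd))
    rownames(stay_se) <- ARMS
    ages <- records$age[records$country == co]
    unc <- list(
      events = lapply(fits, function(f)
        pmin(pmax(f$probabilities[co, ] * f$n[co, ], 0.5), f$n[co, ] - 0.5)),
      n = fits$died$n[co, ],
      stay_se = stay_se,
      cost_se = costs$se[, co, ],
      n_itt_short = n_itt_short, n_pp_short = n_pp_short,
      age_mean = mean(ages), age_se = stats::sd(ages) / sqrt(length(ages)),
      bound = bound)
    country_estimates(
      country = co, p_nonadherence = p_nonadh,
      p_crgnb = prob_of(fits$crgnb_infection),
      p_recurrence = prob_of(fits$recurrence),
      p_death = prob_of(fits$died),
      mean_stay = stay, daily_cost = costs$mean[, co, ],
      mean_age = mean(ages), life_expectancy = konst$life_expectancy,
      discount_rate = konst$discount_rate, lambda = konst$lambda,
      utility_weight = 1, uncertainty = unc)
  })
  out
}

# Standard error of the Tobit linear predictor at new covariate profiles.
tobit_pred_se <- function(fit, newdata) {
  mm <- stats::model.matrix(stats::delete.response(stats::terms(fit$model)),
                            data = newdata)
  sqrt(pmax(diag(mm %*% fit$vcov %*% t(mm)), 0))
}
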