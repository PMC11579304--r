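#' Parameter uncertainty distributions for the PSA
#'
#' Builds the table of sampling distributions for every uncertain
#' decision-tree input of one country, using conventional families:
#' beta(events, nonevents) for each probability (including adherence, from
#' the ITT / per-protocol counts), gamma (moment-matched to the mean and
#' standard error of the mean) for each per-category daily cost, and normal
#' truncated to (0, horizon\] for each mean stay and for the mean age
#' (truncated to (18, life expectancy\]). Each parameter carries the group
#' label used by the value-of-information analysis.
#'
#' @param est a [country_estimates()] with an `uncertainty` block (see
#'   [estimate_country_inputs()]).
#' @return A `data.frame` with one row per uncertain parameter: `name`,
#'   `group`, `family` (`beta`, `gamma`, `tnorm`, or `fixed`), `par1`,
#'   `par2`, `lo`, `hi`, and the base-case `value`.
#' @export
parameter_distributions <- function(est) {
  unc <- est$uncertainty
  if (is.null(unc)) model_error("estimates carry no uncertainty block")
  rows <- list()
  add <- function(name, group, family, par1, par2, lo = -Inf, hi = Inf, value) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, group = group, family = family, par1 = par1, par2 = par2,
      lo = lo, hi = hi, value = value, stringsAsFactors = FALSE)
  }
  # adherence: beta from the ITT/PP shortfall counts
  add("p_nonadherence", "adherence", "beta",
      max(unc$n_itt_short - unc$n_pp_short, 0.5), unc$n_pp_short,
      value = est$p_nonadherence)
  prob_groups <- c(died = "mortality", recurrence = "recurrence",
                   crgnb_infection = "crgnb")
  slot_of <- c(died = "p_death", recurrence = "p_recurrence",
               crgnb_infection = "p_crgnb")
  for (oc in names(prob_groups)) {
    ev <- unc$events[[oc]]
    for (arm in ARMS)
      add(paste0(slot_of[[oc]], ".", arm), prob_groups[[oc]], "beta",
          ev[[arm]], unc$n[[arm]] - ev[[arm]], value = est[[slot_of[[oc]]]][[arm]])
  }
  for (arm in ARMS) for (ocm in OUTCOMES)
    add(paste0("stay.", arm, ".", ocm), "los", "tnorm",
        est$mean_stay[arm, ocm], unc$stay_se[arm, ocm],
        lo = 1e-6, hi = unc$bound, value = est$mean_stay[arm, ocm])
  for (cat in COST_CATEGORIES) for (arm in ARMS) {
    grp <- if (cat == "bed") "bed_cost" else "variable_cost"
    m <- est$daily_cost[cat, arm]
    s <- unc$cost_se[cat, arm]
    if (is.na(s) || s <= 0 || m <= 0) {
      add(paste0("cost.", cat, ".", arm), grp, "fixed", m, 0, value = m)
    } else {
      add(paste0("cost.", cat, ".", arm), grp, "gamma",
          (m / s)^2, s^2 / m, value = m)   # shape, scale
    }
  }
  add("age", "age", "tnorm", unc$age_mean, unc$age_se,
      lo = 18, hi = est$life_expectancy, value = est$mean_age)
  out <- do.call(rbind, rows)
  bad <- out$family == "beta" & (out$par1 <= 0 | out$par2 <= 0) |
    out$family == "gamma" & (out$par1 <= 0 | out$par2 <= 0) |
    out$family == "tnorm" & out$par2 < 0
  if (any(bad))
    config_error(paste("invalid hyperparameters for:",
                       paste(out$name[bad], collapse = ", ")))
  out
}

#' Degenerate (zero-variance) version of a distribution table
#'
#' Replaces every family by a point mass at the base-case value, so the PSA
#' collapses exactly onto the deterministic tree output. Useful for checks
#' and for switching individual parameters off.
#'
#' @param dists distribution table from [parameter_distributions()].
#' @return The table with `family = "fixed"` and `par1 = value` everywhere.
#' @export
degenerate_distributions <- function(dists) {
  dists$family <- "fixed"
  dists$par1 <- dists$value
  dists$par2 <- 0
  dists
}

#' Draw parameter values from their uncertainty distributions
#'
#' @param dists distribution table from [parameter_distributions()].
#' @param n number of Monte Carlo draws.
#' @param seed RNG seed; the same seed reproduces the draw matrix exactly.
#' @return An `n` x `nrow(dists)` matrix, columns named by parameter.
#' @export
sample_parameters <- function(dists, n, seed = 1L) {
  if (n < 1) config_error("need at least one draw")
  set.seed(seed)
  draws <- sapply(seq_len(nrow(dists)), function(j) {
    d <- dists[j, ]
    switch(d$family,
           beta  = stats::rbeta(n, d$par1, d$par2),
           gamma = stats::rgamma(n, shape = d$par1, scale = d$par2),
           tnorm = if (d$par2 == 0) rep(d$par1, n)
                   else rtruncnorm(n, d$par1, d$par2, d$lo, d$hi),
           fixed = rep(d$par1, n),
           config_error(paste("unknown family", d$family)))
  })
  draws <- matrix(draws, nrow = n)
  colnames(draws) <- dists$name
  draws
}

# Substitute one PSA draw into a country_estimates object.
apply_draw <- function(est, draw) {
  est$p_nonadherence <- draw[["p_nonadherence"]]
  for (slot in c("p_death", "p_recurrence", "p_crgnb"))
    for (arm in ARMS)
      est[[slot]][[arm]] <- draw[[paste0(slot, ".", arm)]]
  for (arm in ARMS) for (ocm in OUTCOMES)
    est$mean_stay[arm, ocm] <- draw[[paste0("stay.", arm, ".", ocm)]]
  for (cat in COST_CATEGORIES) for (arm in ARMS)
    est$daily_cost[cat, arm] <- draw[[paste0("cost.", cat, ".", arm)]]
  est$mean_age <- min(draw[["age"]], est$life_expectancy)
  est
}

#' Probabilistic sensitivity analysis
#'
#' Samples `n` joint parameter draws, rolls the decision tree back at each
#' draw, and records per-iteration costs and effects for both strategies,
#' their increments, and the incremental net monetary benefit at the
#' country's willingness-to-pay threshold. Draws whose parameters fail the
#' model's validity checks are rejection-resampled and counted.
#'
#' @param est a [country_estimates()] with an `uncertainty` block.
#' @param n number of Monte Carlo iterations.
#' @param seed RNG seed.
#' @param dists optionally a pre-built distribution table (defaults to
#'   [parameter_distributions()] of `est`).
#' @return A `psa_results` list: `draws` (the parameter matrix), `results`
#'   (a `data.frame` with `cost_sc`, `cost_uc`, `eff_sc`, `eff_uc`,
#'   `delta_cost`, `delta_effect`, `inmb`), `dists`, `lambda`, `country`,
#'   `seed`, `n_rejected`.
#' @export
run_psa <- function(est, n = 1000L, seed = 1L, dists = parameter_distributions(est)) {
  draws <- sample_parameters(dists, n, seed)
  n_rejected <- 0L
  res <- matrix(NA_real_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("cost_sc", "cost_uc", "eff_sc", "eff_uc")))
  for (i in seq_len(n)) {
    repeat {
      cand <- try({
        est_i <- apply_draw(est, draws[i, ])
        sc <- expected_strategy_values(enumerate_pathways(est_i, "short_course"))
        uc <- expected_strategy_values(enumerate_pathways(est_i, "usual_care"))
        c(sc[["cost"]], uc[["cost"]], sc[["effect"]], uc[["effect"]])
      }, silent = TRUE)
      if (!inherits(cand, "try-error")) break
      n_rejected <- n_rejected + 1L
      draws[i, ] <- sample_parameters(dists, 1, seed = seed + n + n_rejected)
    }
    res[i, ] <- cand
  }
  results <- as.data.frame(res)
  results$delta_cost <- results$cost_sc - results$cost_uc
  results$delta_effect <- results$eff_sc - results$eff_uc
  results$inmb <- compute_inmb(est$lambda, results$delta_effect, results$delta_cost)
  structure(list(draws = draws, results = results, dists = dists,
                 lambda = est$lambda, country = est$country, seed = seed,
                 n_rejected = n_rejected),
            class = "psa_results")
}

#' @export
print.psa_results <- function(x, ...) {
  ui <- summarize_ui(x)
  cat(sprintf("PSA: %s, %d iterations (WTP $%s/LY, %d rejected draws)\n",
              x$country, nrow(x$results), format(x$lambda, big.mark = ","),
              x$n_rejected))
  cat(sprintf("  incremental cost $%.0f (95%% UI %.0f to %.0f)\n",
              ui$delta_cost["mean"], ui$delta_cost["lo"], ui$delta_cost["hi"]))
  cat(sprintf("  incremental effect %.2f LY (95%% UI %.2f to %.2f)\n",
              ui$delta_effect["mean"], ui$delta_effect["lo"], ui$delta_effect["hi"]))
  cat(sprintf("  INMB $%.0f (95%% UI %.0f to %.0f); P(cost-effective) %.1f%%\n",
              ui$inmb["mean"], ui$inmb["lo"], ui$inmb["hi"],
              100 * mean(x$results$inmb > 0)))
  invisible(x)
}

#' 95\% uncertainty intervals from PSA output
#'
#' Percentile intervals (2.5th and 97.5th percentiles) using the default
#' linear-interpolation quantile convention (`stats::quantile` type 7), so
#' intervals are reproducible bit-for-bit under a fixed seed.
#'
#' @param psa a `psa_results` object (or a `data.frame` shaped like its
#'   `results` element).
#' @param level interval level.
#' @return A list with `delta_cost`, `delta_effect`, `inmb`, each a named
#'   vector `c(mean, lo, hi)`.
#' @export
summarize_ui <- function(psa, level = 0.95) {
  res <- if (inherits(psa, "psa_results")) psa$results else psa
  if (nrow(res) < 2) data_error("need at least two PSA iterations")
  a <- (1 - level) / 2
  one <- function(v) c(mean = mean(v),
                       lo = unname(stats::quantile(v, a, type = 7)),
                       hi = unname(stats::quantile(v, 1 - a, type = 7)))
  list(delta_cost = one(res$delta_cost),
       delta_effect = one(res$delta_effect),
       inmb = one(res$inmb))
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that the short-course
#' strategy is cost-effective: the fraction of PSA draws with positive net
#' monetary benefit at that threshold.
#'
#' @param psa a `psa_results` object.
#' @param lambda_grid willingness-to-pay grid (USD per life-year); default
#'   0 to 50,000 in steps of 100.
#' @return A `data.frame` with columns `lambda` and `probability`.
#' @export
ceac_curve <- function(psa, lambda_grid = seq(0, 50000, by = 100)) {
  if (length(lambda_grid) == 0) config_error("empty willingness-to-pay grid")
  res <- psa$results
  if (nrow(res) == 0) data_error("empty PSA results")
  prob <- vapply(lambda_grid, function(l)
    mean(l * res$delta_effect - res$delta_cost > 0), numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Probability the intervention is cost-saving
#'
#' @param psa a `psa_results` object.
#' @return Fraction of PSA draws with negative incremental cost.
#' @export
prob_cost_saving <- function(psa) {
  mean(psa$results$delta_cost < 0)
}

#' Write PSA results to CSV (one row per iteration) plus a JSON summary
#'
#' @param psa a `psa_results` object.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the summary list.
#' @export
write_psa_results <- function(psa, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(cbind(iteration = seq_len(nrow(psa$results)), psa$results),
                     csv_path, row.names = FALSE)
  ui <- summarize_ui(psa)
  summary <- list(country = psa$country, lambda = psa$lambda,
                  n_iterations = nrow(psa$results), seed = psa$seed,
                  n_rejected = psa$n_rejected,
                  delta_cost = as.list(ui$delta_cost),
                  delta_effect = as.list(ui$delta_effect),
                  inmb = as.list(ui$inmb),
                  prob_cost_effective = mean(psa$results$inmb > 0),
                  prob_cost_saving = prob_cost_saving(psa))
  if (!is.null(json_path))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
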