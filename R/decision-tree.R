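model_error <- function(msg) {
  stop(errorCondition(msg, class = c("vapcea_model_error", "error", "condition")))
}

#' Decision-tree parameter set for one country
#'
#' Everything the decision tree needs to compare the individualised
#' short-course strategy against usual care in one country: the adherence
#' probability (short-course arm), per-arm branch probabilities for
#' carbapenem-resistant Gram-negative infection, pneumonia recurrence, and
#' 60-day death, mean stays per arm and terminal outcome, per-category
#' daily costs per arm, and the demographic and economic constants used to
#' value a death averted.
#'
#' @param country country label.
#' @param p_nonadherence probability a short-course patient does not adhere.
#' @param p_crgnb,p_recurrence,p_death named per-arm probability vectors
#'   (names `short_course`, `usual_care`).
#' @param mean_stay 2 x 2 matrix, arm x outcome (`death`,
#'   `discharged_alive`), mean days in hospital.
#' @param daily_cost 4 x 2 matrix, category x arm, USD per day.
#' @param mean_age mean age at admission, years.
#' @param life_expectancy country life expectancy, years.
#' @param discount_rate annual discount rate for life-years.
#' @param lambda willingness-to-pay threshold, USD per life-year.
#' @param utility_weight utility applied to life-years (1 in the base case;
#'   set below 1 for the QALY scenario).
#' @param uncertainty optional list of sampling-uncertainty hyperparameters
#'   attached by [estimate_country_inputs()] and consumed by
#'   [parameter_distributions()].
#' @return A validated `country_estimates` object.
#' @export
country_estimates <- function(country, p_nonadherence, p_crgnb, p_recurrence,
                              p_death, mean_stay, daily_cost, mean_age,
                              life_expectancy, discount_rate = 0.03,
                              lambda, utility_weight = 1, uncertainty = NULL) {
  est <- structure(list(
    country = country, p_nonadherence = p_nonadherence,
    p_crgnb = p_crgnb[ARMS], p_recurrence = p_recurrence[ARMS],
    p_death = p_death[ARMS],
    mean_stay = mean_stay[ARMS, OUTCOMES, drop = FALSE],
    daily_cost = daily_cost[COST_CATEGORIES, ARMS, drop = FALSE],
    mean_age = mean_age, life_expectancy = life_expectancy,
    discount_rate = discount_rate, lambda = lambda,
    utility_weight = utility_weight, uncertainty = uncertainty),
    class = "country_estimates")
  validate_country_estimates(est)
  est
}

validate_country_estimates <- function(est) {
  probs <- c(est$p_nonadherence, est$p_crgnb, est$p_recurrence, est$p_death)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1))
    model_error("branch probabilities must lie in [0, 1]")
  if (any(est$mean_stay <= 0) || any(est$mean_stay > 60))
    model_error("mean stays must lie in (0, 60] days")
  if (any(est$daily_cost < 0)) model_error("daily costs must be >= 0")
  if (est$discount_rate < 0 || est$discount_rate >= 1)
    model_error("discount rate must lie in [0, 1)")
  if (est$lambda <= 0) model_error("willingness-to-pay must be positive")
  if (est$utility_weight < 0 || est$utility_weight > 1)
    model_error("utility weight must lie in [0, 1]")
  invisible(est)
}

#' @export
print.country_estimates <- function(x, ...) {
  cat(sprintf("Decision-tree inputs: %s\n", x$country))
  cat(sprintf("  nonadherence %.3f | death SC %.3f / UC %.3f | recurrence SC %.3f / UC %.3f\n",
              x$p_nonadherence, x$p_death["short_course"], x$p_death["usual_care"],
              x$p_recurrence["short_course"], x$p_recurrence["usual_care"]))
  cat(sprintf("  mean age %.1f y | life expectancy %.1f y | discount %.0f%% | WTP $%s/LY\n",
              x$mean_age, x$life_expectancy, 100 * x$discount_rate,
              format(x$lambda, big.mark = ",")))
  invisible(x)
}

# Discounted (possibly utility-weighted) life-years for a death averted in
# this country's average patient.
effect_per_survivor <- function(est) {
  apply_utility_weight(
    discounted_life_years(est$mean_age, est$life_expectancy, est$discount_rate),
    est$utility_weight)
}

# Pathways for one parameter arm (no adherence node): crgnb x recurrence x
# terminal outcome.
arm_pathways <- function(est, param_arm, branch_prob) {
  daily_total <- sum(est$daily_cost[, param_arm])
  eff_alive <- effect_per_survivor(est)
  grid <- expand.grid(crgnb = c(TRUE, FALSE), recurrence = c(TRUE, FALSE),
                      terminal = OUTCOMES, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  p_c <- ifelse(grid$crgnb, est$p_crgnb[param_arm], 1 - est$p_crgnb[param_arm])
  p_r <- ifelse(grid$recurrence, est$p_recurrence[param_arm],
                1 - est$p_recurrence[param_arm])
  p_t <- ifelse(grid$terminal == "death", est$p_death[param_arm],
                1 - est$p_death[param_arm])
  grid$prob <- branch_prob * p_c * p_r * p_t
  grid$cost <- daily_total * est$mean_stay[param_arm, grid$terminal]
  grid$effect <- ifelse(grid$terminal == "death", 0, eff_alive)
  grid
}

#' Enumerate the pathways of the decision tree for one strategy
#'
#' The usual-care strategy branches on carbapenem-resistant infection, then
#' pneumonia recurrence, then the terminal outcome (death or discharged
#' alive): 8 pathways. The short-course strategy first branches on
#' adherence; the nonadherent branch progresses under usual-care parameters
#' (probabilities, stays, and costs), yielding 16 pathways. Pathway cost is
#' the summed per-category daily cost of the parameter arm times the mean
#' stay for the arm and terminal outcome; pathway effect is the discounted
#' life-years gained of the country's average patient if discharged alive,
#' and 0 at death.
#'
#' @param est a [country_estimates()] object.
#' @param strategy `"short_course"` or `"usual_care"`.
#' @return A `data.frame` of pathways with columns `strategy`, `adherent`,
#'   `crgnb`, `recurrence`, `terminal`, `prob`, `cost`, `effect`.
#' @export
enumerate_pathways <- function(est, strategy = ARMS) {
  strategy <- match.arg(strategy)
  validate_country_estimates(est)
  if (strategy == "usual_care") {
    out <- arm_pathways(est, "usual_care", 1)
    out$adherent <- NA
  } else {
    adherent <- arm_pathways(est, "short_course", 1 - est$p_nonadherence)
    adherent$adherent <- TRUE
    nonadh <- arm_pathways(est, "usual_care", est$p_nonadherence)
    nonadh$adherent <- FALSE
    out <- rbind(adherent, nonadh)
  }
  out$strategy <- strategy
  out[, c("strategy", "adherent", "crgnb", "recurrence", "terminal",
          "prob", "cost", "effect")]
}

#' Expected cost and effect of a pathway set
#'
#' @param pathways output of [enumerate_pathways()]; pathway probabilities
#'   must sum to 1.
#' @param tol normalisation tolerance.
#' @return Named numeric vector `c(cost = , effect = )` of
#'   probability-weighted sums.
#' @export
expected_strategy_values <- function(pathways, tol = 1e-9) {
  if (abs(sum(pathways$prob) - 1) > tol)
    model_error("pathway probabilities do not sum to 1")
  c(cost = sum(pathways$prob * pathways$cost),
    effect = sum(pathways$prob * pathways$effect))
}

#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost incremental cost (USD).
#' @param delta_effect incremental effect (life-years).
#' @return `delta_cost / delta_effect`, or `NA` (the undefined-ICER
#'   sentinel) when the incremental effect is zero. A negative ratio is
#'   returned as computed; interpret it through [classify_dominance()].
#' @examples
#' compute_icer(152, 0.14)   # 1085.7 -> prints as 1086
#' compute_icer(-789, 0.13)  # -6069 (a dominant strategy)
#' @export
compute_icer <- function(delta_cost, delta_effect) {
  ifelse(delta_effect == 0, NA_real_, delta_cost / delta_effect)
}

#' Incremental net monetary benefit
#'
#' @param lambda willingness-to-pay threshold (USD per life-year), >= 0.
#' @param delta_effect incremental effect (life-years).
#' @param delta_cost incremental cost (USD).
#' @return `lambda * delta_effect - delta_cost` (USD); positive values mean
#'   the intervention is cost-effective at `lambda`.
#' @export
compute_inmb <- function(lambda, delta_effect, delta_cost) {
  if (any(lambda < 0)) config_error("willingness-to-pay must be >= 0")
  lambda * delta_effect - delta_cost
}

#' Cost-effectiveness plane quadrant / dominance classification
#'
#' @param delta_cost,delta_effect incremental cost and effect of the
#'   intervention vs its comparator.
#' @return `"dominant"` (cheaper and at least as effective, one strictly),
#'   `"dominated"` (the mirror case), `"trade-off NE quadrant"` (more
#'   costly, more effective), `"trade-off SW quadrant"` (cheaper, less
#'   effective), or `"tie"` when both increments are zero.
#' @export
classify_dominance <- function(delta_cost, delta_effect) {
  if (delta_cost == 0 && delta_effect == 0) return("tie")
  if (delta_cost <= 0 && delta_effect >= 0) return("dominant")
  if (delta_cost >= 0 && delta_effect <= 0) return("dominated")
  if (delta_cost > 0) "trade-off NE quadrant" else "trade-off SW quadrant"
}

#' Deterministic cost-effectiveness analysis for one country
#'
#' Rolls back the decision tree for both strategies and reports expected
#' costs, expected (discounted) life-years, the ICER, the incremental net
#' monetary benefit at the country's willingness-to-pay threshold, and the
#' dominance classification of short course vs usual care.
#'
#' @param est a [country_estimates()] object.
#' @return A `cea_result` list.
#' @export
run_cea <- function(est) {
  sc <- expected_strategy_values(enumerate_pathways(est, "short_course"))
  uc <- expected_strategy_values(enumerate_pathways(est, "usual_care"))
  dc <- sc[["cost"]] - uc[["cost"]]
  de <- sc[["effect"]] - uc[["effect"]]
  structure(list(
    country = est$country, lambda = est$lambda,
    cost = c(short_course = sc[["cost"]], usual_care = uc[["cost"]]),
    effect = c(short_course = sc[["effect"]], usual_care = uc[["effect"]]),
    delta_cost = dc, delta_effect = de,
    icer = compute_icer(dc, de),
    inmb = compute_inmb(est$lambda, de, dc),
    dominance = classify_dominance(dc, de)),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness analysis: %s (WTP $%s/LY)\n",
              x$country, format(x$lambda, big.mark = ",")))
  cat(sprintf("  short course: cost $%.0f, effect %.2f LY\n",
              x$cost["short_course"], x$effect["short_course"]))
  cat(sprintf("  usual care:   cost $%.0f, effect %.2f LY\n",
              x$cost["usual_care"], x$effect["usual_care"]))
  cat(sprintf("  incremental:  $%.0f, %.2f LY | ICER %s | INMB $%.0f | %s\n",
              x$delta_cost, x$delta_effect,
              if (is.na(x$icer)) "undefined" else sprintf("$%.0f", x$icer),
              x$inmb, x$dominance))
  invisible(x)
}

#' Serialise country estimates to/from YAML
#'
#' Allows the decision tree and PSA to run standalone from a parameter file
#' without patient-level data.
#'
#' @param est a [country_estimates()] object.
#' @param path file path.
#' @return `read_country_estimates()` returns a validated
#'   `country_estimates`.
#' @export
write_country_estimates <- function(est, path) {
  ser <- unclass(est)
  for (slot in c("p_crgnb", "p_recurrence", "p_death"))
    ser[[slot]] <- as.list(ser[[slot]])   # yaml drops names of atomic vectors
  ser$mean_stay <- list(dim = dim(est$mean_stay), dimnames = dimnames(est$mean_stay),
                        data = as.vector(est$mean_stay))
  ser$daily_cost <- list(dim = dim(est$daily_cost), dimnames = dimnames(est$daily_cost),
                         data = as.vector(est$daily_cost))
  yaml::write_yaml(ser, path)
  invisible(path)
}

#' @rdname write_country_estimates
#' @export
read_country_estimates <- function(path) {
  raw <- yaml::read_yaml(path)
  rebuild <- function(x) array(unlist(x$data), dim = unlist(x$dim), dimnames = x$dimnames)
  country_estimates(
    country = raw$country, p_nonadherence = raw$p_nonadherence,
    p_crgnb = unlist(raw$p_crgnb), p_recurrence = unlist(raw$p_recurrence),
    p_death = unlist(raw$p_death), mean_stay = rebuild(raw$mean_stay),
    daily_cost = rebuild(raw$daily_cost), mean_age = raw$mean_age,
    life_expectancy = raw$life_expectancy, discount_rate = raw$discount_rate,
    lambda = raw$lambda, utility_weight = raw$utility_weight,
    uncertainty = raw$uncertainty)
}
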