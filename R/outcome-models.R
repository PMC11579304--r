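estimation_error <- function(msg) {
  stop(errorCondition(msg, class = c("vapcea_estimation_error", "error", "condition")))
}

#' Country-adjusted logistic regression for a binary outcome
#'
#' Fits a maximum-likelihood logistic regression of a binary outcome (death,
#' pneumonia recurrence, or carbapenem-resistant Gram-negative infection) on
#' arm and country indicators, and returns the predicted probability for
#' every country x arm profile via the inverse logit of the linear
#' predictor.
#'
#' @param records a completed cohort (typically the per-protocol subset, see
#'   [per_protocol_subset()]).
#' @param outcome one of `"died"`, `"recurrence"`, `"crgnb_infection"`.
#' @param covariates model covariates; must include `arm`; `country` is
#'   included whenever the data contain more than one country.
#' @return A `logistic_fit` list: `coefficients`, `vcov`, `probabilities`
#'   (country x arm matrix of predicted probabilities), `n`, and the
#'   country x arm event/total count matrices used downstream for beta
#'   uncertainty distributions.
#' @export
fit_logistic_outcome <- function(records, outcome = c("died", "recurrence",
                                                      "crgnb_infection"),
                                 covariates = c("arm", "country")) {
  outcome <- match.arg(outcome)
  validate_cohort(records)
  y <- records[[outcome]]
  if (length(unique(y)) < 2)
    estimation_error(paste("outcome", outcome, "has a single class; cannot fit"))
  covariates <- intersect(covariates, names(records))
  if (length(unique(records$country)) < 2)
    covariates <- setdiff(covariates, "country")
  if (length(unique(records$arm)) < 2)
    covariates <- setdiff(covariates, "arm")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- withCallingHandlers(
    stats::glm(f, data = records, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        estimation_error(paste("separation detected fitting", outcome))
      invokeRestart("muffleWarning")
    })
  present <- levels(droplevels(records$country))
  grid <- expand.grid(country = factor(present, levels = levels(records$country)),
                      arm = factor(ARMS, levels = ARMS))
  p <- stats::predict(fit, newdata = grid, type = "response")
  probs <- matrix(p, nrow = length(present), ncol = 2,
                  dimnames = list(present, ARMS))
  counts <- table(records$country, records$arm)[present, , drop = FALSE]
  events <- tapply(y, list(records$country, records$arm), sum)[present, , drop = FALSE]
  structure(list(outcome = outcome, coefficients = stats::coef(fit),
                 vcov = stats::vcov(fit), probabilities = probs,
                 n = counts, events = events, model = fit),
            class = "logistic_fit")
}

#' Tobit regression for right-censored length of stay
#'
#' Length of stay from VAP diagnosis to death or discharge is observed only
#' up to the follow-up horizon (60 days): patients still in hospital at the
#' horizon contribute a right-censored observation. The Tobit model is a
#' linear regression under a censored-normal likelihood: an uncensored stay
#' contributes the normal density of its residual, a censored stay the
#' upper-tail probability beyond the bound. Fitted through
#' [survival::survreg()] with a Gaussian error distribution, which maximises
#' exactly this likelihood; with no censored rows it reduces to the ordinary
#' normal MLE.
#'
#' @param records cohort rows to fit (e.g. only patients who died, or only
#'   patients discharged alive).
#' @param covariates regression covariates; `country` is dropped when only
#'   one country is present.
#' @param bound the censoring bound in days.
#' @return A `tobit_fit` list: `coefficients`, `scale` (residual SD, days),
#'   `vcov` (covariance of the coefficients), `loglik`, `bound`, and
#'   `predict(newdata)` giving the linear-predictor mean stay clipped to
#'   (0, bound].
#' @export
fit_tobit_los <- function(records, covariates = c("arm", "country"), bound = 60) {
  validate_cohort(records)
  if (bound <= 0) config_error("censoring bound must be positive")
  event <- !records$censored
  if (!any(event)) estimation_error("all stays are censored; Tobit fit impossible")
  covariates <- intersect(covariates, names(records))
  if (length(unique(droplevels(records$country))) < 2)
    covariates <- setdiff(covariates, "country")
  if (length(unique(droplevels(records$arm))) < 2)
    covariates <- setdiff(covariates, "arm")
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste("survival::Surv(los_days, event) ~", rhs))
  fit <- survival::survreg(f, data = records, dist = "gaussian")
  beta <- stats::coef(fit)
  predict_mean <- function(newdata) {
    mm <- stats::model.matrix(stats::delete.response(stats::terms(fit)),
                              data = newdata)
    mu <- drop(mm %*% beta)
    pmin(pmax(mu, 1e-6), bound)
  }
  vc <- stats::vcov(fit)[seq_along(beta), seq_along(beta), drop = FALSE]
  structure(list(coefficients = beta, scale = fit$scale, vcov = vc,
                 loglik = fit$loglik[2], bound = bound, model = fit,
                 predict = predict_mean),
            class = "tobit_fit")
}

#' Mean daily cost per category, country, and arm
#'
#' Only per-episode cost totals are collected, so the daily cost is derived
#' by dividing each patient's category total by the stay over which costs
#' accrued: `min(los_days, bound)` days (patients not discharged by the
#' horizon accrued costs for exactly `bound` days).
#'
#' @param records completed cohort (no missing cost cells).
#' @param bound the cost-accrual horizon in days.
#' @return A list with `mean`: category x country x arm array of mean daily
#'   costs (USD/day); `se`: matching array of standard errors of the means;
#'   `n`: country x arm counts.
#' @export
estimate_daily_costs <- function(records, bound = 60) {
  validate_cohort(records)
  if (any(records$los_days <= 0)) data_error("los_days must be positive")
  if (anyNA(records[, COST_COLUMNS]))
    data_error("cost cells must be complete (impute first)")
  days <- pmin(records$los_days, bound)
  countries <- levels(droplevels(records$country))
  dims <- list(COST_CATEGORIES, countries, ARMS)
  mean_arr <- array(NA_real_, dim = lengths(dims), dimnames = dims)
  se_arr <- mean_arr
  for (cat in COST_CATEGORIES) {
    daily <- records[[paste0("cost_", cat)]] / days
    for (co in countries) for (arm in ARMS) {
      v <- daily[records$country == co & records$arm == arm]
      if (length(v)) {
        mean_arr[cat, co, arm] <- mean(v)
        se_arr[cat, co, arm] <- stats::sd(v) / sqrt(length(v))
      }
    }
  }
  n <- table(records$country, records$arm)[countries, , drop = FALSE]
  list(mean = mean_arr, se = se_arr, n = n)
}

#' Nonadherence probability from ITT and per-protocol counts
#'
#' The probability that a short-course patient does not receive the complete
#' short-course strategy is the relative shortfall of the per-protocol
#' population: (n_itt - n_pp) / n_itt.
#'
#' @param n_itt_short short-course patients in the intention-to-treat set.
#' @param n_pp_short short-course patients in the per-protocol set.
#' @return The nonadherence probability in \[0, 1).
#' @examples
#' estimate_adherence(231, 211)  # 20/231, about 0.087
#' @export
estimate_adherence <- function(n_itt_short, n_pp_short) {
  if (n_pp_short <= 0 || n_pp_short > n_itt_short)
    data_error("need 0 < n_pp_short <= n_itt_short")
  (n_itt_short - n_pp_short) / n_itt_short
}

#' Discounted life-years gained from a death averted
#'
#' A death averted yields the remaining life expectancy L = life expectancy
#' of an average person in the country minus the patient's age at admission.
#' Future life-years are discounted at an annual rate r, giving the annuity
#' present value (1 - (1+r)^-L) / r (and L itself when r = 0).
#'
#' @param age age at admission, years.
#' @param life_expectancy country life expectancy, years.
#' @param rate annual discount rate in \[0, 1).
#' @return Discounted life-years gained (0, with a warning, if `age`
#'   exceeds `life_expectancy`).
#' @examples
#' discounted_life_years(60, 70, 0.03)  # (1 - 1.03^-10)/0.03 = 8.5302
#' @export
discounted_life_years <- function(age, life_expectancy, rate = 0.03) {
  if (!is.finite(rate) || rate < 0 || rate >= 1)
    config_error("discount rate must lie in [0, 1)")
  L <- life_expectancy - age
  if (any(L < 0)) {
    warning("age exceeds life expectancy; life-years gained set to 0")
    L <- pmax(L, 0)
  }
  if (rate == 0) L else (1 - (1 + rate)^(-L)) / rate
}

#' Apply a health-state utility weight to life-years
#'
#' @param life_years (discounted) life-years gained.
#' @param u utility weight in \[0, 1\].
#' @return Quality-adjusted life-years u * life_years.
#' @export
apply_utility_weight <- function(life_years, u) {
  if (!is.finite(u) || u < 0 || u > 1)
    config_error("utility weight must lie in [0, 1]")
  u * life_years
}

#' Per-protocol subset of a cohort
#'
#' Usual-care patients plus adherent short-course patients. Model inputs are
#' estimated on this subset; nonadherent short-course patients are handled
#' structurally by the adherence chance node of the decision tree.
#'
#' @param records a cohort.
#' @return The per-protocol rows.
#' @export
per_protocol_subset <- function(records) {
  validate_cohort(records)
  keep <- records$arm == "usual_care" |
    (records$arm == "short_course" & records$adhered %in% TRUE)
  records[keep, , drop = FALSE]
}
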