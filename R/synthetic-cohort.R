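# Truncated-distribution samplers via inverse CDF (exact, vectorised).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

rtruncgamma <- function(n, mean, shape, lo = 0, hi = Inf) {
  scale <- mean / shape
  plo <- pgamma(lo, shape, scale = scale)
  phi <- pgamma(hi, shape, scale = scale)
  qgamma(runif(n, plo, phi), shape, scale = scale)
}

#' Generate a synthetic patient-level trial cohort
#'
#' Simulates one patient record per enrolled participant under the study
#' conditions in a [trial_config()]: two arms per country, Bernoulli event
#' outcomes at the configured country- and arm-specific probabilities,
#' gamma-distributed stays (truncated below at 1 day) right-censored at the
#' horizon, and per-category costs generated as a gamma daily rate times the
#' observed stay, so that total cost divided by observed stay recovers the
#' daily rate exactly. Nonadherent short-course patients are simulated under
#' the usual-care event, stay, and cost parameters (their disease course is
#' assumed to follow usual care). Death stays are drawn within the horizon,
#' so a record is censored (in hospital at the horizon) only if alive.
#'
#' @param config a [trial_config()].
#' @param seed RNG seed; defaults to `config$seed`. The same configuration
#'   and seed reproduce the cohort exactly.
#' @return A `data.frame` with one row per patient: `patient_id`, `country`,
#'   `arm`, `age`, `adhered` (NA for usual care), `crgnb_infection`,
#'   `recurrence`, `died`, `los_days`, `censored`, and the four cost totals
#'   `cost_bed`, `cost_pharma`, `cost_diagnostics`, `cost_consumables`.
#' @export
generate_cohort <- function(config, seed = config$seed) {
  validate_trial_config(config)
  set.seed(seed)
  blocks <- list()
  for (co in COUNTRIES) {
    for (arm in ARMS) {
      n <- config$n_per_arm[[co]]
      adhered <- if (arm == "short_course")
        runif(n) >= config$p_nonadherence else rep(NA, n)
      # effective parameter arm: nonadherent short-course -> usual care
      eff <- if (arm == "short_course")
        ifelse(adhered, "short_course", "usual_care") else rep("usual_care", n)
      age <- rtruncnorm(n, config$age_mean[[co]], config$age_sd,
                        config$age_min, config$age_max)
      crgnb <- runif(n) < config$p_crgnb[co, eff]
      recurrence <- runif(n) < config$p_recurrence[co, eff]
      died <- runif(n) < config$p_death[co, eff]
      los <- numeric(n)
      mu_death <- config$los_mean[cbind(co, eff, "death")]
      mu_alive <- config$los_mean[cbind(co, eff, "discharged_alive")]
      # draw both streams to keep the RNG sequence independent of outcomes
      draw_death <- rtruncgamma(n, mu_death, config$los_shape, 1, config$horizon)
      draw_alive <- rtruncgamma(n, mu_alive, config$los_shape, 1, Inf)
      los <- ifelse(died, draw_death, draw_alive)
      censored <- !died & los >= config$horizon
      los <- pmin(los, config$horizon)
      costs <- sapply(COST_CATEGORIES, function(cat) {
        daily <- rtruncgamma(n, config$daily_cost_mean[cbind(co, eff, cat)],
                             config$daily_cost_shape)
        daily * los
      })
      colnames(costs) <- COST_COLUMNS
      blocks[[paste(co, arm)]] <- data.frame(
        country = co, arm = arm, age = age, adhered = adhered,
        crgnb_infection = crgnb, recurrence = recurrence, died = died,
        los_days = los, censored = censored, costs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$country <- factor(out$country, levels = COUNTRIES)
  out$arm <- factor(out$arm, levels = ARMS)
  out <- cbind(patient_id = sprintf("P%04d", seq_len(nrow(out))), out)
  out
}

validate_cohort <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  need <- c("country", "arm", "died", "los_days", "censored", COST_COLUMNS)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    data_error(paste("cohort is missing columns:",
                     paste(missing_cols, collapse = ", ")))
  if (any(records$los_days <= 0, na.rm = TRUE))
    data_error("los_days must be positive")
  if (any(records$censored & records$died))
    data_error("a censored record cannot also be a death")
  invisible(records)
}

#' Mask cost cells under a missing-at-random mechanism
#'
#' Each of the four cost cells is independently set to `NA` with a
#' row-specific probability from a logistic model on observed covariates
#' (country, arm, vital status), whose intercept is calibrated numerically
#' so that the expected masked fraction equals `rate`. Outcome, stay, and
#' covariate columns are never masked.
#'
#' @param records a cohort from [generate_cohort()].
#' @param rate target expected fraction of masked cost cells, in \[0, 1).
#' @param seed RNG seed.
#' @param coef named list of log-odds shifts for `died`, `short_course`, and
#'   per-country offsets, defining the MAR dependence on observables.
#' @return The cohort with some cost cells set to `NA`.
#' @export
apply_missingness <- function(records, rate, seed = 1L,
                              coef = list(died = 0.4, short_course = 0.2,
                                          country = c(Nepal = 0.15, Singapore = -0.15,
                                                      Thailand = 0))) {
  validate_cohort(records)
  if (!is.finite(rate) || rate < 0 || rate >= 1)
    config_error("missingness rate must lie in [0, 1)")
  if (rate == 0) return(records)
  lp <- coef$died * records$died +
    coef$short_course * (records$arm == "short_course") +
    coef$country[as.character(records$country)]
  intercept <- uniroot(function(b0) mean(plogis(b0 + lp)) - rate,
                       interval = c(-30, 30))$root
  p_row <- plogis(intercept + lp)
  set.seed(seed)
  for (col in COST_COLUMNS) {
    mask <- runif(nrow(records)) < p_row
    records[[col]][mask] <- NA_real_
  }
  records
}

#' Summarise a cohort by country and arm
#'
#' @param records a cohort `data.frame`.
#' @return A `data.frame` with one row per country x arm: patient count,
#'   event proportions, nonadherence proportion (short course only), mean
#'   stay, censoring proportion, and mean observed cost per category
#'   (missing cells ignored).
#' @export
cohort_summary <- function(records) {
  validate_cohort(records)
  groups <- split(records, list(records$country, records$arm), drop = FALSE, sep = "|")
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    if (nrow(g) == 0) return(NULL)
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    base <- data.frame(
      country = parts[1], arm = parts[2], n = nrow(g),
      p_nonadherence = if (parts[2] == "short_course")
        mean(!g$adhered) else NA_real_,
      p_crgnb = mean(g$crgnb_infection),
      p_recurrence = mean(g$recurrence),
      p_death = mean(g$died),
      p_censored = mean(g$censored),
      mean_los = mean(g$los_days),
      stringsAsFactors = FALSE)
    for (col in COST_COLUMNS)
      base[[paste0("mean_", col)]] <- mean(g[[col]], na.rm = TRUE)
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read or write a cohort as CSV
#'
#' One row per patient, header as produced by [generate_cohort()]; missing
#' cost cells are written as empty fields.
#'
#' @param records a cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort()` returns the cohort with factor and logical
#'   columns restored.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  out$country <- factor(out$country, levels = COUNTRIES)
  out$arm <- factor(out$arm, levels = ARMS)
  for (col in c("adhered", "crgnb_infection", "recurrence", "died", "censored"))
    out[[col]] <- as.logical(out[[col]])
  validate_cohort(out)
  out
}
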