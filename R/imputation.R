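#' Imputation configuration
#'
#' @param method imputation method: predictive mean matching within chained
#'   equations (`"pmm"`, the primary analysis), random-forest chained
#'   imputation (`"random_forest"`), within-cell mean substitution
#'   (`"simple_mean"`), or dropping incomplete rows (`"complete_case"`).
#' @param m number of imputed datasets (10 for the primary analysis,
#'   matching roughly 10\% missing cost data).
#' @param pmm_donors donor-pool size for predictive mean matching.
#' @param chained_iterations sweeps of the chained-equation cycle per
#'   imputed dataset.
#' @param predictors columns used to predict each cost column (the other
#'   three cost columns are always added as chained predictors).
#' @param rf_trees trees per random forest in the `"random_forest"` method.
#' @param seed RNG seed.
#' @return An `imputation_config` list.
#' @export
imputation_config <- function(method = c("pmm", "random_forest", "simple_mean",
                                         "complete_case"),
                              m = 10L, pmm_donors = 5L, chained_iterations = 10L,
                              predictors = c("country", "arm", "age", "died",
                                             "recurrence", "los_days"),
                              rf_trees = 10L, seed = 1L) {
  method <- match.arg(method)
  if (m < 1) config_error("number of imputations m must be >= 1")
  if (pmm_donors < 1) config_error("pmm_donors must be >= 1")
  if (chained_iterations < 1) config_error("chained_iterations must be >= 1")
  structure(list(method = method, m = as.integer(m),
                 pmm_donors = as.integer(pmm_donors),
                 chained_iterations = as.integer(chained_iterations),
                 predictors = predictors, rf_trees = as.integer(rf_trees),
                 seed = as.integer(seed)),
            class = "imputation_config")
}

# Design matrix of the fully observed predictors (factors expanded).
impute_design <- function(records, predictors) {
  predictors <- intersect(predictors, names(records))
  f <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  stats::model.matrix(f, data = records)
}

# One Bayesian-draw PMM update of column `col` given design X (mice's
# type-1 matching: observed predictions use the least-squares coefficients,
# missing-row predictions use a posterior draw).
pmm_update <- function(y, miss, X, k) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  qrX <- qr(Xo)
  keep <- qrX$pivot[seq_len(qrX$rank)]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- X[miss, keep, drop = FALSE]
  fit <- stats::lm.fit(Xo, yo)
  beta_hat <- fit$coefficients
  res <- fit$residuals
  df <- max(length(yo) - ncol(Xo), 1)
  sigma2_star <- sum(res^2) / stats::rchisq(1, df)
  xtx_inv <- chol2inv(qr.R(qr(Xo)))
  beta_star <- beta_hat +
    drop(t(chol(sigma2_star * xtx_inv + diag(1e-12, ncol(Xo)))) %*%
           stats::rnorm(ncol(Xo)))
  yhat_obs <- drop(Xo %*% beta_hat)
  yhat_mis <- drop(Xm %*% beta_star)
  vapply(yhat_mis, function(pred) {
    d <- abs(yhat_obs - pred)
    donors <- order(d, stats::runif(length(d)))[seq_len(min(k, length(d)))]
    yo[donors[sample.int(length(donors), 1)]]
  }, numeric(1))
}

# Random-forest update: fit on observed rows, then impute each missing row
# with an observed value drawn from the terminal node of a random tree.
rf_update <- function(y, miss, X, ntree) {
  Xo <- X[!miss, , drop = FALSE]
  yo <- y[!miss]
  Xm <- X[miss, , drop = FALSE]
  fit <- randomForest::randomForest(x = Xo, y = yo, ntree = ntree)
  nodes_obs <- attr(stats::predict(fit, Xo, nodes = TRUE), "nodes")
  nodes_mis <- attr(stats::predict(fit, Xm, nodes = TRUE), "nodes")
  vapply(seq_len(nrow(Xm)), function(i) {
    tree <- sample.int(ntree, 1)
    donors <- yo[nodes_obs[, tree] == nodes_mis[i, tree]]
    if (length(donors) == 0) donors <- yo
    donors[sample.int(length(donors), 1)]
  }, numeric(1))
}

chained_impute <- function(records, config, update_fun) {
  validate_cohort(records)
  miss <- is.na(records[, COST_COLUMNS, drop = FALSE])
  cols_with_missing <- COST_COLUMNS[colSums(miss) > 0]
  for (col in COST_COLUMNS)
    if (all(is.na(records[[col]])))
      data_error(paste("cost column", col, "has no observed values"))
  set.seed(config$seed)
  base_design <- impute_design(records, config$predictors)
  out <- vector("list", config$m)
  for (d in seq_len(config$m)) {
    work <- records
    for (col in cols_with_missing) {   # initialise from observed support
      obs <- work[[col]][!is.na(work[[col]])]
      work[[col]][is.na(work[[col]])] <- sample(obs, sum(is.na(work[[col]])),
                                                replace = TRUE)
    }
    if (length(cols_with_missing)) {
      for (sweep in seq_len(config$chained_iterations)) {
        for (col in cols_with_missing) {
          others <- setdiff(COST_COLUMNS, col)
          X <- cbind(base_design, as.matrix(work[, others, drop = FALSE]))
          y <- records[[col]]            # true missingness pattern
          y[is.na(y)] <- work[[col]][is.na(records[[col]])]
          work[[col]][miss[, col]] <- update_fun(y, miss[, col], X, config)
        }
      }
    }
    out[[d]] <- work
  }
  class(out) <- "imputed_datasets"
  attr(out, "method") <- config$method
  out
}

#' Multiple imputation of costs by chained equations with PMM
#'
#' For each of `m` datasets, missing cost cells are initialised from the
#' observed support and then updated over chained sweeps: each cost column
#' in turn is regressed on the covariates plus the other three (current)
#' cost columns, regression parameters are drawn from their approximate
#' posterior, and every missing cell receives the observed value of a donor
#' drawn at random from the `pmm_donors` observed rows whose predicted
#' values lie closest to the missing row's prediction. Imputed values are
#' therefore always members of the column's observed support, which keeps
#' the imputations within the skewed, non-negative cost distribution.
#'
#' @param records cohort with possibly missing cost cells.
#' @param config an [imputation_config()].
#' @return An `imputed_datasets` list of `m` completed cohorts, identical to
#'   `records` except in originally missing cost cells.
#' @export
mice_pmm <- function(records, config = imputation_config()) {
  chained_impute(records, config,
                 function(y, miss, X, cfg) pmm_update(y, miss, X, cfg$pmm_donors))
}

#' Multiple imputation of costs by chained random forests
#'
#' As [mice_pmm()], but the conditional model for each cost column is a
#' random forest and each missing cell is imputed with an observed value
#' drawn from the terminal node (of a randomly chosen tree) into which the
#' missing row falls.
#'
#' @inheritParams mice_pmm
#' @export
random_forest_impute <- function(records, config = imputation_config(method = "random_forest")) {
  chained_impute(records, config,
                 function(y, miss, X, cfg) rf_update(y, miss, X, cfg$rf_trees))
}

#' Single imputation by within-cell means
#'
#' Replaces each missing cost cell by the mean of the observed values of the
#' same cost column within the same country x arm cell.
#'
#' @param records cohort with possibly missing cost cells.
#' @return One completed cohort.
#' @export
simple_impute <- function(records) {
  validate_cohort(records)
  for (col in COST_COLUMNS) {
    if (all(is.na(records[[col]])))
      data_error(paste("cost column", col, "has no observed values"))
    cell_mean <- stats::ave(records[[col]],
                            records$country, records$arm,
                            FUN = function(v) mean(v, na.rm = TRUE))
    idx <- is.na(records[[col]])
    records[[col]][idx] <- cell_mean[idx]
  }
  records
}

#' Drop rows with any missing cost cell
#'
#' @param records cohort with possibly missing cost cells.
#' @return The subset of rows with all four cost categories observed, in the
#'   original order; warns if no complete rows remain.
#' @export
complete_case_filter <- function(records) {
  validate_cohort(records)
  keep <- stats::complete.cases(records[, COST_COLUMNS, drop = FALSE])
  if (!any(keep)) warning("no complete cases remain after filtering")
  records[keep, , drop = FALSE]
}

#' Pool estimates across imputed datasets by Rubin's rule
#'
#' @param estimates per-dataset point estimates (length m).
#' @param variances per-dataset squared standard errors (length m).
#' @param conf confidence level for the normal-approximation interval.
#' @return A `pooled_estimate` list: `estimate` (mean of the estimates),
#'   `within` (mean within-imputation variance), `between` (sample variance
#'   of the estimates), `total` = within + (1 + 1/m) between, `ci` and `m`.
#' @examples
#' rubins_pool(c(1, 2, 3), c(1, 1, 1))  # estimate 2, total variance 2.333
#' @export
rubins_pool <- function(estimates, variances, conf = 0.95) {
  if (length(estimates) != length(variances))
    data_error("estimates and variances must have equal length")
  if (any(variances < 0)) data_error("variances must be >= 0")
  m <- length(estimates)
  if (m < 1) data_error("need at least one estimate")
  point <- mean(estimates)
  within <- mean(variances)
  between <- if (m > 1) stats::var(estimates) else 0
  total <- within + (1 + 1 / m) * between
  z <- stats::qnorm(1 - (1 - conf) / 2)
  structure(list(estimate = point, within = within, between = between,
                 total = total, m = m,
                 ci = c(point - z * sqrt(total), point + z * sqrt(total))),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate (m = %d): %.4g (95%% CI %.4g to %.4g)\n",
              x$m, x$estimate, x$ci[1], x$ci[2]))
  cat(sprintf("  variance: within %.4g, between %.4g, total %.4g\n",
              x$within, x$between, x$total))
  invisible(x)
}

#' Dispatch an imputation method by name
#'
#' @param records cohort with possibly missing cost cells.
#' @param config an [imputation_config()]; `method` selects the routine.
#' @return A list of completed datasets (length `m` for the multiple
#'   imputation methods, 1 for `simple_mean` and `complete_case`).
#' @export
impute_costs <- function(records, config = imputation_config()) {
  switch(config$method,
         pmm = mice_pmm(records, config),
         random_forest = random_forest_impute(records, config),
         simple_mean = structure(list(simple_impute(records)),
                                 class = "imputed_datasets", method = "simple_mean"),
         complete_case = structure(list(complete_case_filter(records)),
                                   class = "imputed_datasets", method = "complete_case"))
}
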