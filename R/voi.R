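#' Expected value of perfect information
#'
#' From a matrix of per-draw net monetary benefits (one column per
#' strategy), the EVPI is the expected NMB of deciding with perfect
#' information minus the expected NMB of the best decision under current
#' information: mean of the row-wise maximum minus the maximum of the
#' column means. Reported per patient, in USD.
#'
#' @param nmb_matrix n x k matrix of NMB draws (k >= 2 strategies).
#' @return EVPI in USD per patient (non-negative up to floating error).
#' @export
evpi <- function(nmb_matrix) {
  nmb_matrix <- as.matrix(nmb_matrix)
  if (ncol(nmb_matrix) < 2) data_error("EVPI needs at least two strategies")
  if (nrow(nmb_matrix) < 2) data_error("EVPI needs at least two draws")
  mean(apply(nmb_matrix, 1, max)) - max(colMeans(nmb_matrix))
}

# NMB matrix (usual care, short course) from PSA output. NMB is defined up
# to a per-draw constant shared by both strategies; using (0, lambda*de-dc)
# leaves EVPI/EVPPI unchanged and matches the incremental scale reported.
psa_nmb_matrix <- function(psa) {
  cbind(usual_care = 0, short_course = psa$results$inmb)
}

# Flexible conditional-mean smoother of y on the columns of phi: thin-plate
# spline GAM (REML) for small groups, second-order polynomial regression
# for larger ones where a multidimensional smooth is impractical.
fit_voi_smoother <- function(y, phi) {
  phi <- as.matrix(phi)
  keep <- apply(phi, 2, function(v) stats::sd(v) > 0)
  if (!any(keep)) return(rep(mean(y), length(y)))
  phi <- phi[, keep, drop = FALSE]
  colnames(phi) <- paste0("x", seq_len(ncol(phi)))
  df <- data.frame(y = y, phi)
  if (ncol(phi) <= 4) {
    k <- max(4, min(10, floor(length(y)^(1 / 3))))
    terms <- paste(sprintf("s(%s, k = %d)", colnames(phi), k), collapse = " + ")
    # near-interpolating fits can halt REML stepping; the fit is still usable
    fit <- suppressWarnings(
      mgcv::gam(stats::as.formula(paste("y ~", terms)), data = df,
                method = "REML"))
  } else {
    main <- paste(colnames(phi), collapse = " + ")
    sq <- paste(sprintf("I(%s^2)", colnames(phi)), collapse = " + ")
    fit <- stats::lm(stats::as.formula(
      paste("y ~ (", main, ")^2 +", sq)), data = df)
  }
  as.numeric(stats::fitted(fit))
}

#' Regression-based EVPPI for a parameter group
#'
#' Single-loop estimator: each strategy's NMB draws are regressed on the
#' group's parameter draws with a flexible smoother (an additive
#' thin-plate-spline GAM with REML smoothness selection for groups of up to
#' four parameters; a second-order polynomial-interaction regression for
#' larger groups). The fitted values estimate the conditional expected NMB
#' given the group, and EVPPI is the mean of their row-wise maximum minus
#' the maximum of their column means, clipped below at zero. A bootstrap
#' over draws (with refitting) supplies the standard error.
#'
#' @param nmb_matrix n x k matrix of per-draw NMB per strategy.
#' @param phi n x p matrix (or vector) of the group's parameter draws,
#'   row-aligned with `nmb_matrix`.
#' @param n_boot bootstrap replicates for the standard error (0 skips it).
#' @param seed RNG seed for the bootstrap.
#' @return A list: `evppi` (USD per patient), `se` (bootstrap SE or `NA`),
#'   `clipped` (`TRUE` if a negative raw estimate was clipped to 0).
#' @export
evppi_regression <- function(nmb_matrix, phi, n_boot = 0L, seed = 1L) {
  nmb_matrix <- as.matrix(nmb_matrix)
  phi <- as.matrix(phi)
  if (nrow(phi) != nrow(nmb_matrix))
    data_error("NMB and parameter draws must be row-aligned")
  if (all(apply(phi, 2, function(v) stats::sd(v) == 0)))
    return(list(evppi = 0, se = 0, clipped = FALSE,
                note = "constant parameter group"))
  point_est <- function(nmb, ph) {
    fitted <- sapply(seq_len(ncol(nmb)), function(j) {
      col <- nmb[, j]
      if (stats::sd(col) == 0) rep(col[1], nrow(nmb))
      else fit_voi_smoother(col, ph)
    })
    mean(apply(fitted, 1, max)) - max(colMeans(fitted))
  }
  raw <- point_est(nmb_matrix, phi)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(seed)
    boots <- replicate(n_boot, {
      idx <- sample.int(nrow(nmb_matrix), replace = TRUE)
      point_est(nmb_matrix[idx, , drop = FALSE], phi[idx, , drop = FALSE])
    })
    se <- stats::sd(boots)
  }
  list(evppi = max(raw, 0), se = se, clipped = raw < 0)
}

#' Nested two-level Monte Carlo EVPPI (reference estimator)
#'
#' Brute-force estimator used to validate [evppi_regression()]: for each
#' outer draw of the group parameters, an inner sample of the remaining
#' parameters gives the conditional expected NMB per strategy; EVPPI is the
#' mean over outer draws of the best conditional NMB, minus the best
#' overall expected NMB. Parameters are sampled independently, so the
#' conditional sampler of the complement is its marginal sampler.
#'
#' @param nmb_fun function `(phi_row, theta_matrix) -> n_inner x k` NMB
#'   matrix for one outer value of the group and a matrix of inner draws of
#'   the complementary parameters.
#' @param sample_phi function `n -> n x p` matrix of group draws.
#' @param sample_theta function `n -> n x q` matrix of complement draws.
#' @param n_outer,n_inner outer and inner Monte Carlo sizes (`n_inner >= 2`).
#' @param seed RNG seed.
#' @return A list: `evppi`, `se` (outer-loop Monte Carlo SE).
#' @export
evppi_nested_mc <- function(nmb_fun, sample_phi, sample_theta,
                            n_outer = 200L, n_inner = 200L, seed = 1L) {
  if (n_inner < 2) config_error("n_inner must be >= 2")
  set.seed(seed)
  phi <- as.matrix(sample_phi(n_outer))
  cond_best <- numeric(n_outer)
  overall <- NULL
  for (i in seq_len(n_outer)) {
    theta <- as.matrix(sample_theta(n_inner))
    nmb <- as.matrix(nmb_fun(phi[i, ], theta))
    cm <- colMeans(nmb)
    cond_best[i] <- max(cm)
    overall <- if (is.null(overall)) cm else overall + cm
  }
  overall <- overall / n_outer
  ev <- mean(cond_best) - max(overall)
  list(evppi = max(ev, 0), se = stats::sd(cond_best) / sqrt(n_outer))
}

#' The eight parameter groups of the value-of-information analysis
#'
#' Maps each group name to the parameter names of the PSA distribution
#' table: adherence probability, recurrence probabilities,
#' carbapenem-resistant infection probabilities, mortality probabilities,
#' lengths of stay, bed-day costs, variable costs (pharmaceuticals,
#' diagnostics, consumables), and age at admission.
#'
#' @param dists a distribution table from [parameter_distributions()].
#' @return Named list of character vectors of parameter names.
#' @export
voi_parameter_groups <- function(dists) {
  groups <- c("adherence", "recurrence", "crgnb", "mortality", "los",
              "bed_cost", "variable_cost", "age")
  lapply(stats::setNames(nm = groups),
         function(g) dists$name[dists$group == g])
}

#' Value-of-information analysis for one country
#'
#' Computes the per-patient EVPI from the PSA NMB draws and the
#' regression-based EVPPI for each of the eight parameter groups.
#'
#' @param psa a `psa_results` object from [run_psa()].
#' @param n_boot bootstrap replicates per EVPPI standard error.
#' @param seed RNG seed for the bootstrap.
#' @return A `voi_result` list: `country`, `evpi`, and `evppi` (a
#'   `data.frame` with `group`, `evppi`, `se`, `clipped`).
#' @export
voi_analysis <- function(psa, n_boot = 0L, seed = 1L) {
  nmb <- psa_nmb_matrix(psa)
  groups <- voi_parameter_groups(psa$dists)
  rows <- lapply(names(groups), function(g) {
    cols <- intersect(groups[[g]], colnames(psa$draws))
    if (length(cols) == 0)
      return(data.frame(group = g, evppi = 0, se = 0, clipped = FALSE))
    r <- evppi_regression(nmb, psa$draws[, cols, drop = FALSE],
                          n_boot = n_boot, seed = seed)
    data.frame(group = g, evppi = r$evppi, se = r$se, clipped = r$clipped)
  })
  structure(list(country = psa$country, evpi = evpi(nmb),
                 evppi = do.call(rbind, rows),
                 n = nrow(psa$results), seed = seed),
            class = "voi_result")
}

#' @export
print.voi_result <- function(x, ...) {
  cat(sprintf("Value of information: %s (n = %d PSA draws)\n", x$country, x$n))
  cat(sprintf("  EVPI: $%.0f per patient\n", x$evpi))
  for (i in seq_len(nrow(x$evppi)))
    cat(sprintf("  EVPPI %-14s $%.0f\n", x$evppi$group[i], x$evppi$evppi[i]))
  invisible(x)
}
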