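#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()].
#'
#' @param trial a [trial_config()] for the synthetic cohort.
#' @param imputation an [imputation_config()].
#' @param settings base-case [analysis_settings()].
#' @param constants per-country constants (list of [country_constants()]).
#' @param psa_n total PSA iterations per country.
#' @param voi_boot bootstrap replicates per EVPPI standard error.
#' @param run_scenarios if `TRUE`, also run the nine scenario analyses.
#' @param scenario_psa_n PSA iterations per scenario and country.
#' @param seed master seed; stage seeds are derived from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trial = trial_config(),
                            imputation = imputation_config(),
                            settings = analysis_settings(),
                            constants = lapply(stats::setNames(nm = COUNTRIES),
                                               country_constants),
                            psa_n = 1000L, voi_boot = 0L,
                            run_scenarios = FALSE, scenario_psa_n = 500L,
                            seed = 1L) {
  structure(list(trial = trial, imputation = imputation, settings = settings,
                 constants = constants, psa_n = as.integer(psa_n),
                 voi_boot = as.integer(voi_boot),
                 run_scenarios = run_scenarios,
                 scenario_psa_n = as.integer(scenario_psa_n),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Stable hash of any R object (MD5 of its canonical serialisation),
# recorded in every artifact for provenance.
config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(x, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_log <- function(messages, text) {
  c(messages, paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), " ", text))
}

#' Run the full economic-evaluation pipeline
#'
#' Executes generate -> mask -> impute (m datasets) -> estimate inputs per
#' dataset -> deterministic decision tree + PSA per dataset -> Rubin-pooled
#' cost-effectiveness summaries -> value-of-information analysis (and,
#' optionally, the nine scenario analyses), all driven by a single
#' [pipeline_config()]. Every returned bundle carries the configuration
#' hash and master seed; identical configurations reproduce identical
#' bundles.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_result` list: `cohort` (masked), `summary` (cohort
#'   summary table), `countries` (per-country CEA, Rubin-pooled increments,
#'   stacked PSA, CEAC, VoI), `table1` (base-case table), `scenarios`
#'   (scenario table or `NULL`), `log`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- character()
  hash <- config_hash(config)
  log <- pipeline_log(log, paste("config hash", hash))

  cohort <- generate_cohort(config$trial, seed = config$seed)
  log <- pipeline_log(log, sprintf("generated %d patients", nrow(cohort)))
  masked <- apply_missingness(cohort, config$trial$missing_rate,
                              seed = config$seed + 1L)
  n_missing <- sum(is.na(masked[, COST_COLUMNS]))
  log <- pipeline_log(log, sprintf("masked %d cost cells (%.1f%%)", n_missing,
                                   100 * n_missing / (4 * nrow(masked))))

  imp <- config$imputation
  imp$seed <- config$seed + 2L
  res <- run_configured_analysis(masked, config$settings, config$constants,
                                 imp, psa_n = config$psa_n,
                                 seed = config$seed + 3L)
  log <- pipeline_log(log, sprintf(
    "analysed %d countries (%d PSA iterations each, %d rejected draws)",
    length(res), config$psa_n,
    sum(vapply(res, function(r) r$psa$n_rejected, integer(1)))))

  countries <- lapply(res, function(r) {
    r$ceac <- ceac_curve(r$psa)
    r$voi <- voi_analysis(r$psa, n_boot = config$voi_boot,
                          seed = config$seed + 4L)
    r$prob_cost_effective <- mean(r$psa$results$inmb > 0)
    r$prob_cost_saving <- prob_cost_saving(r$psa)
    r
  })

  table1 <- do.call(rbind, lapply(countries, function(r) {
    ui <- summarize_ui(r$psa)
    data.frame(
      country = r$country,
      cost_sc = r$cea$cost[["short_course"]],
      cost_uc = r$cea$cost[["usual_care"]],
      effect_sc = r$cea$effect[["short_course"]],
      effect_uc = r$cea$effect[["usual_care"]],
      delta_cost = r$pooled_delta_cost$estimate,
      delta_cost_lo = ui$delta_cost[["lo"]],
      delta_cost_hi = ui$delta_cost[["hi"]],
      delta_effect = r$pooled_delta_effect$estimate,
      delta_effect_lo = ui$delta_effect[["lo"]],
      delta_effect_hi = ui$delta_effect[["hi"]],
      inmb = r$pooled_inmb$estimate,
      icer = compute_icer(r$pooled_delta_cost$estimate,
                          r$pooled_delta_effect$estimate),
      dominance = classify_dominance(r$pooled_delta_cost$estimate,
                                     r$pooled_delta_effect$estimate),
      pct_cost_effective = 100 * r$prob_cost_effective,
      stringsAsFactors = FALSE)
  }))
  rownames(table1) <- NULL

  scenarios <- NULL
  if (config$run_scenarios) {
    scenarios <- run_all_scenarios(masked, config$constants, config$settings,
                                   imp, psa_n = config$scenario_psa_n,
                                   seed = config$seed + 5L)
    log <- pipeline_log(log, sprintf("ran %d scenario rows", nrow(scenarios)))
  }

  structure(list(cohort = masked, summary = cohort_summary(masked),
                 countries = countries, table1 = table1,
                 scenarios = scenarios, log = log,
                 config_hash = hash, seed = config$seed),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Economic-evaluation pipeline result\n")
  cat("  config hash:", x$config_hash, "| seed:", x$seed, "\n")
  cat(sprintf("  cohort: %d patients\n", nrow(x$cohort)))
  tab <- x$table1
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-9s dCost $%7.0f  dLY %5.2f  ICER %s  INMB $%7.0f  P(CE) %4.1f%%\n",
                tab$country[i], tab$delta_cost[i], tab$delta_effect[i],
                if (is.na(tab$icer[i])) "undefined"
                else sprintf("$%.0f", tab$icer[i]),
                tab$inmb[i], tab$pct_cost_effective[i]))
  invisible(x)
}

#' Export pipeline artifacts to a directory
#'
#' Writes the masked cohort CSV, the base-case table CSV, per-country CEAC
#' and PSA CSVs with JSON summaries, the VoI table, the scenario table (if
#' present), and the plain-text log. Every file name is prefixed so the
#' directory is self-describing; every JSON summary carries the config
#' hash and seed.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
export_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(name) { files <<- c(files, file.path(dir, name)); tail(files, 1) }
  write_cohort(result$cohort, w("cohort.csv"))
  utils::write.csv(result$table1, w("table1.csv"), row.names = FALSE)
  voi_rows <- list()
  for (co in names(result$countries)) {
    r <- result$countries[[co]]
    utils::write.csv(r$ceac, w(paste0("ceac_", co, ".csv")), row.names = FALSE)
    write_psa_results(r$psa, csv_path = w(paste0("psa_", co, ".csv")),
                      json_path = w(paste0("psa_", co, ".json")))
    voi_rows[[co]] <- cbind(country = co, r$voi$evppi,
                            evpi = r$voi$evpi)
  }
  utils::write.csv(do.call(rbind, voi_rows), w("voi.csv"), row.names = FALSE)
  if (!is.null(result$scenarios))
    utils::write.csv(result$scenarios, w("scenarios.csv"), row.names = FALSE)
  writeLines(c(paste("config hash:", result$config_hash),
               paste("seed:", result$seed), result$log), w("pipeline.log"))
  invisible(files)
}
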