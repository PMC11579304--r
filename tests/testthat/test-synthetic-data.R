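test_that("cohort generation is deterministic and honours the configuration", {
  cfg <- small_trial_config(seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 2L * sum(cfg$n_per_arm))
  expect_setequal(levels(a$country), c("Nepal", "Singapore", "Thailand"))
  counts <- table(a$country, a$arm)
  expect_true(all(counts == matrix(cfg$n_per_arm, 3, 2)))
  # record invariants
  expect_true(all(a$los_days > 0 & a$los_days <= cfg$horizon))
  expect_true(all(a$los_days[a$censored] == cfg$horizon))
  expect_false(any(a$censored & a$died))
  expect_true(all(is.na(a$adhered[a$arm == "usual_care"])))
  expect_false(anyNA(a$adhered[a$arm == "short_course"]))
  costs <- as.matrix(a[, c("cost_bed", "cost_pharma", "cost_diagnostics",
                           "cost_consumables")])
  expect_true(all(costs >= 0))
  # a different seed produces a different cohort
  expect_false(identical(a, generate_cohort(cfg, seed = 12L)))
})

test_that("invalid configurations are rejected", {
  expect_error(trial_config(n_per_arm = c(Nepal = 0L, Singapore = 10L, Thailand = 10L)),
               class = "vapcea_config_error")
  expect_error(trial_config(p_nonadherence = 1.2), class = "vapcea_config_error")
  expect_error(trial_config(missing_rate = 1), class = "vapcea_config_error")
  expect_error(trial_config(horizon = 0), class = "vapcea_config_error")
})

test_that("event rates recover configured probabilities at large n", {
  p_death <- matrix(0.38, 3, 2, dimnames = list(c("Nepal", "Singapore", "Thailand"),
                                                c("short_course", "usual_care")))
  cfg <- trial_config(n_per_arm = c(Nepal = 5000L, Singapore = 100L, Thailand = 100L),
                      p_death = p_death, p_nonadherence = 0, seed = 21L)
  coh <- generate_cohort(cfg)
  nepal_uc <- coh[coh$country == "Nepal" & coh$arm == "usual_care", ]
  deaths <- sum(nepal_uc$died)
  # exact binomial 99% interval around p = 0.38 at n = 5000
  bounds <- qbinom(c(0.005, 0.995), 5000, 0.38)
  expect_gte(deaths, bounds[1])
  expect_lte(deaths, bounds[2])
})

test_that("stay distribution moments match the truncated/censored oracle", {
  cfg <- trial_config(n_per_arm = c(Nepal = 6000L, Singapore = 100L, Thailand = 100L),
                      p_nonadherence = 0, seed = 31L)
  coh <- generate_cohort(cfg)
  g <- coh[coh$country == "Nepal" & coh$arm == "usual_care" & !coh$died, ]
  # oracle: E[min(X, 60)] for X ~ gamma(mean mu, shape k) truncated below 1,
  # by numerical integration
  mu <- cfg$los_mean["Nepal", "usual_care", "discharged_alive"]
  k <- cfg$los_shape
  sc <- mu / k
  norm <- 1 - pgamma(1, k, scale = sc)
  dens <- function(x) dgamma(x, k, scale = sc) / norm
  expected <- integrate(function(x) pmin(x, 60) * dens(x), 1, Inf)$value
  mc_se <- sd(g$los_days) / sqrt(nrow(g))
  expect_lt(abs(mean(g$los_days) - expected), 3 * mc_se)
})

test_that("cost totals are daily rate times observed stay", {
  cfg <- small_trial_config(seed = 41L)
  coh <- generate_cohort(cfg)
  # implied daily rates must be positive and finite for every category
  for (col in c("cost_bed", "cost_pharma", "cost_diagnostics", "cost_consumables")) {
    daily <- coh[[col]] / coh$los_days
    expect_true(all(is.finite(daily) & daily > 0))
  }
})

test_that("missingness masking hits the target rate and only cost cells", {
  cfg <- trial_config(n_per_arm = c(Nepal = 400L, Singapore = 300L, Thailand = 300L),
                      seed = 51L)
  coh <- generate_cohort(cfg)
  masked <- apply_missingness(coh, rate = 0.1, seed = 52L)
  cost_cols <- c("cost_bed", "cost_pharma", "cost_diagnostics", "cost_consumables")
  n_cells <- 4 * nrow(coh)
  n_masked <- sum(is.na(masked[, cost_cols]))
  bounds <- qbinom(c(0.005, 0.995), n_cells, 0.1)
  expect_gte(n_masked, bounds[1])
  expect_lte(n_masked, bounds[2])
  # outcome and stay columns untouched
  other <- setdiff(names(coh), cost_cols)
  expect_identical(masked[, other], coh[, other])
  # rate 0 is the identity
  expect_identical(apply_missingness(coh, 0), coh)
  expect_error(apply_missingness(coh, 1), class = "vapcea_config_error")
})

test_that("cohort summary matches a brute-force recount", {
  coh <- generate_cohort(small_trial_config(seed = 61L))
  masked <- apply_missingness(coh, 0.15, seed = 62L)
  s <- cohort_summary(masked)
  expect_equal(nrow(s), 6L)
  for (i in seq_len(nrow(s))) {
    g <- masked[masked$country == s$country[i] & masked$arm == s$arm[i], ]
    expect_equal(s$n[i], nrow(g))
    expect_equal(s$p_death[i], mean(g$died))
    expect_equal(s$mean_los[i], mean(g$los_days))
    expect_equal(s$mean_cost_bed[i], mean(g$cost_bed, na.rm = TRUE))
  }
  # single-record degenerate cases
  one <- manual_cohort(n = 1, died = TRUE)
  expect_equal(cohort_summary(one)$p_death, 1.0)
  two <- manual_cohort(n = 2)
  two$cost_bed <- c(100, NA)
  expect_equal(cohort_summary(two)$mean_cost_bed, 100)
  expect_error(cohort_summary(coh[0, ]))
})

test_that("cohort CSV round trip is lossless", {
  coh <- apply_missingness(generate_cohort(small_trial_config(seed = 71L)),
                           0.1, seed = 72L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(back$los_days, coh$los_days)
  expect_identical(back$died, coh$died)
  expect_identical(is.na(back$cost_pharma), is.na(coh$cost_pharma))
  expect_equal(back$cost_bed, coh$cost_bed)
})

test_that("trial configuration YAML round trip preserves all parameters", {
  cfg <- small_trial_config(seed = 81L, missing_rate = 0.2)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_trial_config(cfg, path)
  back <- read_trial_config(path)
  expect_equal(back$p_death, cfg$p_death)
  expect_equal(back$los_mean, cfg$los_mean)
  expect_equal(back$daily_cost_mean, cfg$daily_cost_mean)
  expect_equal(back$missing_rate, cfg$missing_rate)
  expect_identical(generate_cohort(back), generate_cohort(cfg))
})
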