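test_that("intercept-only logistic prediction equals the sample proportion", {
  coh <- manual_cohort(n = 50)
  coh$died <- rep(c(TRUE, FALSE), c(18, 32))
  fit <- fit_logistic_outcome(coh, "died", covariates = character())
  expect_equal(unname(fit$probabilities["Nepal", "usual_care"]), 18 / 50,
               tolerance = 1e-8)
})

test_that("logistic regression recovers a known arm effect", {
  set.seed(202)
  n <- 5000
  arm <- rep(c("short_course", "usual_care"), each = n / 2)
  lp <- -0.5 + 0.5 * (arm == "short_course")
  coh <- manual_cohort(n = n)
  coh$arm <- factor(arm, levels = levels(coh$arm))
  coh$adhered <- ifelse(arm == "short_course", TRUE, NA)
  coh$died <- runif(n) < plogis(lp)
  fit <- fit_logistic_outcome(coh, "died", covariates = "arm")
  est <- fit$coefficients[["armusual_care"]]
  se <- sqrt(fit$vcov["armusual_care", "armusual_care"])
  expect_lt(abs(est - (-0.5)), 3 * se)
})

test_that("degenerate binary outcomes raise estimation errors", {
  coh <- manual_cohort(n = 20, died = TRUE)
  expect_error(fit_logistic_outcome(coh, "died"),
               class = "vapcea_estimation_error")
})

test_that("Tobit with no censoring equals the ordinary normal MLE", {
  set.seed(212)
  coh <- manual_cohort(n = 200)
  coh$los_days <- pmax(rnorm(200, 30, 8), 1)
  coh$censored <- FALSE
  fit <- fit_tobit_los(coh, covariates = character(), bound = 60)
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), mean(coh$los_days),
               tolerance = 1e-6)
  mle_sd <- sqrt(mean((coh$los_days - mean(coh$los_days))^2))
  expect_equal(unname(fit$scale), mle_sd, tolerance = 1e-4)
})

test_that("Tobit recovers coefficients under right-censoring", {
  set.seed(222)
  n <- 5000
  arm <- rep(c("usual_care", "short_course"), each = n / 2)
  y <- 30 + 10 * (arm == "short_course") + rnorm(n, 0, 15)
  coh <- manual_cohort(n = n)
  coh$arm <- factor(arm, levels = levels(coh$arm))
  coh$adhered <- ifelse(arm == "short_course", TRUE, NA)
  coh$censored <- y >= 60
  coh$los_days <- pmax(pmin(y, 60), 0.5)
  expect_gt(mean(coh$censored), 0.05)  # censoring is actually at work
  fit <- fit_tobit_los(coh, covariates = "arm", bound = 60)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$vcov))
  # the reference level is short_course: intercept 30 + 10, arm shift -10
  expect_lt(abs(beta[["(Intercept)"]] - 40), 3 * se[[1]])
  expect_lt(abs(beta[["armusual_care"]] - (-10)), 3 * se[[2]])
  # the naive mean of the censored column underestimates the true mean
  truth_sc <- 40
  naive <- mean(coh$los_days[coh$arm == "short_course"])
  nd <- data.frame(arm = factor("short_course", levels = levels(coh$arm)))
  tobit_mean <- fit$predict(nd)
  expect_lt(abs(tobit_mean - truth_sc), abs(naive - truth_sc))
})

test_that("a fully censored sample cannot be fitted", {
  coh <- manual_cohort(n = 10, los = 60)
  coh$censored <- TRUE
  expect_error(fit_tobit_los(coh), class = "vapcea_estimation_error")
})

test_that("daily costs divide totals by the bounded stay", {
  coh <- manual_cohort(n = 1, los = 30, costs = 600)
  est <- estimate_daily_costs(coh)
  expect_equal(unname(est$mean["bed", "Nepal", "usual_care"]), 20)
  # a patient still in hospital at day 60 accrued costs over 60 days
  cen <- manual_cohort(n = 1, los = 60, costs = 600)
  cen$censored <- TRUE
  est <- estimate_daily_costs(cen)
  expect_equal(unname(est$mean["pharma", "Nepal", "usual_care"]), 10)
  # brute-force group-by oracle on a generated cohort
  coh <- generate_cohort(small_trial_config(seed = 231L))
  est <- estimate_daily_costs(coh)
  g <- coh[coh$country == "Thailand" & coh$arm == "short_course", ]
  expect_equal(unname(est$mean["bed", "Thailand", "short_course"]),
               mean(g$cost_bed / pmin(g$los_days, 60)))
  # totals are reconstructed exactly for uncensored patients
  uncensored <- coh[!coh$censored, ]
  daily <- uncensored$cost_bed / pmin(uncensored$los_days, 60)
  expect_equal(daily * uncensored$los_days, uncensored$cost_bed)
  # missing costs are rejected
  holed <- coh
  holed$cost_bed[1] <- NA
  expect_error(estimate_daily_costs(holed), class = "vapcea_data_error")
})

test_that("nonadherence probability is the ITT/per-protocol shortfall", {
  expect_equal(estimate_adherence(231, 211), 20 / 231)
  expect_equal(estimate_adherence(100, 100), 0)
  expect_error(estimate_adherence(100, 0), class = "vapcea_data_error")
  expect_error(estimate_adherence(100, 101), class = "vapcea_data_error")
})

test_that("life-year discounting matches the closed-form annuity", {
  expect_equal(discounted_life_years(70, 70, 0.03), 0)
  expect_equal(discounted_life_years(60, 70, 0), 10)
  expect_equal(discounted_life_years(60, 70, 0.03),
               (1 - 1.03^-10) / 0.03, tolerance = 1e-10)
  expect_equal(round(discounted_life_years(60, 70, 0.03), 4), 8.5302)
  expect_equal(round(discounted_life_years(60, 70, 0.05), 4), 7.7217)
  expect_warning(res <- discounted_life_years(80, 70, 0.03), "exceeds")
  expect_equal(res, 0)
  expect_error(discounted_life_years(60, 70, 1), class = "vapcea_config_error")
})

test_that("discounted life-years are monotone in horizon and rate", {
  L <- seq(0, 30, by = 2.5)
  vals <- sapply(L, function(l) discounted_life_years(70 - l, 70, 0.03))
  expect_true(all(diff(vals) > 0 | L[-1] == 0))
  rates <- seq(0, 0.1, by = 0.01)
  vals <- sapply(rates, function(r) discounted_life_years(60, 70, r))
  expect_true(all(diff(vals) < 0))
  # result never exceeds the undiscounted horizon
  expect_true(all(sapply(rates, function(r)
    discounted_life_years(60, 70, r)) <= 10))
})

test_that("utility weighting scales life-years linearly", {
  expect_equal(apply_utility_weight(8.5302, 1), 8.5302)
  expect_equal(apply_utility_weight(8.5302, 0), 0)
  expect_equal(round(apply_utility_weight(8.5302, 0.8), 4), 6.8242)
  expect_error(apply_utility_weight(5, 1.2), class = "vapcea_config_error")
})

test_that("estimated inputs reproduce cohort structure country by country", {
  coh <- generate_cohort(small_trial_config(seed = 241L))
  ests <- estimate_country_inputs(coh)
  expect_named(ests, c("Nepal", "Singapore", "Thailand"))
  for (est in ests) {
    expect_s3_class(est, "country_estimates")
    expect_true(all(est$p_death >= 0 & est$p_death <= 1))
    expect_true(all(est$mean_stay > 0 & est$mean_stay <= 60))
    expect_false(is.null(est$uncertainty))
  }
  # adherence equals the cohort's ITT/PP shortfall
  n_itt <- sum(coh$arm == "short_course")
  n_pp <- sum(coh$arm == "short_course" & coh$adhered)
  expect_equal(ests$Nepal$p_nonadherence, (n_itt - n_pp) / n_itt)
  # pooled estimation gives every country the same probabilities and stays
  pooled <- estimate_country_inputs(coh, pooled = TRUE)
  expect_equal(pooled$Nepal$p_death, pooled$Thailand$p_death)
  expect_equal(pooled$Nepal$mean_stay, pooled$Singapore$mean_stay)
})
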