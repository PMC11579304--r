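test_that("pathway enumeration has the tree's combinatorial structure", {
  est <- toy_estimates()
  uc <- enumerate_pathways(est, "usual_care")
  sc <- enumerate_pathways(est, "short_course")
  expect_equal(nrow(uc), 8L)
  expect_equal(nrow(sc), 16L)
  expect_equal(sum(uc$prob), 1, tolerance = 1e-12)
  expect_equal(sum(sc$prob), 1, tolerance = 1e-12)
  expect_true(all(uc$cost >= 0))
  # death pathways carry zero effect
  expect_true(all(sc$effect[sc$terminal == "death"] == 0))
  expect_true(all(sc$effect[sc$terminal == "discharged_alive"] > 0))
})

test_that("universal mortality removes all effect", {
  est <- toy_estimates(p_death_sc = 1, p_death_uc = 1)
  for (s in c("short_course", "usual_care")) {
    v <- expected_strategy_values(enumerate_pathways(est, s))
    expect_equal(unname(v["effect"]), 0)
  }
})

test_that("expected values are probability-weighted sums", {
  one <- data.frame(prob = 1, cost = 100, effect = 2)
  expect_equal(expected_strategy_values(one), c(cost = 100, effect = 2))
  expect_error(expected_strategy_values(data.frame(prob = 0.5, cost = 1, effect = 1)),
               class = "vapcea_model_error")
  est <- toy_estimates()
  p <- enumerate_pathways(est, "short_course")
  v <- expected_strategy_values(p)
  # linearity: doubling costs doubles expected cost
  p2 <- p; p2$cost <- 2 * p2$cost
  expect_equal(expected_strategy_values(p2)[["cost"]], 2 * v[["cost"]])
  # brute-force oracle: explicit sum over every pathway
  expect_equal(v[["cost"]], sum(p$prob * p$cost))
  expect_equal(v[["effect"]], sum(p$prob * p$effect))
  # closed-form oracle for the adherent-branch arm values
  dly <- (1 - 1.03^-(70 - 60)) / 0.03
  daily_sc <- sum(c(24, 14, 7, 5))
  exp_cost_adherent <- daily_sc * (0.36 * 16 + 0.64 * 28)
  adherent <- p[p$adherent, ]
  expect_equal(sum(adherent$prob * adherent$cost) / sum(adherent$prob),
               exp_cost_adherent, tolerance = 1e-10)
  expect_equal(sum(adherent$prob * adherent$effect) / sum(adherent$prob),
               0.64 * dly, tolerance = 1e-10)
})

test_that("ICER reproduces the worked incremental examples", {
  expect_equal(round(compute_icer(152, 0.14)), 1086)
  expect_equal(round(compute_icer(-789, 0.13)), -6069)
  expect_equal(round(compute_icer(50, 0.19)), 263)
  expect_equal(compute_icer(0, 0.5), 0)
  expect_true(is.na(compute_icer(100, 0)))
})

test_that("INMB is lambda times effect minus cost", {
  expect_equal(compute_inmb(0, 0.5, 100), -100)
  expect_equal(compute_inmb(4751, 0.19, 50), 852.69)
  expect_equal(compute_inmb(1000, 0, 0), 0)
  expect_error(compute_inmb(-1, 1, 1), class = "vapcea_config_error")
})

test_that("dominance classification covers all quadrants", {
  expect_equal(classify_dominance(-789, 0.13), "dominant")
  expect_equal(classify_dominance(152, 0.14), "trade-off NE quadrant")
  expect_equal(classify_dominance(100, -0.1), "dominated")
  expect_equal(classify_dominance(-100, -0.1), "trade-off SW quadrant")
  expect_equal(classify_dominance(0, 0), "tie")
  expect_equal(classify_dominance(0, 0.1), "dominant")
  expect_equal(classify_dominance(-5, 0), "dominant")
})

test_that("full nonadherence makes the strategies identical", {
  est <- toy_estimates(p_nonadherence = 1)
  cea <- run_cea(est)
  expect_equal(cea$delta_cost, 0, tolerance = 1e-12)
  expect_equal(cea$delta_effect, 0, tolerance = 1e-12)
  expect_equal(cea$dominance, "tie")
})

test_that("identical arm parameters give zero increments", {
  est <- toy_estimates(p_death_sc = 0.39, p_death_uc = 0.39)
  est$p_recurrence[] <- 0.13
  est$daily_cost[, "short_course"] <- est$daily_cost[, "usual_care"]
  est$mean_stay["short_course", ] <- est$mean_stay["usual_care", ]
  cea <- run_cea(est)
  expect_equal(cea$delta_cost, 0, tolerance = 1e-12)
  expect_equal(cea$delta_effect, 0, tolerance = 1e-12)
})

test_that("INMB sign agrees with the ICER-threshold rule on random draws", {
  set.seed(303)
  for (i in 1:50) {
    est <- toy_estimates(
      p_nonadherence = runif(1, 0, 0.3),
      p_death_sc = runif(1, 0.1, 0.6), p_death_uc = runif(1, 0.1, 0.6),
      lambda = runif(1, 500, 40000))
    est$daily_cost[, "short_course"] <-
      est$daily_cost[, "usual_care"] * runif(4, 0.7, 1.3)
    cea <- run_cea(est)
    expect_equal(cea$inmb,
                 compute_inmb(est$lambda, cea$delta_effect, cea$delta_cost))
    if (cea$delta_effect > 0) {
      expect_equal(cea$inmb > 0,
                   cea$icer < est$lambda || cea$dominance == "dominant")
    }
    expect_equal(sum(enumerate_pathways(est, "short_course")$prob), 1,
                 tolerance = 1e-9)
  }
})

test_that("country estimates YAML round trip drives the same tree", {
  est <- toy_estimates()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_country_estimates(est, path)
  back <- read_country_estimates(path)
  expect_equal(run_cea(back)[c("delta_cost", "delta_effect", "icer")],
               run_cea(est)[c("delta_cost", "delta_effect", "icer")])
})

test_that("invalid tree parameters are rejected", {
  expect_error(toy_estimates(p_death_sc = 1.5), class = "vapcea_model_error")
  est <- toy_estimates()
  est$mean_stay[1, 1] <- 75
  expect_error(vapcea:::validate_country_estimates(est),
               class = "vapcea_model_error")
})
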