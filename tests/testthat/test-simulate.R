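test_that("config validation names the offending fields", {
  expect_error(simulation_config(n_participants = 1), "n_participants")
  expect_error(simulation_config(sigma_eps = 0), "sigma_eps")
  expect_error(simulation_config(sigma_eps = 400, rt_baseline = 500),
               "rt_baseline")
  expect_error(simulation_config(indirect_extra_dprime = 0.3),
               "single_source")
  expect_error(simulation_config(n_epochs = 2, learning_onset_epoch = 3),
               "learning_onset_epoch")
  expect_equal(config_q2(simulation_config()), 0.09, tolerance = 1e-12)
})

test_that("identical config and seed give bit-identical tables", {
  cfg <- simulation_config(seed = 314)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$search$rt_ms, b$search$rt_ms)
  expect_identical(a$recognition$response, b$recognition$response)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_experiment(cfg, seed = 315)
  expect_false(identical(a$search$rt_ms, c2$search$rt_ms))
})

test_that("tables have the declared shape and schema", {
  cfg <- simulation_config(n_participants = 5, k_per_condition = 10,
                           k_direct_per_condition = 6, n_epochs = 3,
                           seed = 1)
  sim <- simulate_experiment(cfg)
  expect_equal(nrow(sim$search), 5 * 2 * 10 * 3)
  expect_equal(nrow(sim$recognition), 5 * 2 * 6)
  expect_equal(sort(unique(sim$search$epoch)), 1:3)
  expect_true(all(sim$search$rt_ms > 0))
  expect_equal(table_task(sim$search), "search")
  expect_equal(table_task(sim$recognition), "recognition")
})

test_that("null world produces near-zero sensitivities in both tasks", {
  set.seed(41)
  cfg <- simulation_config(n_participants = 150, k_per_condition = 40,
                           k_direct_per_condition = 12, delta = 0,
                           sigma_effect = 0)
  sim <- simulate_experiment(cfg)
  ind <- indirect_dprime_from_trials(sim$search, epochs = "all")
  dir <- direct_dprime_from_trials(sim$recognition)
  expect_lt(abs(attr(ind, "group_mean")), 3 * attr(ind, "group_se"))
  expect_lt(abs(attr(dir, "group_mean")), 3 * attr(dir, "group_se"))
})

test_that("baby-weight world yields ~55% direct accuracy at d' = 0.25", {
  set.seed(42)
  cfg <- simulation_config(n_participants = 40, k_per_condition = 10,
                           k_direct_per_condition = 500, delta = 100,
                           sigma_eps = 400, sigma_effect = 0,
                           rt_baseline = 3400)
  sim <- simulate_experiment(cfg)
  acc <- mean((sim$recognition$condition == "repeated") ==
                (sim$recognition$response == "old"))
  n <- nrow(sim$recognition)
  expect_lt(abs(acc - accuracy_from_dprime(0.25)),
            3 * sqrt(0.25 / n) + 1e-12)
  expect_equal(round(100 * accuracy_from_dprime(0.25)), 55)
})

test_that("median-split d' converges under log-normal emission too", {
  set.seed(43)
  cfg <- simulation_config(n_participants = 6, k_per_condition = 4000,
                           delta = 0.3, sigma_eps = 1, sigma_effect = 0,
                           rt_model = "lognormal", rt_baseline = 100)
  sim <- simulate_experiment(cfg)
  ind <- indirect_dprime_from_trials(sim$search, epochs = "all")
  expect_true(all(abs(ind$dprime - 0.3) < 3 * ind$se))
})

test_that("dual-source worlds create a detectable ITA", {
  set.seed(44)
  cfg <- simulation_config(n_participants = 40, k_per_condition = 200,
                           k_direct_per_condition = 12, delta = 0.1,
                           sigma_eps = 1, sigma_effect = 0.3,
                           source_model = "dual_source",
                           indirect_extra_dprime = 0.4, rt_baseline = 100)
  hits <- replicate(60, {
    sim <- simulate_experiment(cfg)
    cmp <- compare_group_trialwise(
      direct_dprime_from_trials(sim$recognition),
      indirect_dprime_from_trials(sim$search, epochs = "all"))
    cmp$ci_low > 0
  })
  # claimed power > 0.8; 60 reps cannot fall below the 99.9% binomial band
  expect_gte(mean(hits), qbinom(0.001, 60, 0.8) / 60)
})

test_that("recovery_study reports unbiased estimates at the null", {
  set.seed(45)
  cfg <- simulation_config(n_participants = 15, k_per_condition = 30,
                           delta = 0, sigma_eps = 1, sigma_effect = 0.2,
                           rt_baseline = 100)
  rec <- recovery_study(cfg, reps = 200, paths = c("summary", "trials"))
  expect_equal(nrow(rec), 2)
  expect_true(all(abs(rec$bias) < 3 * rec$mc_se))
  expect_error(recovery_study(cfg, reps = 10), "reps")
})

test_that("typical_pattern_demo shows the flawed pattern on null data", {
  demo <- typical_pattern_demo(
    simulation_config(n_participants = 14, k_per_condition = 1000,
                      k_direct_per_condition = 200, delta = 100,
                      sigma_eps = 400, sigma_effect = 0,
                      rt_baseline = 3400, seed = 4242))
  # clear mean RT effect ...
  expect_lt(demo$p, 0.001)
  expect_gt(demo$rt_effect_ms, 50)
  # ... next to near-chance direct accuracy ...
  expect_lt(abs(demo$direct_accuracy - 0.55), 0.03)
  # ... and no indirect task advantage under the sensitivity comparison
  expect_equal(demo$comparison$decision, "no evidence for ITA")
  out <- capture.output(print(demo))
  expect_true(any(grepl("Sensitivity comparison", out)))
})
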