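test_that("estimator_constant matches frozen values and preconditions", {
  expect_equal(round(estimator_constant(14, 96, 0.09), 3), 0.091)
  expect_equal(estimator_constant(14, 96, 0), 0.0513348, tolerance = 1e-6)
  expect_error(estimator_constant(2, 96, 0.09), "N must be")
  expect_error(estimator_constant(14, 96, -0.1), "q2")
  # large-N limit: c * sqrt(N) -> sqrt(q2 + 4/K)
  expect_equal(estimator_constant(20000, 96, 0.09) * sqrt(20000),
               sqrt(0.09 + 4 / 96), tolerance = 1e-4)
  # numerically stable far beyond N = 300
  expect_true(is.finite(estimator_constant(5000, 100, 0.09)))
})

test_that("estimator_constant is monotone in its arguments", {
  q2 <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(sapply(q2, function(q)
    estimator_constant(20, 100, q))) > 0))
  N <- c(5, 10, 20, 50, 100)
  expect_true(all(diff(sapply(N, function(n)
    estimator_constant(n, 100, 0.09))) < 0))
  K <- c(10, 20, 50, 100, 400)
  expect_true(all(diff(sapply(K, function(k)
    estimator_constant(20, k, 0.09))) < 0))
  expect_true(all(sapply(N, function(n)
    estimator_constant(n, 100, 0)) > 0))
})

test_that("dprime_from_t reproduces the worked example and scales with t", {
  est <- dprime_from_t(2.61, 14, 96, 0.09)
  expect_equal(round(est$dprime, 2), 0.24)
  expect_equal(est$source, "indirect_summary")
  expect_equal(dprime_from_t(0, 14, 96, 0.09)$dprime, 0)
  expect_equal(dprime_from_t(-1, 20, 100, 0.04)$dprime,
               -dprime_from_t(1, 20, 100, 0.04)$dprime)
})

test_that("se_dprime_from_t follows the noncentral-t convention", {
  # frozen from the closed form, confirmed against a 1e6-draw simulation
  expect_equal(se_dprime_from_t(2.61, 14, 96, 0.09), 0.1116953,
               tolerance = 1e-6)
  nu <- 13
  expect_equal(se_dprime_from_t(0, 14, 96, 0.09),
               estimator_constant(14, 96, 0.09) * sqrt(nu / (nu - 2)),
               tolerance = 1e-12)
  expect_error(se_dprime_from_t(1, 3, 96, 0.09), "N < 4")
  # simulation oracle at a second point
  set.seed(77)
  b <- sqrt(9 / 2) * exp(lgamma(4) - lgamma(4.5))
  draws <- rt(2e5, df = 9, ncp = 1.8 / b)
  mc <- estimator_constant(10, 50, 0.04) * sd(draws)
  mc_se <- estimator_constant(10, 50, 0.04) * sd(draws) / sqrt(2 * (2e5 - 1))
  expect_equal(se_dprime_from_t(1.8, 10, 50, 0.04), mc,
               tolerance = 10 * mc_se / mc)
})

test_that("t-to-d' estimator is unbiased over simulated replicates", {
  set.seed(55)
  cfg <- simulation_config(n_participants = 20, k_per_condition = 50,
                           delta = 0.3, sigma_eps = 1, sigma_effect = 0.3,
                           rt_baseline = 100)
  rec <- recovery_study(cfg, reps = 2000, paths = "summary")
  expect_lt(abs(rec$bias), 3 * rec$mc_se)
})

test_that("pooled_trial_variance pools by cell degrees of freedom", {
  df <- data.frame(participant = rep(c("a", "b"), each = 8),
                   epoch = 1L, block = 1L,
                   condition = rep(rep(c("repeated", "new"), each = 4), 2),
                   rt_ms = 0)
  # all cells with identical variance v return v
  set.seed(8)
  x <- rnorm(4)
  df$rt_ms <- rep(500, 16) + rep(x - mean(x), 4)
  tab <- trial_table(df, "search")
  expect_equal(pooled_trial_variance(tab), var(x - mean(x)))
  # two equal-df cells with variances 1 and 3 pool to 2
  df2 <- data.frame(participant = "a", epoch = 1L, block = 1L,
                    condition = rep(c("repeated", "new"), each = 3),
                    rt_ms = c(c(-1, 0, 1) + 500, sqrt(3) * c(-1, 0, 1) + 500))
  expect_equal(pooled_trial_variance(trial_table(df2, "search")), 2)
  df3 <- df2[-(1:2), ]  # leaves a 1-trial cell
  expect_error(pooled_trial_variance(trial_table(df3, "search")),
               "fewer than 2")
})

test_that("estimate_q2 matches an independent arithmetic oracle", {
  set.seed(9)
  tab <- latent_search(12, 30, dprime = 0.4, sigma = 50, baseline = 800)
  vd <- estimate_q2(tab)
  # oracle: direct tapply arithmetic, written independently of the package
  s2 <- mean(tapply(tab$rt_ms,
                    interaction(tab$participant, tab$condition), var))
  eff <- tapply(tab$rt_ms, list(tab$participant, tab$condition), mean)
  effects <- eff[, "repeated"] - eff[, "new"]
  q2_oracle <- (var(effects) - (4 / 60) * s2) / s2
  expect_equal(vd$q2_hat, q2_oracle, tolerance = 1e-10)
  expect_equal(vd$sigma2_eps, s2, tolerance = 1e-10)
  # Eq-4 round trip: SE reconstructed from the components equals the SE
  # the estimator inverted
  expect_equal(se_from_variances(vd$sigma2_effect, vd$sigma2_eps, 12, 60),
               vd$se_effects, tolerance = 1e-10)
})

test_that("q2_hat recovers the configured variance ratio and can be negative", {
  set.seed(10)
  cfg <- simulation_config(n_participants = 50, k_per_condition = 100,
                           delta = 0.1, sigma_eps = 1, sigma_effect = 0.2,
                           rt_baseline = 100)
  rec <- recovery_study(cfg, reps = 300, paths = "q2")
  expect_equal(rec$truth, 0.04)
  expect_lt(abs(rec$bias), 3 * rec$mc_se)
  # sigma_effect = 0: estimates scatter around 0, negative values allowed
  cfg0 <- simulation_config(n_participants = 30, k_per_condition = 40,
                            delta = 0, sigma_eps = 1, sigma_effect = 0,
                            rt_baseline = 100)
  q2s <- replicate(200, estimate_q2(simulate_experiment(cfg0)$search)$q2_hat)
  expect_lt(abs(mean(q2s)), 3 * sd(q2s) / sqrt(200))
  expect_true(any(q2s < 0))
})
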