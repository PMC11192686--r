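test_that("compare_group_trialwise handles identical and mismatched inputs", {
  set.seed(21)
  tab <- latent_search(8, 30, dprime = 0.2)
  ind <- indirect_dprime_from_trials(tab, epochs = "all")
  same <- compare_group_trialwise(ind, ind)
  expect_equal(same$d_difference, 0)
  expect_equal(same$t_stat, 0)
  expect_equal(same$decision, "no evidence for ITA")
  other <- ind[-1, ]
  class(other) <- class(ind)
  attr(other, "source") <- "direct"
  expect_error(compare_group_trialwise(other, ind), "participant sets")
})

test_that("compare_summary combines SEs in quadrature", {
  a <- sensitivity_estimate(0.24, se = 0.10, source = "indirect_summary")
  b <- sensitivity_estimate(0.11, se = 0.14, source = "direct")
  r <- compare_summary(a, b, N = 14)
  expect_equal(r$d_difference, 0.13)
  expect_equal(r$se, sqrt(0.10^2 + 0.14^2), tolerance = 1e-12)
  expect_equal(round(r$se, 3), 0.172)
  expect_equal(r$df, 13)
  expect_true(r$ci_low <= r$d_difference & r$d_difference <= r$ci_high)
  same <- compare_summary(a, a, N = 14)
  expect_equal(same$d_difference, 0)
  expect_error(compare_summary(sensitivity_estimate(0.2), b, N = 14),
               "standard errors")
})

test_that("one-sided JZS Bayes factor matches frozen and symmetric values", {
  expect_equal(round(jzs_bf_one_sided(0.66, 14), 2), 0.47)
  # at t = 0 the positive-truncation BF equals the two-sided BF
  expect_equal(jzs_bf_one_sided(0, 14), jzs_bf_two_sided(0, 14),
               tolerance = 1e-6)
  # strictly increasing in t
  ts <- seq(0, 10, by = 0.5)
  bfs <- sapply(ts, jzs_bf_one_sided, N = 20)
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_one_sided(Inf, 10), "finite")
  expect_error(jzs_bf_one_sided(1, 1), "N")
})

test_that("JZS quadrature agrees with a Monte-Carlo prior-integration oracle", {
  set.seed(23)
  n_draw <- 2e5
  for (case in list(c(t = 1.5, N = 20), c(t = -0.8, N = 12),
                    c(t = 3, N = 30))) {
    t <- case[["t"]]; N <- case[["N"]]
    delta <- abs(rcauchy(n_draw, 0, 1 / sqrt(2)))  # half-Cauchy prior draws
    w <- dt(t, N - 1, ncp = delta * sqrt(N)) / dt(t, N - 1)
    mc <- mean(w)
    mc_se <- sd(w) / sqrt(n_draw)
    expect_equal(jzs_bf_one_sided(t, N), mc, tolerance = 3 * mc_se / mc)
  }
})

test_that("proportion_ci covers the frozen interval and the edge cases", {
  ci <- proportion_ci(48, 766)
  expect_equal(round(ci[["lower"]], 3), 0.047)
  expect_equal(round(ci[["upper"]], 3), 0.082)
  expect_equal(proportion_ci(0, 20)[["lower"]], 0)
  expect_equal(proportion_ci(20, 20)[["upper"]], 1)
  w <- proportion_ci(48, 766, method = "wilson")
  expect_true(w[["lower"]] > 0.04 && w[["upper"]] < 0.09)
})

test_that("funnel coordinates place points and boundaries correctly", {
  r0 <- comparison_result(0, 0.1, -0.2, 0.2, 0, 10, 1, 0.5, mode = "summary")
  r1 <- comparison_result(1.96 * 0.1, 0.1, 0.0, 0.4, 1.96, 10, 0.07, 1.5,
                          mode = "summary")
  fd <- funnel_coordinates(list(r0, r1))
  expect_equal(fd$points$d_difference, c(0, 0.196))
  # the 5% boundary at se = 0.1 is exactly +/- 1.96... * 0.1
  b <- fd$boundaries[fd$boundaries$alpha == 0.05, ]
  expect_equal(max(b$upper) / max(b$se), qnorm(0.975), tolerance = 1e-12)
  expect_equal(b$lower, -b$upper)
  # null ensemble coverage: ~95% of standard-normal deviates in the funnel
  set.seed(24)
  z <- rnorm(2000)
  inside <- abs(z) < qnorm(0.975)
  df <- data.frame(d_difference = z * 0.2, se = 0.2)
  fd2 <- funnel_coordinates(df)
  expect_equal(mean(abs(fd2$points$d_difference) <
                      qnorm(0.975) * fd2$points$se),
               mean(inside))
  expect_gt(mean(inside), 0.93)
})

test_that("individual ITA tests flag an extreme participant and stay stable", {
  set.seed(25)
  # participant with perfectly separated search RTs and chance-level
  # recognition responses: a clear individual ITA
  search <- data.frame(participant = "x", epoch = 1L, block = 1L,
                       condition = rep(c("repeated", "new"), each = 24),
                       rt_ms = c(rnorm(24, 400, 10), rnorm(24, 700, 10)))
  recog <- data.frame(participant = "x",
                      condition = rep(c("repeated", "new"), each = 12),
                      response = rep(c("old", "new"), 12))
  res <- individual_ita_tests(trial_table(search, "search"),
                              trial_table(recog, "recognition"),
                              B = 400, seed = 99)
  expect_true(res$significant[1])
  expect_equal(attr(res, "n_total"), 1)
  expect_error(individual_ita_tests(trial_table(search, "search"),
                                    trial_table(recog, "recognition"),
                                    B = 50), "B must be")
})

test_that("bootstrap SEs are stable between B = 200 and B = 2000", {
  set.seed(26)
  sim <- simulate_experiment(
    simulation_config(n_participants = 6, k_per_condition = 60,
                      k_direct_per_condition = 20, delta = 0.25,
                      sigma_eps = 1, sigma_effect = 0, rt_baseline = 100),
    seed = 123)
  r1 <- individual_ita_tests(sim$search, sim$recognition, B = 200,
                             seed = 7, epochs = "all")
  r2 <- individual_ita_tests(sim$search, sim$recognition, B = 2000,
                             seed = 7, epochs = "all")
  expect_equal(r1$d_difference, r2$d_difference)  # point estimates identical
  expect_true(all(abs(r1$se_boot - r2$se_boot) / r2$se_boot < 0.15))
})

test_that("comparison_result validates invariants and categorizes BFs", {
  expect_error(comparison_result(0.5, 0.1, 0.6, 0.7, 5, 10, 0.01, 2,
                                 mode = "summary"), "bracket")
  expect_error(comparison_result(0, 0.1, -0.1, 0.1, 0, 10, 1, -2,
                                 mode = "summary"), "positive")
  expect_equal(bf_category(c(0.2, 0.47, 5)),
               c("against", "inconclusive", "for"))
  r <- comparison_result(0.3, 0.1, 0.1, 0.5, 3, 10, 0.013, 6,
                         mode = "summary")
  expect_equal(r$decision, "ITA")
})
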