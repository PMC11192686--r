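#' Unbiasing constant for the t-to-d' estimator
#'
#' The constant `c` such that `t * c` is an unbiased estimate of the
#' trial-level sensitivity underlying a reported paired t statistic:
#' \deqn{c_{N,K,q^2} = \sqrt{\frac{q^2 + 4/K}{N}}\,\sqrt{\frac{2}{N-1}}\,
#'   \frac{\Gamma((N-1)/2)}{\Gamma((N-2)/2)}}
#' where `N` is the number of participants, `K` the total number of search
#' trials per participant (balanced across the two conditions) and `q2` the
#' ratio of between-subject variance of true RT effects to trial-level RT
#' variance. Gamma ratios are evaluated in log space so large `N` is safe.
#'
#' @param N Number of participants (>= 3).
#' @param K Total trials per participant, both conditions (>= 2).
#' @param q2 Variance ratio, `>= 0`.
#' @return The constant (dimensionless).
#' @examples
#' estimator_constant(14, 96, 0.09) # 0.091
#' @export
estimator_constant <- function(N, K, q2) {
  if (any(!is.finite(N)) || any(N < 3) || any(N != round(N)))
    stop("N must be an integer >= 3")
  if (any(!is.finite(K)) || any(K < 2)) stop("K must be >= 2")
  if (any(!is.finite(q2)) || any(q2 < 0)) stop("q2 must be >= 0")
  sqrt((q2 + 4 / K) / N) * sqrt(2 / (N - 1)) *
    gamma_ratio_half((N - 1) / 2, (N - 2) / 2)
}

# E[T] = b * ncp for a noncentral t with nu df; b = sqrt(nu/2)*G((nu-1)/2)/G(nu/2)
nct_mean_factor <- function(nu) {
  if (nu < 2) stop("mean of a t statistic requires df >= 2")
  sqrt(nu / 2) * gamma_ratio_half((nu - 1) / 2, nu / 2)
}

#' Standard error of the summary-based sensitivity estimate
#'
#' Convention used throughout this package: the estimate is `t * c`, the
#' reported `t` is modelled as a noncentral t with `nu = N - 1` degrees of
#' freedom, the noncentrality is solved from the mean relation
#' `E[T] = b(nu) * ncp` (so `ncp = t / b(nu)`), and the SE is `c` times the
#' closed-form standard deviation of that noncentral t. Requires `N >= 4`
#' (the variance of a t with `df <= 2` is undefined).
#'
#' @inheritParams estimator_constant
#' @param t Reported paired t statistic.
#' @return Standard error (dimensionless).
#' @export
se_dprime_from_t <- function(t, N, K, q2) {
  if (!is.finite(t)) stop("t must be finite")
  nu <- N - 1
  if (nu <= 2) stop("SE undefined for N < 4 (variance of t needs df > 2)")
  b <- nct_mean_factor(nu)
  ncp <- t / b
  v <- nu * (1 + ncp^2) / (nu - 2) - ncp^2 * b^2
  estimator_constant(N, K, q2) * sqrt(v)
}

#' Indirect sensitivity from a reported paired t statistic
#'
#' Unbiased estimate of the search-task (indirect) sensitivity from reported
#' statistics only: `d'_indirect = t * c_{N,K,q2}` (see
#' [estimator_constant()]). The SE follows the package's noncentral-t
#' convention ([se_dprime_from_t()]) and is `NA` for `N < 4`.
#'
#' @inheritParams se_dprime_from_t
#' @return A [sensitivity_estimate()], `source = "indirect_summary"`.
#' @examples
#' dprime_from_t(2.61, 14, 96, 0.09) # d' ~ 0.24
#' @export
dprime_from_t <- function(t, N, K, q2) {
  if (!is.finite(t)) stop("t must be finite")
  d <- t * estimator_constant(N, K, q2)
  se <- if (N >= 4) se_dprime_from_t(t, N, K, q2) else NA_real_
  sensitivity_estimate(d, se = se, n_signal = K / 2, n_noise = K / 2,
                       source = "indirect_summary")
}

#' Pooled trial-level RT variance
#'
#' Variance of RTs within each participant-by-condition cell, pooled across
#' cells with weights equal to the cell degrees of freedom (`n_cell - 1`).
#'
#' @param table A search `trial_table` (already restricted to the trials
#'   under analysis).
#' @return Pooled variance (squared RT units).
#' @export
pooled_trial_variance <- function(table) {
  stopifnot(inherits(table, "trial_table"), table_task(table) == "search")
  cell <- interaction(table$participant, table$condition, drop = TRUE)
  ns <- tabulate(cell)
  if (any(ns < 2)) {
    bad <- levels(cell)[ns < 2]
    stop("cell(s) with fewer than 2 trials: ", paste(bad, collapse = ", "))
  }
  vars <- tapply(table$rt_ms, cell, stats::var)
  ns <- as.vector(table(cell))
  sum(vars * (ns - 1)) / sum(ns - 1)
}

#' Estimate the variance ratio q-squared from trial data
#'
#' Decomposes the variability of per-participant mean RT effects
#' (`mean(repeated) - mean(new)`) into trial-level noise and genuine
#' between-subject variance:
#' \deqn{\hat q^2 = \frac{N\,SE^2 - (4/K)\hat\sigma^2_\varepsilon}
#'   {\hat\sigma^2_\varepsilon}}
#' where `SE` is the standard error of the effects,
#' `sigma2_eps` the pooled trial variance ([pooled_trial_variance()]) and
#' `K` the total trials per participant. For unbalanced designs `4/K` is
#' replaced by the participant average of `1/k_rep + 1/k_new`. The numerator
#' is an unbiased estimate of the between-subject variance, so `q2_hat` may
#' legitimately be negative; it is reported unclamped.
#'
#' @inheritParams pooled_trial_variance
#' @return An object of class `variance_decomposition` with fields
#'   `sigma2_eps`, `sigma2_effect`, `se_effects`, `q2_hat`, `n_participants`,
#'   `k_mean`.
#' @export
estimate_q2 <- function(table) {
  stopifnot(inherits(table, "trial_table"), table_task(table) == "search")
  s2_eps <- pooled_trial_variance(table)
  by_p <- split(seq_len(nrow(table)), table$participant)
  eff <- vapply(by_p, function(i) {
    rep_rt <- table$rt_ms[i][table$condition[i] == "repeated"]
    new_rt <- table$rt_ms[i][table$condition[i] == "new"]
    mean(rep_rt) - mean(new_rt)
  }, numeric(1))
  noise_w <- vapply(by_p, function(i) {
    k_rep <- sum(table$condition[i] == "repeated")
    k_new <- sum(table$condition[i] == "new")
    1 / k_rep + 1 / k_new
  }, numeric(1))
  N <- length(eff)
  if (N < 2) stop("need at least 2 participants to estimate q2")
  se <- stats::sd(eff) / sqrt(N)
  s2_effect <- N * se^2 - mean(noise_w) * s2_eps
  structure(list(sigma2_eps = s2_eps,
                 sigma2_effect = s2_effect,
                 se_effects = se,
                 q2_hat = s2_effect / s2_eps,
                 n_participants = N,
                 k_mean = mean(lengths(by_p))),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("Variance decomposition (N = %d, mean K = %.1f):\n",
                     "  trial-level variance     sigma2_eps    = %.4g\n",
                     "  between-subject variance sigma2_effect = %.4g\n",
                     "  SE of mean effects                     = %.4g\n",
                     "  variance ratio           q2_hat        = %.4g\n"),
              x$n_participants, x$k_mean, x$sigma2_eps, x$sigma2_effect,
              x$se_effects, x$q2_hat))
  invisible(x)
}

#' Reconstruct the standard error of mean RT effects
#'
#' The forward variance-decomposition relation: given a between-subject
#' variance, a trial-level variance, `N` participants and `K` total trials
#' per participant, the SE of per-participant mean effects is
#' `sqrt((sigma2_effect + (4/K) sigma2_eps) / N)`. Inverse of the numerator
#' of [estimate_q2()].
#'
#' @param sigma2_effect,sigma2_eps Variance components (same squared units).
#' @param N,K Participants and total trials per participant.
#' @return The implied standard error.
#' @export
se_from_variances <- function(sigma2_effect, sigma2_eps, N, K) {
  sqrt((sigma2_effect + (4 / K) * sigma2_eps) / N)
}
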