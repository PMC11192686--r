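#' Comparison result container
#'
#' Holds a sensitivity difference (indirect minus direct) together with its
#' SE, confidence interval, t test, two-sided p, one-sided JZS Bayes factor
#' and the decision implied by the CI rule: evidence for an ITA is declared
#' iff the lower CI bound lies above 0.
#'
#' @param d_difference,se,ci_low,ci_high,t_stat,df,p_two_sided,bf10_one_sided
#'   Components as named.
#' @param mode `"trial_paired"` or `"summary"`.
#' @param d_direct,d_indirect Optional point estimates entering the
#'   difference.
#' @param label Optional study/condition label.
#' @param ci_level Confidence level of the interval.
#' @return An object of class `comparison_result`.
#' @export
comparison_result <- function(d_difference, se, ci_low, ci_high, t_stat, df,
                              p_two_sided, bf10_one_sided,
                              mode = c("trial_paired", "summary"),
                              d_direct = NA_real_, d_indirect = NA_real_,
                              label = NA_character_, ci_level = 0.95) {
  mode <- match.arg(mode)
  if (!(ci_low <= d_difference && d_difference <= ci_high))
    stop("confidence interval must bracket the point estimate")
  if (!is.finite(bf10_one_sided) || bf10_one_sided <= 0)
    stop("bf10 must be positive")
  structure(list(label = label, d_direct = d_direct, d_indirect = d_indirect,
                 d_difference = d_difference, se = se,
                 ci_low = ci_low, ci_high = ci_high, ci_level = ci_level,
                 t_stat = t_stat, df = df, p_two_sided = p_two_sided,
                 bf10_one_sided = bf10_one_sided,
                 bf_category = bf_category(bf10_one_sided),
                 decision = if (ci_low > 0) "ITA" else "no evidence for ITA",
                 mode = mode),
            class = "comparison_result")
}

#' Evidence category of a Bayes factor
#'
#' Conventional cut-offs: `BF10 < 1/3` evidence against an ITA, `BF10 > 3`
#' evidence for, otherwise inconclusive.
#'
#' @param bf10 Positive Bayes factor(s).
#' @return Character vector: `"against"`, `"inconclusive"`, `"for"`.
#' @export
bf_category <- function(bf10) {
  ifelse(bf10 < 1 / 3, "against", ifelse(bf10 > 3, "for", "inconclusive"))
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Sensitivity comparison (%s mode)%s\n", x$mode,
              if (is.na(x$label)) "" else paste0(" - ", x$label)))
  if (!is.na(x$d_indirect))
    cat(sprintf("  d'_indirect = %.2f   d'_direct = %.2f\n",
                x$d_indirect, x$d_direct))
  cat(sprintf("  d'_difference = %.2f, SE = %.3f, %d%% CI [%.2f, %.2f]\n",
              x$d_difference, x$se, round(100 * x$ci_level),
              x$ci_low, x$ci_high))
  cat(sprintf("  t(%g) = %.2f, p = %.3g, BF10(one-sided) = %.2f (%s)\n",
              x$df, x$t_stat, x$p_two_sided, x$bf10_one_sided,
              x$bf_category))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' Group-level sensitivity comparison from paired trial data
#'
#' Per-participant differences (indirect minus direct d-prime) are tested
#' against zero with a one-sample t test; the confidence interval, two-sided
#' p and one-sided JZS Bayes factor are reported. Pairing within
#' participants needs no independence assumption across tasks.
#'
#' @param direct,indirect `participant_sensitivities` objects covering the
#'   same participants (see [direct_dprime_from_trials()],
#'   [indirect_dprime_from_trials()]).
#' @param ci_level Confidence level (default 0.95).
#' @param bf_scale Cauchy prior scale of the Bayes factor (default
#'   `1/sqrt(2)`).
#' @param label Optional label carried into the result.
#' @return A [comparison_result()], `mode = "trial_paired"`.
#' @export
compare_group_trialwise <- function(direct, indirect, ci_level = 0.95,
                                    bf_scale = 1 / sqrt(2),
                                    label = NA_character_) {
  stopifnot(inherits(direct, "participant_sensitivities"),
            inherits(indirect, "participant_sensitivities"))
  if (!setequal(direct$participant, indirect$participant))
    stop("participant sets differ between the direct and indirect estimates")
  d <- direct[order(direct$participant), ]
  i <- indirect[order(indirect$participant), ]
  diffs <- i$dprime - d$dprime
  n <- length(diffs)
  if (n < 2) stop("need at least 2 participants")
  m <- mean(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  df <- n - 1
  t_stat <- if (se == 0) 0 else m / se
  crit <- stats::qt((1 + ci_level) / 2, df)
  p <- 2 * stats::pt(-abs(t_stat), df)
  bf <- jzs_bf_one_sided(t_stat, n, scale = bf_scale)
  comparison_result(m, se, m - crit * se, m + crit * se, t_stat, df, p, bf,
                    mode = "trial_paired",
                    d_direct = mean(d$dprime), d_indirect = mean(i$dprime),
                    label = label, ci_level = ci_level)
}

#' Sensitivity comparison from summary estimates
#'
#' Difference of two sensitivity point estimates with SEs combined in
#' quadrature (tasks treated as independent -- documented convention for
#' summary-statistic reanalyses, where pairing is unavailable); t uses
#' `df = N - 1`.
#'
#' @param d_ind,d_dir [sensitivity_estimate()] objects carrying SEs.
#' @param N Number of participants (for df and the Bayes factor).
#' @param df Degrees of freedom (default `N - 1`).
#' @inheritParams compare_group_trialwise
#' @return A [comparison_result()], `mode = "summary"`.
#' @export
compare_summary <- function(d_ind, d_dir, N, df = N - 1, ci_level = 0.95,
                            bf_scale = 1 / sqrt(2), label = NA_character_) {
  stopifnot(inherits(d_ind, "sensitivity_estimate"),
            inherits(d_dir, "sensitivity_estimate"))
  if (is.na(d_ind$se) || is.na(d_dir$se))
    stop("both estimates must carry standard errors")
  diff <- d_ind$dprime - d_dir$dprime
  se <- sqrt(d_ind$se^2 + d_dir$se^2)
  t_stat <- if (se == 0) 0 else diff / se
  crit <- stats::qt((1 + ci_level) / 2, df)
  p <- 2 * stats::pt(-abs(t_stat), df)
  bf <- jzs_bf_one_sided(t_stat, N, scale = bf_scale)
  comparison_result(diff, se, diff - crit * se, diff + crit * se, t_stat, df,
                    p, bf, mode = "summary",
                    d_direct = d_dir$dprime, d_indirect = d_ind$dprime,
                    label = label, ci_level = ci_level)
}

jzs_marginal_h1 <- function(t, nu, N, scale, lower, upper) {
  # marginal likelihood of t under delta ~ Cauchy(0, scale) restricted to
  # (lower, upper); the noncentral-t density integrates out the JZS
  # variance mixing internally
  mass <- stats::pcauchy(upper, 0, scale) - stats::pcauchy(lower, 0, scale)
  # R's noncentral-t density warns about ~1e-8 accuracy at large ncp;
  # far below the accuracy needed here
  f <- function(delta)
    suppressWarnings(stats::dt(t, nu, ncp = delta * sqrt(N))) *
      stats::dcauchy(delta, 0, scale) / mass
  out <- tryCatch(
    stats::integrate(f, lower, upper, rel.tol = 1e-8, abs.tol = 0,
                     stop.on.error = TRUE),
    error = function(e) stop("Bayes factor integration failed: ",
                             conditionMessage(e)))
  out$value
}

#' One-sided default-prior (JZS) Bayes factor for a one-sample t
#'
#' Bayes factor of H+: standardized effect `delta ~ Cauchy(0, scale)`
#' truncated to positive values, against the point null `delta = 0`, for a
#' one-sample (paired) t statistic from `N` participants. Computed by
#' adaptive quadrature of the noncentral-t likelihood over the truncated
#' Cauchy prior; relative accuracy ~1e-8.
#'
#' @param t Observed t statistic.
#' @param N Number of participants (>= 2); degrees of freedom are `N - 1`.
#' @param scale Cauchy prior scale (default `1/sqrt(2)`, the conventional
#'   "medium" default).
#' @return `BF10` (positive scalar); values below 1 favour the null.
#' @examples
#' jzs_bf_one_sided(0.66, 14) # ~0.47
#' @export
jzs_bf_one_sided <- function(t, N, scale = 1 / sqrt(2)) {
  if (!is.finite(t)) stop("t must be finite")
  if (N < 2) stop("N must be >= 2")
  jzs_marginal_h1(t, N - 1, N, scale, 0, Inf) / stats::dt(t, N - 1)
}

#' Two-sided JZS Bayes factor (diagnostic companion)
#'
#' @inheritParams jzs_bf_one_sided
#' @return `BF10` for the untruncated Cauchy alternative.
#' @export
jzs_bf_two_sided <- function(t, N, scale = 1 / sqrt(2)) {
  if (!is.finite(t)) stop("t must be finite")
  if (N < 2) stop("N must be >= 2")
  jzs_marginal_h1(t, N - 1, N, scale, -Inf, Inf) / stats::dt(t, N - 1)
}

#' Binomial proportion confidence interval
#'
#' @param successes,n Counts with `0 <= successes <= n`.
#' @param method `"clopper_pearson"` (exact, default) or `"wilson"`.
#' @param level Confidence level.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' proportion_ci(48, 766) # ~ [0.047, 0.082]
#' @export
proportion_ci <- function(successes, n,
                          method = c("clopper_pearson", "wilson"),
                          level = 0.95) {
  method <- match.arg(method)
  stopifnot(n >= 1, successes >= 0, successes <= n)
  a <- (1 - level) / 2
  if (method == "clopper_pearson") {
    lo <- if (successes == 0) 0 else stats::qbeta(a, successes, n - successes + 1)
    hi <- if (successes == n) 1 else stats::qbeta(1 - a, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - a)
    p <- successes / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw)
    hi <- min(1, ctr + hw)
  }
  c(lower = lo, upper = hi)
}

# bootstrap replicate d' for one participant's search trials (median split)
boot_indirect_dprime <- function(rep_rt, new_rt, B, correction) {
  k1 <- length(rep_rt); k2 <- length(new_rt)
  rep_bs <- matrix(rep_rt[sample.int(k1, k1 * B, replace = TRUE)], k1, B)
  new_bs <- matrix(new_rt[sample.int(k2, k2 * B, replace = TRUE)], k2, B)
  meds <- apply(rbind(rep_bs, new_bs), 2, stats::median)
  hits <- colSums(rep_bs < rep(meds, each = k1))
  fas <- colSums(new_bs < rep(meds, each = k2))
  a <- if (correction == "log_linear") 0.5 else 0
  hr <- (hits + a) / (k1 + 2 * a)
  fa <- (fas + a) / (k2 + 2 * a)
  if (correction == "none" && any(hr %in% c(0, 1) | fa %in% c(0, 1)))
    stop("bootstrap produced an extreme rate; use correction = \"log_linear\"")
  stats::qnorm(hr) - stats::qnorm(fa)
}

# bootstrap replicate d' for one participant's recognition responses;
# resampling binary trials within condition == binomial resampling of counts
boot_direct_dprime <- function(n_sig, hr_obs, n_noi, fa_obs, B, correction) {
  hits <- stats::rbinom(B, n_sig, hr_obs)
  fas <- stats::rbinom(B, n_noi, fa_obs)
  a <- if (correction == "log_linear") 0.5 else 0
  hr <- (hits + a) / (n_sig + 2 * a)
  fa <- (fas + a) / (n_noi + 2 * a)
  if (correction == "none" && any(hr %in% c(0, 1) | fa %in% c(0, 1)))
    stop("bootstrap produced an extreme rate; use correction = \"log_linear\"")
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' Individual-participant ITA tests with bootstrap standard errors
#'
#' For each participant, the sensitivity difference (median-split indirect
#' minus direct d-prime) is tested one-sidedly against 0 using a bootstrap
#' SE: search trials are resampled with replacement within condition (the
#' median and classification are recomputed per resample) and recognition
#' responses are resampled within condition. The test statistic
#' `difference / SE_boot` is referred to a t distribution with
#' `k_search + k_recognition - 2` degrees of freedom (normal-theory test
#' with bootstrap SE). The summary reports the proportion of significant
#' participants with a binomial CI.
#'
#' @param search,recognition Trial tables covering the same participants.
#' @param B Bootstrap replicates per participant (>= 200; default 2000).
#' @param alpha One-sided significance level (default 0.05).
#' @param seed Optional master seed; per-participant streams are derived
#'   from it so results are reproducible and order-independent.
#' @param ci_method Method for the proportion CI, see [proportion_ci()].
#' @inheritParams indirect_dprime_from_trials
#' @return An object of class `individual_ita`: data frame
#'   (`participant`, `d_indirect`, `d_direct`, `d_difference`, `se_boot`,
#'   `t`, `p_one_sided`, `significant`) with summary attributes
#'   (`n_significant`, `n_total`, `proportion`, `proportion_ci`, `alpha`).
#' @export
individual_ita_tests <- function(search, recognition, B = 2000, alpha = 0.05,
                                 seed = NULL, epochs = "last",
                                 correct_only = NULL,
                                 correction = c("log_linear", "none"),
                                 ci_method = "clopper_pearson") {
  correction <- match.arg(correction)
  if (B < 200) stop("B must be >= 200")
  stopifnot(inherits(recognition, "trial_table"),
            table_task(recognition) == "recognition")
  sel <- select_trials(search, epochs = epochs, correct_only = correct_only)
  ids <- intersect(unique(sel$participant), unique(recognition$participant))
  if (!length(ids)) stop("no participant appears in both tables")
  if (!is.null(seed)) set.seed(seed)
  pseeds <- sample.int(.Machine$integer.max, length(ids))
  rows <- vector("list", length(ids))
  skipped <- character(0)
  for (j in seq_along(ids)) {
    p <- ids[j]
    si <- sel$participant == p
    rep_rt <- sel$rt_ms[si & sel$condition == "repeated"]
    new_rt <- sel$rt_ms[si & sel$condition == "new"]
    ri <- recognition$participant == p
    cond <- recognition$condition[ri]
    resp <- recognition$response[ri]
    n_sig <- sum(cond == "repeated"); n_noi <- sum(cond == "new")
    if (length(rep_rt) < 2 || length(new_rt) < 2 || n_sig < 2 || n_noi < 2) {
      skipped <- c(skipped, p)
      next
    }
    cnt_s <- classify_counts(c(rep_rt, new_rt),
                             rep(c("repeated", "new"),
                                 c(length(rep_rt), length(new_rt))))
    rs <- rates_from_counts(cnt_s, correction)
    d_ind <- dprime_from_rates(rs[["hr"]], rs[["fa"]])
    hits <- sum(cond == "repeated" & resp == "old")
    fas <- sum(cond == "new" & resp == "old")
    cnt_r <- recognition_counts(hits, n_sig - hits, fas, n_noi - fas)
    rr <- rates_from_counts(cnt_r, correction)
    d_dir <- dprime_from_rates(rr[["hr"]], rr[["fa"]])
    set.seed(pseeds[j])
    bi <- boot_indirect_dprime(rep_rt, new_rt, B, correction)
    bd <- boot_direct_dprime(n_sig, hits / n_sig, n_noi, fas / n_noi, B,
                             correction)
    se <- stats::sd(bi - bd)
    df <- length(rep_rt) + length(new_rt) + n_sig + n_noi - 2
    t_stat <- if (se == 0) 0 else (d_ind - d_dir) / se
    p_one <- stats::pt(t_stat, df, lower.tail = FALSE)
    rows[[j]] <- data.frame(participant = p, d_indirect = d_ind,
                            d_direct = d_dir, d_difference = d_ind - d_dir,
                            se_boot = se, t = t_stat, p_one_sided = p_one,
                            significant = p_one < alpha)
  }
  if (length(skipped))
    ita_log("individual_ita_tests: skipped participant(s) with too few trials: %s",
            paste(skipped, collapse = ", "))
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res) || !nrow(res)) stop("no participant had enough trials")
  n_sig_p <- sum(res$significant)
  structure(res, class = c("individual_ita", "data.frame"),
            n_significant = n_sig_p, n_total = nrow(res),
            proportion = n_sig_p / nrow(res),
            proportion_ci = proportion_ci(n_sig_p, nrow(res),
                                          method = ci_method),
            alpha = alpha, B = B)
}

#' @export
print.individual_ita <- function(x, ...) {
  ci <- attr(x, "proportion_ci")
  cat(sprintf(paste0("Individual ITA tests (one-sided alpha = %.2f, ",
                     "B = %d bootstrap reps):\n  %d of %d participants ",
                     "significant (%.1f%%, 95%% CI [%.1f, %.1f])\n"),
              attr(x, "alpha"), attr(x, "B"), attr(x, "n_significant"),
              attr(x, "n_total"), 100 * attr(x, "proportion"),
              100 * ci[["lower"]], 100 * ci[["upper"]]))
  invisible(x)
}

#' Funnel-plot coordinates for sensitivity differences
#'
#' Emits the (difference, SE) points of a set of comparisons together with
#' the significance boundary lines `x = +/- z_{1-alpha/2} * SE`, as plain
#' data for any plotting backend.
#'
#' @param results A `comparison_result`, or a list of them, or a data frame
#'   with columns `d_difference` and `se` (optionally `label`).
#' @param alphas Significance levels for the boundary lines.
#' @param n_grid Number of SE grid points per boundary line.
#' @return List of class `funnel_data` with elements `points` (label,
#'   d_difference, se) and `boundaries` (alpha, se, lower, upper).
#' @export
funnel_coordinates <- function(results, alphas = c(0.05, 0.01),
                               n_grid = 50) {
  if (inherits(results, "comparison_result")) results <- list(results)
  if (is.data.frame(results)) {
    stopifnot(all(c("d_difference", "se") %in% names(results)))
    pts <- data.frame(
      label = if (is.null(results$label)) as.character(seq_len(nrow(results)))
              else as.character(results$label),
      d_difference = results$d_difference, se = results$se)
  } else {
    pts <- do.call(rbind, lapply(seq_along(results), function(k) {
      r <- results[[k]]
      stopifnot(inherits(r, "comparison_result"))
      data.frame(label = if (is.na(r$label)) as.character(k) else r$label,
                 d_difference = r$d_difference, se = r$se)
    }))
  }
  se_grid <- seq(0, max(pts$se) * 1.05, length.out = n_grid)
  bounds <- do.call(rbind, lapply(alphas, function(a) {
    z <- stats::qnorm(1 - a / 2)
    data.frame(alpha = a, se = se_grid, lower = -z * se_grid,
               upper = z * se_grid)
  }))
  structure(list(points = pts, boundaries = bounds), class = "funnel_data")
}
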