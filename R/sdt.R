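#' Recognition counts from a binary old/new task
#'
#' Container for the 2x2 outcome table of a binary recognition task:
#' `hits` (repeated configurations called "old"), `misses` (repeated called
#' "new"), `false_alarms` (new called "old") and `correct_rejections`
#' (new called "new").
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative integer
#'   counts. Each task side (signal: hits + misses; noise: false alarms +
#'   correct rejections) must contain at least one trial.
#' @return An object of class `recognition_counts`.
#' @examples
#' recognition_counts(11, 17, 10, 18)
#' @export
recognition_counts <- function(hits, misses, false_alarms, correct_rejections) {
  x <- c(hits = hits, misses = misses,
         false_alarms = false_alarms, correct_rejections = correct_rejections)
  if (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (hits + misses < 1L) stop("need at least one signal (repeated) trial")
  if (false_alarms + correct_rejections < 1L)
    stop("need at least one noise (new) trial")
  structure(as.list(x), class = "recognition_counts")
}

#' @export
print.recognition_counts <- function(x, ...) {
  cat("Recognition counts: H =", x$hits, " M =", x$misses,
      " FA =", x$false_alarms, " CR =", x$correct_rejections, "\n")
  invisible(x)
}

#' Sensitivity estimate container
#'
#' A d-prime with its standard error, the trial counts it is based on, and a
#' provenance tag saying how it was obtained.
#'
#' @param dprime Finite sensitivity value.
#' @param se Standard error (`NA` when not yet derived).
#' @param n_signal,n_noise Trial counts on the signal/noise side.
#' @param source One of `"direct"`, `"indirect_trials"`, `"indirect_summary"`.
#' @return An object of class `sensitivity_estimate`.
#' @export
sensitivity_estimate <- function(dprime, se = NA_real_, n_signal = NA_integer_,
                                 n_noise = NA_integer_,
                                 source = c("direct", "indirect_trials",
                                            "indirect_summary")) {
  source <- match.arg(source)
  if (!is.finite(dprime)) stop("dprime must be finite")
  if (!is.na(se) && (!is.finite(se) || se < 0)) stop("se must be >= 0")
  structure(list(dprime = dprime, se = se, n_signal = n_signal,
                 n_noise = n_noise, source = source),
            class = "sensitivity_estimate")
}

#' @export
print.sensitivity_estimate <- function(x, ...) {
  cat(sprintf("d' = %.2f (SE = %s, source = %s)\n", x$dprime,
              if (is.na(x$se)) "NA" else sprintf("%.3f", x$se), x$source))
  invisible(x)
}

#' Sensitivity from hit and false-alarm rates
#'
#' Equal-variance Gaussian sensitivity, `qnorm(hr) - qnorm(fa)`. Rates at
#' exactly 0 or 1 are rejected: apply an extreme-rate correction first (see
#' [rates_from_counts()] with `correction = "log_linear"`).
#'
#' @param hr,fa Hit and false-alarm rates, strictly inside (0, 1). Vectorized.
#' @return Sensitivity d' (dimensionless).
#' @examples
#' dprime_from_rates(0.393, 0.351) # ~0.11
#' @export
dprime_from_rates <- function(hr, fa) {
  if (any(!is.finite(hr)) || any(!is.finite(fa)))
    stop("rates must be finite")
  if (any(hr <= 0 | hr >= 1) || any(fa <= 0 | fa >= 1))
    stop("rates must lie strictly inside (0, 1); ",
         "apply an extreme-rate correction (e.g. log_linear) first")
  stats::qnorm(hr) - stats::qnorm(fa)
}

#' Hit and false-alarm rates from recognition counts
#'
#' @param counts A [recognition_counts()] object.
#' @param correction `"log_linear"` adds 0.5 to all four cells before
#'   dividing (guaranteeing rates strictly inside (0,1)); `"none"` divides
#'   raw counts and errors on a 0 or 1 rate.
#' @return Named numeric vector `c(hr = , fa = )`.
#' @examples
#' rates_from_counts(recognition_counts(4, 0, 0, 4), "log_linear") # 0.9, 0.1
#' @export
rates_from_counts <- function(counts, correction = c("log_linear", "none")) {
  stopifnot(inherits(counts, "recognition_counts"))
  correction <- match.arg(correction)
  a <- if (correction == "log_linear") 0.5 else 0
  hr <- (counts$hits + a) / (counts$hits + counts$misses + 2 * a)
  fa <- (counts$false_alarms + a) /
    (counts$false_alarms + counts$correct_rejections + 2 * a)
  if (correction == "none" && any(c(hr, fa) %in% c(0, 1)))
    stop("a rate of exactly 0 or 1 occurred; use correction = \"log_linear\"")
  c(hr = hr, fa = fa)
}

#' Percent correct of an unbiased optimal observer
#'
#' For an equal-variance Gaussian observer with sensitivity d' who places the
#' decision criterion midway between the two distributions, overall accuracy
#' is `pnorm(dprime / 2)`.
#'
#' @param dprime Sensitivity, `>= 0`. Vectorized.
#' @return Proportion correct in `[0.5, 1)`.
#' @examples
#' accuracy_from_dprime(0.25) # ~0.55
#' @export
accuracy_from_dprime <- function(dprime) {
  if (any(!is.finite(dprime)) || any(dprime < 0))
    stop("dprime must be finite and >= 0")
  stats::pnorm(dprime / 2)
}

#' Hit/false-alarm rates of the unbiased optimal observer
#'
#' Inverse of [dprime_from_rates()] under the midpoint criterion:
#' `hr = pnorm(d/2)`, `fa = pnorm(-d/2)`.
#'
#' @inheritParams accuracy_from_dprime
#' @return Named numeric vector `c(hr = , fa = )` (or a 2-column matrix for
#'   vector input).
#' @examples
#' optimal_unbiased_rates(0.25) # ~ (0.55, 0.45)
#' @export
optimal_unbiased_rates <- function(dprime) {
  if (any(!is.finite(dprime)) || any(dprime < 0))
    stop("dprime must be finite and >= 0")
  hr <- stats::pnorm(dprime / 2)
  fa <- stats::pnorm(-dprime / 2)
  if (length(dprime) == 1L) c(hr = hr, fa = fa) else cbind(hr = hr, fa = fa)
}

# delta-method SE of d' given rates and per-side trial counts
se_dprime_from_rates <- function(hr, fa, n_signal, n_noise) {
  if (any(n_signal < 1) || any(n_noise < 1)) stop("need at least one trial per side")
  v <- hr * (1 - hr) / (n_signal * stats::dnorm(stats::qnorm(hr))^2) +
    fa * (1 - fa) / (n_noise * stats::dnorm(stats::qnorm(fa))^2)
  sqrt(v)
}

#' Standard error of d' from recognition counts
#'
#' Delta-method standard error of `dprime_from_rates()` treating hits and
#' false alarms as independent binomials:
#' `Var = HR(1-HR) / (n_s * phi(qnorm(HR))^2) + FA(1-FA) / (n_n * phi(qnorm(FA))^2)`
#' with `phi` the standard normal density, evaluated at the (possibly
#' corrected) rates; `n_s`, `n_n` are the raw per-side trial counts.
#'
#' @inheritParams rates_from_counts
#' @return Standard error (dimensionless).
#' @export
se_dprime_from_counts <- function(counts, correction = c("log_linear", "none")) {
  r <- rates_from_counts(counts, correction)
  se_dprime_from_rates(r[["hr"]], r[["fa"]],
                       counts$hits + counts$misses,
                       counts$false_alarms + counts$correct_rejections)
}

#' Sensitivity estimate from recognition counts
#'
#' Convenience wrapper: rates, d' and its delta-method SE in one
#' [sensitivity_estimate()].
#'
#' @inheritParams rates_from_counts
#' @param source Provenance tag, see [sensitivity_estimate()].
#' @return A `sensitivity_estimate`.
#' @export
dprime_from_counts <- function(counts, correction = c("log_linear", "none"),
                               source = "direct") {
  correction <- match.arg(correction)
  r <- rates_from_counts(counts, correction)
  sensitivity_estimate(
    dprime = dprime_from_rates(r[["hr"]], r[["fa"]]),
    se = se_dprime_from_counts(counts, correction),
    n_signal = counts$hits + counts$misses,
    n_noise = counts$false_alarms + counts$correct_rejections,
    source = source
  )
}
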