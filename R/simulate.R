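#' Simulation configuration for a contextual-cueing style experiment
#'
#' The generator draws, per participant i, a true RT effect
#' `Delta_i ~ Normal(delta, sigma_effect^2)` (so the variance ratio is
#' `q^2 = (sigma_effect / sigma_eps)^2`) and emits:
#'
#' * search trials: latent values `Normal(-Delta_i/2, sigma_eps^2)` for
#'   repeated and `Normal(+Delta_i/2, sigma_eps^2)` for new configurations,
#'   either added to `rt_baseline` on the millisecond scale
#'   (`rt_model = "gaussian_latent"`, where d-prime is exact by
#'   construction) or exponentiated
#'   (`"lognormal"`: `rt = exp(meanlog + sdlog * z)` with `z` the
#'   standardized latent), honouring the log-normal shape of real search
#'   RTs; the median split is optimal in either case;
#' * recognition trials: evidence `Normal(+d_i/2, 1)` for repeated and
#'   `Normal(-d_i/2, 1)` for new items with `d_i = Delta_i / sigma_eps`;
#'   the response is "old" when evidence exceeds the participant's
#'   criterion, `criterion_i ~ Normal(0, criterion_sd^2)` (0 = unbiased
#'   optimal observer).
#'
#' Under `source_model = "single_source"` one latent signal drives both
#' tasks, so the expected sensitivity difference is exactly zero -- the
#' generative null the sensitivity comparison is calibrated against. Under
#' `"dual_source"`, `indirect_extra_dprime` is added to the search-task
#' separation only, creating a true ITA of that size.
#'
#' Defaults mirror the canonical contextual-cueing layout: 14 participants,
#' 48 search trials per condition (96 total, one epoch), 12 + 12 recognition
#' trials, a 50 ms cueing effect against 400 ms trial-level noise
#' (d' = 0.125) and `sigma_effect = 120` ms, i.e. q^2 = 0.09.
#'
#' @param n_participants Number of participants (>= 2).
#' @param k_per_condition Search trials per condition per epoch (>= 2).
#' @param k_direct_per_condition Recognition trials per condition (>= 2).
#' @param delta Mean true RT effect (ms on the latent scale).
#' @param sigma_eps Trial-level latent SD (ms).
#' @param sigma_effect Between-subject SD of true effects (ms).
#' @param rt_model `"gaussian_latent"` or `"lognormal"`.
#' @param source_model `"single_source"` or `"dual_source"`.
#' @param indirect_extra_dprime Extra search-only sensitivity
#'   (dual-source only).
#' @param criterion_sd SD of the recognition criterion across participants.
#' @param n_epochs Number of search epochs (the effect is present from
#'   `learning_onset_epoch` on; earlier epochs have zero effect).
#' @param learning_onset_epoch First epoch with a nonzero effect.
#' @param rt_baseline Baseline RT (ms) added under the Gaussian model; must
#'   exceed `5 * sigma_eps` so RTs stay positive.
#' @param lognormal_meanlog,lognormal_sdlog Location/scale of the log-normal
#'   emission.
#' @param seed Optional integer seed stored in the config;
#'   [simulate_experiment()] applies it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 14, k_per_condition = 48,
                              k_direct_per_condition = 12, delta = 50,
                              sigma_eps = 400, sigma_effect = 120,
                              rt_model = c("gaussian_latent", "lognormal"),
                              source_model = c("single_source", "dual_source"),
                              indirect_extra_dprime = 0, criterion_sd = 0,
                              n_epochs = 1, learning_onset_epoch = 1,
                              rt_baseline = 2500,
                              lognormal_meanlog = log(1000),
                              lognormal_sdlog = 0.4, seed = NULL) {
  rt_model <- match.arg(rt_model)
  source_model <- match.arg(source_model)
  cfg <- list(n_participants = as.integer(n_participants),
              k_per_condition = as.integer(k_per_condition),
              k_direct_per_condition = as.integer(k_direct_per_condition),
              delta = delta, sigma_eps = sigma_eps,
              sigma_effect = sigma_effect, rt_model = rt_model,
              source_model = source_model,
              indirect_extra_dprime = indirect_extra_dprime,
              criterion_sd = criterion_sd, n_epochs = as.integer(n_epochs),
              learning_onset_epoch = as.integer(learning_onset_epoch),
              rt_baseline = rt_baseline,
              lognormal_meanlog = lognormal_meanlog,
              lognormal_sdlog = lognormal_sdlog, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  if (cfg$n_participants < 2) stop("n_participants must be >= 2")
  if (cfg$k_per_condition < 2) stop("k_per_condition must be >= 2")
  if (cfg$k_direct_per_condition < 2)
    stop("k_direct_per_condition must be >= 2")
  if (cfg$sigma_eps <= 0) stop("sigma_eps must be > 0")
  if (cfg$sigma_effect < 0) stop("sigma_effect must be >= 0")
  if (cfg$criterion_sd < 0) stop("criterion_sd must be >= 0")
  if (cfg$n_epochs < 1 || cfg$learning_onset_epoch < 1 ||
        cfg$learning_onset_epoch > cfg$n_epochs)
    stop("need 1 <= learning_onset_epoch <= n_epochs")
  if (cfg$rt_model == "gaussian_latent" &&
        cfg$rt_baseline < 5 * cfg$sigma_eps)
    stop("rt_baseline must be >= 5 * sigma_eps under the gaussian model ",
         "(to keep RTs positive); increase rt_baseline or use lognormal")
  if (cfg$source_model == "single_source" && cfg$indirect_extra_dprime != 0)
    stop("indirect_extra_dprime must be 0 under single_source")
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("Simulation config: N = %d, K = %d/condition x %d ",
                     "epoch(s), K_direct = %d/condition\n  delta = %g, ",
                     "sigma_eps = %g, sigma_effect = %g (q^2 = %.4g), ",
                     "model = %s/%s\n"),
              x$n_participants, x$k_per_condition, x$n_epochs,
              x$k_direct_per_condition, x$delta, x$sigma_eps,
              x$sigma_effect, (x$sigma_effect / x$sigma_eps)^2,
              x$rt_model, x$source_model))
  invisible(x)
}

#' True variance ratio implied by a config
#' @param config A `simulation_config`.
#' @return `(sigma_effect / sigma_eps)^2`.
#' @export
config_q2 <- function(config) (config$sigma_effect / config$sigma_eps)^2

# matrix-level generative core; assumes the RNG state is already set.
# Returns per-participant truth and N x k matrices per condition/epoch.
sim_core <- function(cfg) {
  N <- cfg$n_participants
  k <- cfg$k_per_condition
  ke <- k * cfg$n_epochs
  delta_i <- stats::rnorm(N, cfg$delta, cfg$sigma_effect)
  d_i <- delta_i / cfg$sigma_eps
  d_search_i <- d_i + if (cfg$source_model == "dual_source")
    cfg$indirect_extra_dprime else 0
  # effect present only from the learning onset epoch on
  active <- rep(seq_len(cfg$n_epochs) >= cfg$learning_onset_epoch, each = k)
  half <- outer(d_search_i * cfg$sigma_eps / 2, as.numeric(active))
  rep_lat <- -half + matrix(stats::rnorm(N * ke, 0, cfg$sigma_eps), N, ke)
  new_lat <- half + matrix(stats::rnorm(N * ke, 0, cfg$sigma_eps), N, ke)
  if (cfg$rt_model == "gaussian_latent") {
    rep_rt <- cfg$rt_baseline + rep_lat
    new_rt <- cfg$rt_baseline + new_lat
  } else {
    rep_rt <- exp(cfg$lognormal_meanlog +
                    cfg$lognormal_sdlog * rep_lat / cfg$sigma_eps)
    new_rt <- exp(cfg$lognormal_meanlog +
                    cfg$lognormal_sdlog * new_lat / cfg$sigma_eps)
  }
  kd <- cfg$k_direct_per_condition
  criterion_i <- stats::rnorm(N, 0, cfg$criterion_sd)
  ev_sig <- outer(d_i / 2, rep(1, kd)) + matrix(stats::rnorm(N * kd), N, kd)
  ev_noi <- outer(-d_i / 2, rep(1, kd)) + matrix(stats::rnorm(N * kd), N, kd)
  list(delta_i = delta_i, d_i = d_i, d_search_i = d_search_i,
       criterion_i = criterion_i,
       rep_rt = rep_rt, new_rt = new_rt,
       epoch = rep(seq_len(cfg$n_epochs), each = k),
       old_sig = ev_sig > criterion_i, old_noi = ev_noi > criterion_i)
}

#' Simulate a contextual-cueing experiment
#'
#' Draws one experiment from the generative model described in
#' [simulation_config()] and returns trial tables in the package's CSV
#' schema plus the per-participant true parameters.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with elements `search` (search `trial_table`),
#'   `recognition` (recognition `trial_table`), `truth` (data frame of
#'   per-participant true effects and sensitivities) and `config`.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  core <- sim_core(config)
  N <- config$n_participants
  ids <- sprintf("P%03d", seq_len(N))
  ke <- ncol(core$rep_rt)
  search <- data.frame(
    participant = rep(ids, times = 2 * ke),
    epoch = rep(core$epoch, each = N, times = 2),
    block = rep(core$epoch, each = N, times = 2),
    condition = rep(c("repeated", "new"), each = N * ke),
    rt_ms = c(as.vector(core$rep_rt), as.vector(core$new_rt)))
  search <- search[order(search$participant, search$epoch, search$condition), ]
  rownames(search) <- NULL
  kd <- config$k_direct_per_condition
  recognition <- data.frame(
    participant = rep(ids, times = 2 * kd),
    condition = rep(c("repeated", "new"), each = N * kd),
    response = ifelse(c(as.vector(core$old_sig), as.vector(core$old_noi)),
                      "old", "new"))
  recognition <- recognition[order(recognition$participant,
                                   recognition$condition), ]
  rownames(recognition) <- NULL
  truth <- data.frame(participant = ids, delta_true = core$delta_i,
                      d_direct_true = core$d_i,
                      d_search_true = core$d_search_i,
                      criterion = core$criterion_i)
  list(search = trial_table(search, "search"),
       recognition = trial_table(recognition, "recognition"),
       truth = truth, config = config)
}

# paired t statistic of the RT effect (new - repeated) from core matrices
core_t_stat <- function(core) {
  eff <- rowMeans(core$new_rt) - rowMeans(core$rep_rt)
  n <- length(eff)
  mean(eff) / (stats::sd(eff) / sqrt(n))
}

#' Recovery and calibration study for the sensitivity estimators
#'
#' Repeatedly simulates experiments from `config` and measures bias, RMSE
#' and Monte-Carlo SE of (a) the summary-path estimate `t * c` computed from
#' each replicate's own paired t statistic, (b) the trial-path group mean of
#' per-participant median-split sensitivities, and (c) the variance-ratio
#' estimate `q2_hat`. The true values are implied by the config
#' (`d' = delta / sigma_eps + indirect_extra_dprime`;
#' `q^2 = (sigma_effect / sigma_eps)^2`).
#'
#' @param config A [simulation_config()] (the stated world of the study).
#' @param reps Number of simulated replicates (>= 100).
#' @param paths Subset of `c("summary", "trials", "q2")` to evaluate;
#'   dropping the trial paths makes large-`reps` runs cheap.
#' @param seed Optional seed.
#' @return Data frame with one row per path: `path`, `truth`,
#'   `mean_estimate`, `bias`, `rmse`, `mc_se`, `reps`.
#' @export
recovery_study <- function(config, reps = 100,
                           paths = c("summary", "trials", "q2"),
                           seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  paths <- match.arg(paths, several.ok = TRUE)
  if (reps < 100) stop("reps must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  K_total <- 2 * config$k_per_condition * config$n_epochs
  q2_true <- config_q2(config)
  d_true <- config$delta / config$sigma_eps +
    if (config$source_model == "dual_source") config$indirect_extra_dprime else 0
  c_const <- estimator_constant(config$n_participants, K_total, q2_true)
  need_tables <- any(c("trials", "q2") %in% paths)
  est <- matrix(NA_real_, reps, 3,
                dimnames = list(NULL, c("summary", "trials", "q2")))
  for (r in seq_len(reps)) {
    if (need_tables) {
      sim <- simulate_experiment(config, seed = NULL)
      if ("summary" %in% paths) {
        eff <- tapply(sim$search$rt_ms,
                      list(sim$search$participant, sim$search$condition),
                      mean)
        diffs <- eff[, "new"] - eff[, "repeated"]
        t_stat <- mean(diffs) / (stats::sd(diffs) / sqrt(length(diffs)))
        est[r, "summary"] <- t_stat * c_const
      }
      if ("trials" %in% paths) {
        ind <- indirect_dprime_from_trials(sim$search, epochs = "all")
        est[r, "trials"] <- attr(ind, "group_mean")
      }
      if ("q2" %in% paths)
        est[r, "q2"] <- estimate_q2(sim$search)$q2_hat
    } else {
      core <- sim_core(config)
      est[r, "summary"] <- core_t_stat(core) * c_const
    }
  }
  rows <- lapply(intersect(colnames(est), paths), function(p) {
    x <- est[, p]
    truth <- if (p == "q2") q2_true else d_true
    data.frame(path = p, truth = truth, mean_estimate = mean(x),
               bias = mean(x) - truth,
               rmse = sqrt(mean((x - truth)^2)),
               mc_se = stats::sd(x) / sqrt(reps), reps = reps)
  })
  do.call(rbind, rows)
}

#' Demonstrate the flawed "typical pattern" on single-source data
#'
#' Simulates one experiment in which a single latent signal drives both
#' tasks, then reports the four headline numbers from which the flawed
#' standard reasoning would infer implicit recognition -- a clearly
#' significant mean RT effect next to near-chance explicit accuracy --
#' followed by the sensitivity comparison, which correctly finds no
#' indirect task advantage.
#'
#' @inheritParams simulate_experiment
#' @param epochs Epoch selection for the analysis (default `"all"`; the
#'   default config has a single epoch).
#' @return Object of class `ita_demo`: list with `rt_effect_ms`,
#'   `t`, `df`, `p`, `d_direct_mean`, `direct_accuracy`,
#'   `d_indirect_mean`, and `comparison` (a [comparison_result()]).
#' @export
typical_pattern_demo <- function(config = simulation_config(),
                                 seed = config$seed, epochs = "all") {
  stopifnot(inherits(config, "simulation_config"))
  sim <- simulate_experiment(config, seed = seed)
  eff <- tapply(sim$search$rt_ms,
                list(sim$search$participant, sim$search$condition), mean)
  diffs <- eff[, "new"] - eff[, "repeated"]
  n <- length(diffs)
  se <- stats::sd(diffs) / sqrt(n)
  t_stat <- mean(diffs) / se
  p <- 2 * stats::pt(-abs(t_stat), n - 1)
  dir <- direct_dprime_from_trials(sim$recognition)
  ind <- indirect_dprime_from_trials(sim$search, epochs = epochs)
  acc <- mean((sim$recognition$condition == "repeated") ==
                (sim$recognition$response == "old"))
  cmp <- compare_group_trialwise(dir, ind)
  structure(list(rt_effect_ms = mean(diffs), t = t_stat, df = n - 1, p = p,
                 d_direct_mean = attr(dir, "group_mean"),
                 direct_accuracy = acc,
                 d_indirect_mean = attr(ind, "group_mean"),
                 comparison = cmp, config = config),
            class = "ita_demo")
}

#' @export
print.ita_demo <- function(x, ...) {
  cat("Typical pattern (single latent source drives both tasks):\n")
  cat(sprintf("  mean RT effect = %.1f ms, t(%d) = %.2f, p = %.3g\n",
              x$rt_effect_ms, x$df, x$t, x$p))
  cat(sprintf("  direct d' = %.2f (accuracy %.0f%%)  vs  indirect d' = %.2f\n",
              x$d_direct_mean, 100 * x$direct_accuracy, x$d_indirect_mean))
  cat("Sensitivity comparison:\n")
  print(x$comparison)
  invisible(x)
}
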