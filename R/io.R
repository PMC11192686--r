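# fixed CSV dialect: UTF-8, comma separator, header required, period decimal

search_cols <- c("participant", "epoch", "block", "condition", "rt_ms")
recog_cols <- c("participant", "condition", "response")

#' Read a trial-level CSV
#'
#' Reads either schema of the fixed trial CSV dialect:
#' search tables (`participant, epoch, block, condition, rt_ms[, correct]`)
#' or recognition tables (`participant, condition, response`); the presence
#' of a `response` column selects the recognition schema. Extra columns are
#' kept with a logged warning; row-level violations are reported with their
#' file line numbers (header = line 1).
#'
#' @param path Path to a CSV file.
#' @return A [trial_table()].
#' @export
read_trial_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  task <- if ("response" %in% names(df)) "recognition" else "search"
  need <- if (task == "search") search_cols else recog_cols
  allowed <- c(need, if (task == "search") "correct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), allowed)
  if (length(extra)) {
    warning("ignoring extra column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
    ita_log("read_trial_csv: extra column(s) %s loaded but unused",
            paste(extra, collapse = ", "))
  }
  line <- function(i) i + 1L  # header occupies line 1
  if (task == "search") {
    bad <- which(!is.finite(df$rt_ms) | df$rt_ms <= 0)
    if (length(bad))
      stop(path, ": non-positive rt_ms on line(s) ",
           paste(line(utils::head(bad, 5)), collapse = ", "))
  }
  bad <- which(!df$condition %in% c("repeated", "new"))
  if (length(bad))
    stop(path, ": unknown condition label on line(s) ",
         paste(line(utils::head(bad, 5)), collapse = ", "))
  if (task == "recognition") {
    bad <- which(!df$response %in% c("old", "new"))
    if (length(bad))
      stop(path, ": unknown response label on line(s) ",
           paste(line(utils::head(bad, 5)), collapse = ", "))
  }
  ita_log("read_trial_csv: %d %s trials, %d participants from %s",
          nrow(df), task, length(unique(df$participant)), basename(path))
  trial_table(df, task)
}

#' Read a study-summary CSV
#'
#' Schema: `label, t, N, K, q2, hr, fa, n_direct_signal, n_direct_noise`.
#' A blank `q2` falls back to `q2_default` (logged). Rows violating the
#' estimator's preconditions (`N < 3`, rates at 0/1) are rejected with a
#' hint.
#'
#' @param path Path to a CSV file.
#' @param q2_default Variance-ratio assumption for rows without a stated
#'   `q2` (default 0.09; 0.0225 and 0.25 are conventional sensitivity
#'   alternates).
#' @return Data frame of class `summary_studies`.
#' @export
read_summary_csv <- function(path, q2_default = 0.09) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("label", "t", "N", "K", "q2", "hr", "fa",
            "n_direct_signal", "n_direct_noise")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required column(s): ", paste(miss, collapse = ", "))
  blank <- is.na(df$q2)
  if (any(blank)) {
    df$q2[blank] <- q2_default
    ita_log("read_summary_csv: q2 blank for %s; using default %.4g",
            paste(df$label[blank], collapse = ", "), q2_default)
  }
  line <- function(i) i + 1L
  if (any(df$N < 3))
    stop(path, ": N < 3 on line(s) ",
         paste(line(which(df$N < 3)), collapse = ", "),
         " (estimator undefined for N < 3)")
  bad <- which(df$hr <= 0 | df$hr >= 1 | df$fa <= 0 | df$fa >= 1)
  if (length(bad))
    stop(path, ": hr/fa at or beyond 0/1 on line(s) ",
         paste(line(bad), collapse = ", "),
         "; apply an extreme-rate correction to the counts first")
  if (any(df$q2 < 0))
    stop(path, ": q2 must be >= 0")
  structure(df, class = c("summary_studies", "data.frame"))
}

#' Sensitivity comparison for summary-statistic studies
#'
#' For each study row: the indirect sensitivity is estimated from the
#' reported paired t ([dprime_from_t()]), the direct sensitivity from the
#' reported rates (SE via the delta method at the stated direct trial
#' counts), and the two are compared ([compare_summary()]).
#'
#' @param studies A `summary_studies` data frame (see [read_summary_csv()]).
#' @inheritParams compare_group_trialwise
#' @return List of [comparison_result()] objects, one per study row.
#' @export
analyze_summary_studies <- function(studies, ci_level = 0.95,
                                    bf_scale = 1 / sqrt(2)) {
  stopifnot(is.data.frame(studies), nrow(studies) >= 1)
  lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    d_ind <- dprime_from_t(s$t, s$N, s$K, s$q2)
    d_dir <- sensitivity_estimate(
      dprime = dprime_from_rates(s$hr, s$fa),
      se = se_dprime_from_rates(s$hr, s$fa, s$n_direct_signal,
                                s$n_direct_noise),
      n_signal = s$n_direct_signal, n_noise = s$n_direct_noise,
      source = "direct")
    compare_summary(d_ind, d_dir, N = s$N, ci_level = ci_level,
                    bf_scale = bf_scale, label = s$label)
  })
}

#' Flatten comparison results to a data frame
#'
#' @param results A [comparison_result()] or list of them.
#' @return Data frame with one row per result, deterministic column order.
#' @export
results_table <- function(results) {
  if (inherits(results, "comparison_result")) results <- list(results)
  if (!length(results)) stop("results must be nonempty")
  do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "comparison_result"))
    data.frame(label = r$label, mode = r$mode, d_direct = r$d_direct,
               d_indirect = r$d_indirect, d_difference = r$d_difference,
               se = r$se, ci_low = r$ci_low, ci_high = r$ci_high,
               t = r$t_stat, df = r$df, p = r$p_two_sided,
               bf10 = r$bf10_one_sided, bf_category = r$bf_category,
               decision = r$decision)
  }))
}

#' Write a sensitivity-comparison report
#'
#' Serializes comparison results with a deterministic field order. Numbers
#' are kept at full precision in JSON/CSV; the markdown rendering rounds to
#' `digits` for display.
#'
#' @param results A [comparison_result()] or nonempty list of them.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"markdown"`.
#' @param digits Display digits for the markdown format.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("json", "csv", "markdown"),
                         digits = 2) {
  format <- match.arg(format)
  tab <- results_table(results)
  if (format == "json") {
    jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE)
  } else {
    num <- vapply(tab, is.numeric, logical(1))
    disp <- tab
    disp[num] <- lapply(disp[num], function(x) formatC(x, digits = digits,
                                                       format = "f"))
    header <- paste(names(disp), collapse = " | ")
    sep <- paste(rep("---", ncol(disp)), collapse = " | ")
    body <- apply(disp, 1, paste, collapse = " | ")
    writeLines(c(paste("|", header, "|"), paste("|", sep, "|"),
                 paste("|", body, "|")), path)
  }
  ita_log("write_report: wrote %d result(s) to %s (%s)", nrow(tab), path,
          format)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' The YAML keys mirror the arguments of [simulation_config()]; unknown keys
#' are an error.
#'
#' @param path Path to a YAML file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop(path, ": unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, vals)
}

#' Write simulated trial tables in the trial CSV schema
#'
#' @param sim Result of [simulate_experiment()].
#' @param prefix Output path prefix; writes `<prefix>_search.csv`,
#'   `<prefix>_recognition.csv` and `<prefix>_truth.csv`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_simulation_csv <- function(sim, prefix) {
  paths <- paste0(prefix, c("_search.csv", "_recognition.csv", "_truth.csv"))
  utils::write.csv(as.data.frame(sim$search), paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(sim$recognition), paths[2],
                   row.names = FALSE)
  utils::write.csv(sim$truth, paths[3], row.names = FALSE)
  invisible(paths)
}
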