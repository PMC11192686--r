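#' Trial-level table for a search or recognition task
#'
#' Validates and tags a data frame of trial records.
#'
#' Search tables need columns `participant`, `condition`
#' (`"repeated"`/`"new"`), `rt_ms` (positive, finite) and optionally `epoch`,
#' `block` (positive integers, default 1) and `correct` (0/1). Recognition
#' tables need `participant`, `condition` (true status, `"repeated"`/`"new"`)
#' and `response` (`"old"`/`"new"`).
#'
#' @param records A data frame of trial records.
#' @param task `"search"` or `"recognition"`.
#' @return The validated data frame with class `trial_table` and a `task`
#'   attribute.
#' @export
trial_table <- function(records, task = c("search", "recognition")) {
  task <- match.arg(task)
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records)
  need <- if (task == "search") c("participant", "condition", "rt_ms")
          else c("participant", "condition", "response")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  bad_cond <- which(!records$condition %in% c("repeated", "new"))
  if (length(bad_cond))
    stop("unknown condition label(s) in row(s): ",
         paste(utils::head(bad_cond, 5), collapse = ", "),
         " (must be \"repeated\" or \"new\")")
  if (task == "search") {
    bad_rt <- which(!is.finite(records$rt_ms) | records$rt_ms <= 0)
    if (length(bad_rt))
      stop("non-positive or non-finite rt_ms in row(s): ",
           paste(utils::head(bad_rt, 5), collapse = ", "))
    for (col in c("epoch", "block")) {
      if (is.null(records[[col]])) records[[col]] <- 1L
      if (any(!is.finite(records[[col]]) | records[[col]] < 1 |
                records[[col]] != round(records[[col]])))
        stop(col, " must contain positive integers")
    }
    if (!is.null(records$correct) && !all(records$correct %in% c(0, 1)))
      stop("correct must be 0/1")
  } else {
    bad_resp <- which(!records$response %in% c("old", "new"))
    if (length(bad_resp))
      stop("unknown response label(s) in row(s): ",
           paste(utils::head(bad_resp, 5), collapse = ", "),
           " (must be \"old\" or \"new\")")
  }
  structure(records, class = c("trial_table", "data.frame"), task = task)
}

#' Task of a trial table
#' @param table A `trial_table`.
#' @return `"search"` or `"recognition"`.
#' @export
table_task <- function(table) attr(table, "task")

reassert_table <- function(records, task) {
  structure(as.data.frame(records), class = c("trial_table", "data.frame"),
            task = task)
}

#' Select analysis trials
#'
#' Filters a search table to the epochs under analysis and (optionally) to
#' correct trials. The default `epochs = "last"` keeps only each table's
#' final epoch: late trials carry the largest RT effect relative to their
#' trial-to-trial spread, so analysing them favours finding an indirect
#' advantage (benefit-of-the-doubt policy). Every filter applied is logged.
#'
#' @param table A search `trial_table`.
#' @param epochs `"last"`, `"all"`, or an integer vector of epoch indices.
#' @param correct_only Drop error trials? Default (`NULL`): `TRUE` when a
#'   `correct` column exists, otherwise no filtering.
#' @param rt_range Optional `c(min, max)` bounds on `rt_ms`; trials outside
#'   are dropped (no trimming by default).
#' @return The filtered `trial_table`.
#' @export
select_trials <- function(table, epochs = "last", correct_only = NULL,
                          rt_range = NULL) {
  stopifnot(inherits(table, "trial_table"), table_task(table) == "search")
  n0 <- nrow(table)
  participants <- unique(table$participant)
  if (identical(epochs, "last")) {
    epochs <- max(table$epoch)
  } else if (identical(epochs, "all")) {
    epochs <- sort(unique(table$epoch))
  }
  if (!all(epochs %in% table$epoch))
    stop("requested epoch(s) not present: ",
         paste(setdiff(epochs, table$epoch), collapse = ", "))
  keep <- table$epoch %in% epochs
  if (is.null(correct_only)) correct_only <- !is.null(table$correct)
  if (isTRUE(correct_only)) {
    if (is.null(table$correct))
      stop("correct_only = TRUE but the table has no 'correct' column")
    keep <- keep & table$correct == 1
  }
  if (!is.null(rt_range)) {
    stopifnot(length(rt_range) == 2L, rt_range[1] < rt_range[2])
    keep <- keep & table$rt_ms >= rt_range[1] & table$rt_ms <= rt_range[2]
  }
  out <- table[keep, , drop = FALSE]
  gone <- setdiff(participants, unique(out$participant))
  if (length(gone))
    stop("trial selection left no trials for participant(s): ",
         paste(gone, collapse = ", "))
  ita_log("select_trials: kept %d of %d trials (epochs: %s; correct_only: %s) across %d participants",
          nrow(out), n0, paste(epochs, collapse = ","), correct_only,
          length(participants))
  reassert_table(out, "search")
}

#' Per-participant median RT
#'
#' Midpoint median of all of one participant's selected RTs, both conditions
#' pooled. Pooling across conditions and blocks gives the ideal observer a
#' stable classification criterion, which favours the indirect measure.
#'
#' @param rts Numeric vector of at least 2 RTs.
#' @return The median (same units as input).
#' @export
participant_median <- function(rts) {
  if (length(rts) < 2L) stop("need at least 2 RTs to form a median")
  if (any(!is.finite(rts))) stop("RTs must be finite")
  stats::median(rts)
}

#' Median-split ideal-observer classification
#'
#' Predicts `"repeated"` for trials strictly faster than the participant's
#' median RT and `"new"` otherwise (ties go to `"new"`; the split is optimal
#' for log-normally distributed RTs).
#'
#' @param rt Numeric vector of one participant's selected RTs.
#' @param med Classification criterion; defaults to [participant_median()]
#'   of `rt`.
#' @return Character vector of predicted conditions.
#' @export
median_split_classify <- function(rt, med = participant_median(rt)) {
  ifelse(rt < med, "repeated", "new")
}

# counts for one participant's classified search trials
classify_counts <- function(rt, condition) {
  pred <- median_split_classify(rt)
  recognition_counts(
    hits = sum(condition == "repeated" & pred == "repeated"),
    misses = sum(condition == "repeated" & pred == "new"),
    false_alarms = sum(condition == "new" & pred == "repeated"),
    correct_rejections = sum(condition == "new" & pred == "new")
  )
}

participant_sensitivities <- function(df, source) {
  n <- nrow(df)
  structure(df, class = c("participant_sensitivities", "data.frame"),
            source = source,
            group_mean = mean(df$dprime),
            group_se = stats::sd(df$dprime) / sqrt(n))
}

#' @export
print.participant_sensitivities <- function(x, ...) {
  cat(sprintf("Per-participant %s sensitivities (N = %d): mean d' = %.3f, SE = %.3f\n",
              attr(x, "source"), nrow(x), attr(x, "group_mean"),
              attr(x, "group_se")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Group summary of per-participant sensitivities
#' @param x A `participant_sensitivities` object.
#' @return List with `mean`, `se`, `n`, `source`.
#' @export
group_sensitivity <- function(x) {
  stopifnot(inherits(x, "participant_sensitivities"))
  list(mean = attr(x, "group_mean"), se = attr(x, "group_se"),
       n = nrow(x), source = attr(x, "source"))
}

#' Indirect sensitivity from trial-level search RTs
#'
#' Runs the median-split ideal observer per participant on the selected
#' search trials: trials faster than the participant's pooled median are
#' predicted "repeated", slower ones "new"; comparing predictions with the
#' true condition yields hit and false-alarm rates, hence an indirect
#' d-prime per participant.
#'
#' @inheritParams select_trials
#' @param correction Extreme-rate correction for [rates_from_counts()].
#' @return A `participant_sensitivities` data frame (columns `participant`,
#'   `dprime`, `se`, `hr`, `fa`, `n_signal`, `n_noise`) with the group mean
#'   and its SE as attributes (see [group_sensitivity()]).
#' @export
indirect_dprime_from_trials <- function(table, epochs = "last",
                                        correct_only = NULL,
                                        correction = c("log_linear", "none"),
                                        rt_range = NULL) {
  correction <- match.arg(correction)
  sel <- select_trials(table, epochs = epochs, correct_only = correct_only,
                       rt_range = rt_range)
  by_p <- split(seq_len(nrow(sel)), sel$participant)
  rows <- lapply(names(by_p), function(p) {
    i <- by_p[[p]]
    cond <- sel$condition[i]
    if (sum(cond == "repeated") < 2L || sum(cond == "new") < 2L)
      stop("participant ", p, " has fewer than 2 trials in a condition")
    cnt <- classify_counts(sel$rt_ms[i], cond)
    r <- rates_from_counts(cnt, correction)
    data.frame(participant = p,
               dprime = dprime_from_rates(r[["hr"]], r[["fa"]]),
               se = se_dprime_from_counts(cnt, correction),
               hr = r[["hr"]], fa = r[["fa"]],
               n_signal = cnt$hits + cnt$misses,
               n_noise = cnt$false_alarms + cnt$correct_rejections)
  })
  participant_sensitivities(do.call(rbind, rows), "indirect_trials")
}

#' Direct sensitivity from trial-level recognition responses
#'
#' Per participant, tabulates old/new responses against the true condition
#' and computes the explicit-report d-prime with its delta-method SE.
#'
#' @param table A recognition `trial_table`.
#' @inheritParams indirect_dprime_from_trials
#' @return A `participant_sensitivities` data frame, `source = "direct"`.
#' @export
direct_dprime_from_trials <- function(table,
                                      correction = c("log_linear", "none")) {
  stopifnot(inherits(table, "trial_table"),
            table_task(table) == "recognition")
  correction <- match.arg(correction)
  by_p <- split(seq_len(nrow(table)), table$participant)
  rows <- lapply(names(by_p), function(p) {
    i <- by_p[[p]]
    cond <- table$condition[i]
    resp <- table$response[i]
    if (!any(cond == "repeated") || !any(cond == "new"))
      stop("participant ", p, " is missing a response cell ",
           "(needs both repeated and new trials)")
    cnt <- recognition_counts(
      hits = sum(cond == "repeated" & resp == "old"),
      misses = sum(cond == "repeated" & resp == "new"),
      false_alarms = sum(cond == "new" & resp == "old"),
      correct_rejections = sum(cond == "new" & resp == "new"))
    r <- rates_from_counts(cnt, correction)
    data.frame(participant = p,
               dprime = dprime_from_rates(r[["hr"]], r[["fa"]]),
               se = se_dprime_from_counts(cnt, correction),
               hr = r[["hr"]], fa = r[["fa"]],
               n_signal = cnt$hits + cnt$misses,
               n_noise = cnt$false_alarms + cnt$correct_rejections)
  })
  participant_sensitivities(do.call(rbind, rows), "direct")
}
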