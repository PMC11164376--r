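#' Pooled reaction-time trimming
#'
#' Removes the fastest and slowest `tail` fraction of trials, pooling all
#' participants, sessions and blocks, before drift-diffusion fitting.
#' Quantiles use the default linear-interpolation sample quantile; rows
#' exactly at a quantile are retained, so a table of identical RTs loses
#' no rows. Correct and incorrect trials are both kept.
#'
#' @param trials trial table with an `rt` column.
#' @param tail fraction removed at each end (default 0.01).
#' @return The filtered table.
#' @export
trim_rt <- function(trials, tail = 0.01) {
  stopifnot(tail >= 0, tail < 0.5)
  if (nrow(trials) == 0) {
    warning("empty trial table; nothing to trim")
    return(trials)
  }
  if (tail == 0) return(trials)
  q <- stats::quantile(trials$rt, c(tail, 1 - tail), names = FALSE)
  trials[trials$rt >= q[1] & trials$rt <= q[2], ]
}

#' Per-block accuracy table
#'
#' Accuracy in percent per participant x session x block, training and
#' generalization blocks reported separately (`phase` column).
#'
#' @param trials trial table with `participant_id`, `session`, `block`,
#'   `phase`, `correct`.
#' @return tibble with `n_trials`, `accuracy_pct`, `mean_rt` per cell.
#' @export
block_accuracy <- function(trials) {
  dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$session,
                    .data$block, .data$phase),
    n_trials = dplyr::n(),
    accuracy_pct = 100 * mean(.data$correct),
    mean_rt = mean(.data$rt),
    .groups = "drop")
}

#' Learner cutoff: final-block accuracy at or below this percentage marks
#' a non-learner (chance 25% plus a 10-point band under the study's
#' cumulative-binomial convention for 40 trials at p = 0.25).
#' @export
LEARNER_CUTOFF_PCT <- 35

#' Classify learners from final-block accuracy
#'
#' A participant is a non-learner if their accuracy in the last training
#' block of the last session is at or below the chance-based cutoff
#' (default [LEARNER_CUTOFF_PCT], i.e. exactly 35% is a non-learner), and
#' a learner otherwise.
#'
#' @param final_block_acc_pct numeric vector of final-block accuracies.
#' @param cutoff_pct cutoff in percent.
#' @return character vector, `"learner"` or `"non_learner"`; `NA`
#'   accuracies yield `NA` (unclassifiable).
#' @export
classify_learner <- function(final_block_acc_pct,
                             cutoff_pct = LEARNER_CUTOFF_PCT) {
  ifelse(is.na(final_block_acc_pct), NA_character_,
         ifelse(final_block_acc_pct <= cutoff_pct,
                "non_learner", "learner"))
}

#' Score an operation-span task
#'
#' Sum of the span lengths of all perfectly recalled spans: a span counts
#' its full length if the recalled sequence matches the presented one
#' exactly and in order, and zero otherwise. Arithmetic accuracy is not
#' used for filtering. Maximum 75 over 15 trials of spans 3-7.
#'
#' @param records tibble of OSPAN rows with `span_length` and list-columns
#'   `presented_letters`, `recalled_letters`.
#' @return integer score in `[0, 75]`.
#' @export
ospan_score <- function(records) {
  need <- c("span_length", "presented_letters", "recalled_letters")
  if (!all(need %in% names(records))) {
    stop("malformed OSPAN records: need ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$span_length != lengths(records$presented_letters))) {
    stop("span_length inconsistent with presented sequence", call. = FALSE)
  }
  ok <- mapply(function(p, r) length(p) == length(r) && all(p == r),
               records$presented_letters, records$recalled_letters)
  as.integer(sum(records$span_length[ok]))
}

#' Maintenance deltas across adjacent blocks
#'
#' For each participant, accuracy changes (percentage points) between
#' adjacent training blocks separated by no delay (block 5 to 6 within
#' sessions 1 and 2) or by the inter-session delay (block 6 of one
#' session to block 1 of the next, transitions 1 to 2 and 2 to 3).
#' Negative delay deltas indicate forgetting over the gap.
#'
#' @param metrics block accuracy table from [block_accuracy()].
#' @return tibble with `participant_id`, `transition` (1 or 2), `delay`
#'   (`"delay"` or `"no_delay"`), `delta_pct`.
#' @export
maintenance_scores <- function(metrics) {
  acc <- function(pid, ses, blk) {
    v <- metrics$accuracy_pct[metrics$participant_id == pid &
                                metrics$session == ses &
                                metrics$block == blk &
                                metrics$phase == "training"]
    if (length(v) == 1) v else NA_real_
  }
  pids <- unique(metrics$participant_id)
  out <- lapply(pids, function(pid) {
    tibble::tibble(
      participant_id = pid,
      transition = rep(1:2, 2L),
      delay = rep(c("no_delay", "delay"), each = 2L),
      delta_pct = c(acc(pid, 1, 6) - acc(pid, 1, 5),
                    acc(pid, 2, 6) - acc(pid, 2, 5),
                    acc(pid, 2, 1) - acc(pid, 1, 6),
                    acc(pid, 3, 1) - acc(pid, 2, 6)))
  })
  dplyr::bind_rows(out)
}

#' Generalization scores
#'
#' Per participant x session: accuracy on the feedback-free
#' generalization block minus accuracy on the final training block, in
#' percentage points.
#'
#' @param metrics block accuracy table from [block_accuracy()].
#' @param final_block index of the last training block (default 6).
#' @return tibble with `participant_id`, `session`, `generalization_pct`
#'   (the raw test accuracy) and `generalization_score_pct`.
#' @export
generalization_score <- function(metrics, final_block = 6L) {
  gen <- metrics[metrics$phase == "generalization", ]
  fin <- metrics[metrics$phase == "training" &
                   metrics$block == final_block, ]
  m <- dplyr::left_join(
    gen[, c("participant_id", "session", "accuracy_pct")],
    fin[, c("participant_id", "session", "accuracy_pct")],
    by = c("participant_id", "session"),
    suffix = c("_gen", "_final"))
  tibble::tibble(participant_id = m$participant_id, session = m$session,
                 generalization_pct = m$accuracy_pct_gen,
                 generalization_score_pct =
                   m$accuracy_pct_gen - m$accuracy_pct_final)
}

#' High/low WM grouping by median split
#'
#' Scores at or above the sample median are `"high"`, below are `"low"`.
#' Used for visualization grouping only; association models always use
#' the raw OSPAN score.
#'
#' @param ospan_scores numeric vector (at least 2 values).
#' @return character vector of `"high"` / `"low"`.
#' @export
median_split <- function(ospan_scores) {
  stopifnot(length(ospan_scores) >= 2)
  md <- stats::median(ospan_scores)
  ifelse(ospan_scores >= md, "high", "low")
}

#' Assemble the per-participant metrics table
#'
#' Convenience wrapper joining block accuracies, learner classification,
#' OSPAN scores and WM grouping into one participant-level table, the
#' input expected by the association models.
#'
#' @param trials trial table (untrimmed or trimmed; accuracy metrics use
#'   whatever is supplied).
#' @param ospan tibble with `participant_id`, `ospan_score`.
#' @param final_session,final_block cell used for learner classification.
#' @return list with `blocks` (block accuracy table), `participants`
#'   (one row each: `ospan_score`, `learner`, `wm_group`,
#'   `final_block_acc_pct`), `maintenance`, `generalization`.
#' @export
behavior_metrics <- function(trials, ospan, final_session = 3L,
                             final_block = 6L) {
  blocks <- block_accuracy(trials)
  fin <- blocks[blocks$session == final_session &
                  blocks$block == final_block &
                  blocks$phase == "training",
                c("participant_id", "accuracy_pct")]
  names(fin)[2] <- "final_block_acc_pct"
  part <- dplyr::left_join(ospan, fin, by = "participant_id")
  part$learner <- classify_learner(part$final_block_acc_pct)
  part$wm_group <- median_split(part$ospan_score)
  list(blocks = blocks, participants = part,
       maintenance = maintenance_scores(blocks),
       generalization = generalization_score(blocks, final_block))
}
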