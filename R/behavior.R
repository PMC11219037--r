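#' Model-free behavioral summaries
#'
#' Computes, per subject, wave and feedback-timing condition: accuracy
#' (proportion of contingent choices over valid trials), win-stay and
#' lose-shift proportions, and the valid trial count.  Stay/shift
#' transitions are evaluated within cue - the next valid trial of the
#' same cue - because contingencies are cue-specific and cues are
#' interleaved; non-response trials break a transition and enter no
#' denominator.  A poor-learner flag (see [flag_poor_learners()]) is
#' attached per subject-wave.
#'
#' @param data A `choice_data` data frame.
#' @param window,threshold Passed to [flag_poor_learners()].
#' @return Data frame with one row per subject x wave x condition:
#'   `accuracy`, `win_stay`, `lose_shift`, `n_valid`, `poor_learner`.
#'   Proportions with empty denominators are `NA`.
#' @export
summarize_behavior <- function(data, window = 20, threshold = 0.5) {
  data <- as_choice_data(data)
  flags <- flag_poor_learners(data, window, threshold)
  groups <- unique(data[, c("subject_id", "wave", "condition")])
  groups <- groups[order(groups$subject_id, groups$wave, groups$condition), ]
  res <- lapply(seq_len(nrow(groups)), function(g) {
    d <- data[data$subject_id == groups$subject_id[g] &
              data$wave == groups$wave[g] &
              data$condition == groups$condition[g], ]
    valid <- d[d$choice != "none", ]
    acc <- if (nrow(valid)) mean(valid$choice == "contingent") else NA_real_
    ws_num <- ws_den <- ls_num <- ls_den <- 0L
    for (cue in unique(d$cue_id)) {
      v <- valid[valid$cue_id == cue, ]
      if (nrow(v) < 2) next
      stay <- v$choice[-1] == v$choice[-nrow(v)]
      # a transition only counts when the trials are consecutive
      # presentations of the cue (a non-response in between breaks it)
      all_cue <- d[d$cue_id == cue, ]
      pres <- match(v$trial_index, all_cue$trial_index)
      adjacent <- diff(pres) == 1
      win <- v$reward[-nrow(v)] == 1
      ws_num <- ws_num + sum(stay & win & adjacent)
      ws_den <- ws_den + sum(win & adjacent)
      ls_num <- ls_num + sum(!stay & !win & adjacent)
      ls_den <- ls_den + sum(!win & adjacent)
    }
    fl <- flags$poor_learner[flags$subject_id == groups$subject_id[g] &
                             flags$wave == groups$wave[g]]
    data.frame(subject_id = groups$subject_id[g], wave = groups$wave[g],
               condition = groups$condition[g], accuracy = acc,
               win_stay = if (ws_den) ws_num / ws_den else NA_real_,
               lose_shift = if (ls_den) ls_num / ls_den else NA_real_,
               n_valid = nrow(valid),
               poor_learner = if (length(fl)) fl else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag poor learners
#'
#' A subject-wave is flagged when accuracy over the last `window` valid
#' trials (pooled across conditions) fails to reach `threshold`:
#' strictly below flags, exactly reaching does not.  Subject-waves with
#' fewer valid trials than `window` are judged on all their valid
#' trials.
#'
#' @param data A `choice_data` data frame.
#' @param window Number of final valid trials examined (default 20).
#' @param threshold Accuracy that must be reached (default 0.5).
#' @return Data frame `subject_id`, `wave`, `late_accuracy`,
#'   `poor_learner`.
#' @export
flag_poor_learners <- function(data, window = 20, threshold = 0.5) {
  data <- as_choice_data(data)
  groups <- unique(data[, c("subject_id", "wave")])
  groups <- groups[order(groups$subject_id, groups$wave), ]
  res <- lapply(seq_len(nrow(groups)), function(g) {
    d <- data[data$subject_id == groups$subject_id[g] &
              data$wave == groups$wave[g] & data$choice != "none", ]
    if (!nrow(d))
      return(data.frame(subject_id = groups$subject_id[g],
                        wave = groups$wave[g], late_accuracy = NA_real_,
                        poor_learner = NA, stringsAsFactors = FALSE))
    last <- tail(d$choice, min(window, nrow(d)))
    acc <- mean(last == "contingent")
    data.frame(subject_id = groups$subject_id[g], wave = groups$wave[g],
               late_accuracy = acc, poor_learner = acc < threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Drop non-response trials
#'
#' Removes rows with `choice == "none"` and reports the per-wave
#' excluded proportions in the `"excluded"` attribute.  Subjects left
#' with zero valid trials are removed entirely with a warning.
#'
#' @param data A `choice_data` data frame.
#' @return The cleaned `choice_data` frame.
#' @export
drop_nonresponses <- function(data) {
  data <- as_choice_data(data)
  excl <- tapply(data$choice == "none", data$wave, mean)
  out <- data[data$choice != "none", , drop = FALSE]
  kept <- unique(out$subject_id)
  gone <- setdiff(unique(data$subject_id), kept)
  if (length(gone))
    warning("subject(s) with no valid trials removed: ",
            paste(gone, collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("choice_data", "data.frame")
  attr(out, "excluded") <- excl
  out
}
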