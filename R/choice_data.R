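#' Trial-level choice data
#'
#' A choice dataset is a long-format data frame with one row per trial and
#' columns `subject_id`, `wave` (1 or 2), `trial_index` (1-based within
#' wave), `block`, `cue_id`, `condition` (`"immediate"` or `"delayed"`),
#' `choice` (`"contingent"`, `"noncontingent"` or `"none"` for a
#' non-response), `reward` (0/1, `NA` on non-response) and optionally
#' `p_contingent` (latent probability recorded by the simulator).
#' `as_choice_data()` validates the columns and sorts rows into the
#' canonical subject / wave / trial order used by all model code.
#'
#' @param x A data frame with the columns above.
#' @return A data frame of class `choice_data` in canonical row order.
#' @export
as_choice_data <- function(x) {
  need <- c("subject_id", "wave", "trial_index", "block", "cue_id",
            "condition", "choice", "reward")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("choice data lacks columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)
  if (!all(x$wave %in% c(1L, 2L)))
    stop("wave must be 1 or 2")
  if (!all(x$condition %in% c("immediate", "delayed")))
    stop("condition must be 'immediate' or 'delayed'")
  if (!all(x$choice %in% c("contingent", "noncontingent", "none")))
    stop("choice must be 'contingent', 'noncontingent' or 'none'")
  bad <- x$choice != "none" & (!x$reward %in% c(0, 1) | is.na(x$reward))
  if (any(bad))
    stop("reward must be 0/1 on valid-response trials")
  ord <- order(x$subject_id, x$wave, x$trial_index)
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("choice_data", "data.frame")
  x
}

#' Read / write trial records as CSV
#'
#' Round-trip-safe long-format CSV serialization of a choice dataset.
#'
#' @param path File path.
#' @param data A `choice_data` data frame (or coercible).
#' @return `read_trials()` returns a `choice_data` data frame;
#'   `write_trials()` returns `path` invisibly.
#' @export
read_trials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if ("reward" %in% names(df)) df$reward <- suppressWarnings(as.integer(df$reward))
  as_choice_data(df)
}

#' @rdname read_trials
#' @export
write_trials <- function(data, path) {
  data <- as_choice_data(data)
  write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Encode a dataset into the flat integer arrays the C++ kernels consume.
# Blocks are contiguous subject-wave runs; cue ids are re-indexed 0-based
# within each subject-wave (wave-2 cues are new objects, so states never
# carry across waves).
encode_dataset <- function(data) {
  data <- as_choice_data(data)
  n <- nrow(data)
  if (n == 0L)
    return(list(blk_start = integer(0), blk_len = integer(0),
                sub_of_blk = integer(0), wave_of_blk = integer(0),
                cue = integer(0), cond = integer(0), choice = integer(0),
                reward = integer(0), n_cues = 1L, n_sub = 0L,
                subjects = character(0),
                block_key = data.frame(subject_id = character(0),
                                       wave = integer(0)),
                data = data))
  key <- paste(data$subject_id, data$wave, sep = "\r")
  blk <- match(key, unique(key))
  blk_start <- as.integer(tapply(seq_len(n), blk, min)) - 1L
  blk_len <- as.integer(tabulate(blk))
  ublk <- !duplicated(blk)
  subjects <- sort(unique(data$subject_id))
  sub_of_blk <- match(data$subject_id[ublk], subjects) - 1L
  wave_of_blk <- as.integer(data$wave[ublk]) - 1L
  cue0 <- integer(n)
  for (b in seq_along(blk_start)) {
    i <- (blk_start[b] + 1L):(blk_start[b] + blk_len[b])
    cue0[i] <- match(data$cue_id[i], sort(unique(data$cue_id[i]))) - 1L
  }
  list(
    blk_start = blk_start, blk_len = blk_len,
    sub_of_blk = sub_of_blk, wave_of_blk = wave_of_blk,
    cue = cue0,
    cond = as.integer(data$condition == "delayed"),
    choice = ifelse(data$choice == "none", -1L,
                    as.integer(data$choice == "contingent")),
    reward = ifelse(is.na(data$reward), -1L, as.integer(data$reward)),
    n_cues = max(tapply(cue0, blk, max)) + 1L,
    n_sub = length(subjects), subjects = subjects,
    block_key = data.frame(subject_id = data$subject_id[ublk],
                           wave = data$wave[ublk]),
    data = data)
}
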