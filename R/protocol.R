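#' Define a learning set
#'
#' A learning set is a block of consecutive training days governed by a
#' single reward rule: one relevant sensory dimension (odor or LED color;
#' location is never relevant) and one correct feature within it.  The
#' reward schedule is deterministic: choosing the option that carries the
#' correct feature is always rewarded, the alternative never is.
#'
#' @param set_label Set name, one of `"ODOR1"`, `"ODOR2"`, `"LED"`.
#' @param relevant_dimension `"odor"` or `"led"`.
#' @param correct_feature Which feature of the relevant dimension is
#'   rewarded, `1` or `2`.
#' @param n_days Number of training days in the set.
#' @param trials_per_day Trials per day, either a single number or a
#'   vector of length `n_days`.  Daily sessions in this task run 50-100
#'   trials.
#' @param odor_pair_id Integer tag distinguishing the odor pair in use;
#'   intra- and extra-dimensional shifts introduce new odor pairs, but
#'   feature indices stay in `{1, 2}` because values are re-zeroed at set
#'   boundaries, so the pair identity is metadata only.
#'
#' @return A one-row tibble describing the set.
#' @export
set_spec <- function(set_label, relevant_dimension, correct_feature = 1L,
                     n_days = 5L, trials_per_day = 100L, odor_pair_id = 1L) {
  set_label <- match.arg(set_label, c("ODOR1", "ODOR2", "LED"))
  relevant_dimension <- match.arg(relevant_dimension, c("odor", "led"))
  stopifnot(correct_feature %in% 1:2, n_days >= 1)
  if (length(trials_per_day) == 1L) {
    trials_per_day <- rep(as.integer(trials_per_day), n_days)
  }
  if (length(trials_per_day) != n_days || any(trials_per_day < 1)) {
    abort("`trials_per_day` must be positive, length 1 or `n_days`.")
  }
  tibble(
    set_label = set_label,
    relevant_dimension = relevant_dimension,
    correct_feature = as.integer(correct_feature),
    n_days = as.integer(n_days),
    trials_per_day = list(as.integer(trials_per_day)),
    odor_pair_id = as.integer(odor_pair_id)
  )
}

#' Build an experiment protocol
#'
#' The odor-first protocol trains the sets ODOR1 -> ODOR2 (intra-dimensional
#' shift: new odor pair, odor still rules) -> LED (extra-dimensional shift).
#' The LED-first protocol trains LED -> ODOR1 (extra-dimensional shift only).
#'
#' @param group `"odor_first"` or `"led_first"`.
#' @param n_days Days per set, a vector as long as the group's set
#'   sequence (3 sets odor-first, 2 sets LED-first).
#' @param trials_per_day Trials per day (single number, or a list with one
#'   vector per set).
#'
#' @return A tibble with one row per set, in training order, carrying a
#'   `group` column.
#' @export
#' @examples
#' maze_protocol("odor_first", n_days = c(4, 3, 8))
maze_protocol <- function(group = c("odor_first", "led_first"),
                          n_days = NULL, trials_per_day = 100L) {
  group <- match.arg(group)
  labels <- if (group == "odor_first") c("ODOR1", "ODOR2", "LED") else c("LED", "ODOR1")
  if (is.null(n_days)) {
    n_days <- if (group == "odor_first") c(4L, 2L, 8L) else c(6L, 7L)
  }
  if (length(n_days) != length(labels)) {
    abort(sprintf("`n_days` must have length %d for group '%s'.",
                  length(labels), group))
  }
  if (!is.list(trials_per_day)) {
    trials_per_day <- if (length(trials_per_day) == length(labels)) {
      as.list(trials_per_day)        # one scalar per set
    } else {
      rep(list(trials_per_day), length(labels))
    }
  }
  # new odor pair at each shift involving odors
  pair_id <- cumsum(rep(1L, length(labels)))
  sets <- pmap(
    list(labels, n_days, trials_per_day, pair_id),
    function(lab, nd, tpd, pid) {
      set_spec(lab,
               relevant_dimension = if (lab == "LED") "led" else "odor",
               correct_feature = 1L, n_days = nd, trials_per_day = tpd,
               odor_pair_id = pid)
    }
  )
  mutate(list_rbind(sets), group = group, .before = 1)
}

# Validate a behavioral log tibble; returns the log invisibly or aborts
# with row-numbered diagnostics. Used by read_maze_log() and the replay
# entry points.
validate_log <- function(log, strict = TRUE) {
  missing_cols <- setdiff(setdiff(log_columns, "group"), names(log))
  if (length(missing_cols) > 0) {
    abort(paste0("log is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0) {
      abort(sprintf("invalid log: %s (rows %s)", what,
                    paste(head(i, 5), collapse = ", ")))
    }
  }
  bad(!(log$arm_a %in% 1:4) | !(log$arm_b %in% 1:4), "arm out of 1..4")
  bad(!(log$odor_a %in% 1:2) | !(log$odor_b %in% 1:2), "odor out of 1..2")
  bad(!(log$led_a %in% 1:2) | !(log$led_b %in% 1:2), "LED color out of 1..2")
  bad(log$arm_a == log$arm_b, "both options on the same arm")
  bad(log$odor_a == log$odor_b, "both options carry the same odor")
  bad(log$led_a == log$led_b, "both options carry the same LED color")
  bad(!(log$chosen %in% c("a", "b")), "chosen must be 'a' or 'b'")
  bad(!(log$reward %in% 0:1), "reward must be 0 or 1")
  key <- paste(log$set_label, log$day, log$trial)
  if (anyDuplicated(key)) {
    abort(sprintf("invalid log: duplicate (set, day, trial) key (rows %s)",
                  paste(head(which(duplicated(key)), 5), collapse = ", ")))
  }
  ord <- order(match(log$set_label, unique(log$set_label)), log$day, log$trial)
  if (is.unsorted(ord, strictly = TRUE) && !identical(ord, seq_len(nrow(log)))) {
    abort("invalid log: trials are not in chronological order within sets")
  }
  invisible(log)
}

# Split a (possibly multi-set) log into single-set logs in training order.
split_sets <- function(log) {
  split(log, factor(log$set_label, levels = unique(log$set_label)))
}
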