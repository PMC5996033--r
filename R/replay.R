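# Encode a single-set log for the C++ replay kernel.
# Returns feat matrix, chosen/reward/day integer vectors and day count.
encode_set_log <- function(log) {
  if (length(unique(log$set_label)) != 1) {
    abort("expected a single-set log; use split_sets() or filter first.")
  }
  if (is.unsorted(log$day)) abort("log days must be in chronological order.")
  days <- unique(log$day)
  day_index <- match(log$day, days)
  for (d in seq_along(days)) {
    tr <- log$trial[day_index == d]
    if (is.unsorted(tr, strictly = TRUE)) {
      abort(sprintf("trials within day %s are not strictly increasing", days[d]))
    }
  }
  list(
    feat = cbind(log$arm_a, log$odor_a, log$led_a,
                 log$arm_b, log$odor_b, log$led_b),
    chosen = as.integer(log$chosen == "b"),
    reward = as.integer(log$reward),
    day = as.integer(day_index),
    n_days = length(days),
    days = days
  )
}

check_params_cover <- function(params, enc) {
  if (length(params$alpha) != enc$n_days) {
    abort(sprintf("params supply %d day(s) of parameters but the log has %d.",
                  length(params$alpha), enc$n_days))
  }
}

weights_matrix <- function(params, model) {
  if (model == "wam") params$weights else matrix(numeric(0), 0, 3)
}

#' Replay a behavioral log under a model
#'
#' Deterministically re-runs one set's log through a model: starting from
#' all-zero values, each trial's decision index, choice probability and
#' deterministic prediction are computed from the pre-update state, after
#' which the chosen option's values are updated with the day's learning
#' rate.  Day boundaries switch the day parameters (and apply the
#' overnight decay) but values persist within the set.
#'
#' @param log A single-set behavioral log (see [simulate_agent()] /
#'   [read_maze_log()]).
#' @param params A [set_params()] covering the log's days.
#' @param model `"nrl"` or `"wam"`.
#' @return A tibble, one row per trial, with `set_label, day, trial,
#'   index, p_choose_a, p_chosen, deterministic_pick` (`"a"`, `"b"` or
#'   `"tie"`) and the per-trial log-likelihood contribution `ll`.
#' @export
replay_log <- function(log, params, model = c("nrl", "wam")) {
  model <- match_model(model[1])
  params_match_model(params, model)
  enc <- encode_set_log(log)
  check_params_cover(params, enc)
  out <- replay_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
                    params$alpha, weights_matrix(params, model),
                    params$beta, params$decay, model == "wam", FALSE)
  tibble(
    set_label = log$set_label, day = log$day, trial = log$trial,
    index = out$index,
    p_choose_a = out$p_a,
    p_chosen = ifelse(enc$chosen == 0L, out$p_a, 1 - out$p_a),
    deterministic_pick = dplyr::case_when(
      out$index > 0 ~ "a", out$index < 0 ~ "b", TRUE ~ "tie"
    ),
    ll = out$ll
  )
}

#' Value trajectory of a replayed log
#'
#' Like [replay_log()] but returns the post-update value state after each
#' trial: 16 combination-value columns for the NRL, 8 feature-value
#' columns for the WAM.
#'
#' @inheritParams replay_log
#' @return A tibble with `set_label, day, trial` and one column per value
#'   entry.
#' @export
value_trajectory <- function(log, params, model = c("nrl", "wam")) {
  model <- match_model(model[1])
  params_match_model(params, model)
  enc <- encode_set_log(log)
  check_params_cover(params, enc)
  out <- replay_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
                    params$alpha, weights_matrix(params, model),
                    params$beta, params$decay, model == "wam", TRUE)
  vals <- out$values
  colnames(vals) <- names(if (model == "nrl") nrl_values() else wam_values())
  bind_cols(tibble(set_label = log$set_label, day = log$day, trial = log$trial),
            as_tibble(vals))
}

#' Log-likelihood of a set's choices under a model
#'
#' Replays the log and returns the sum over trials of the log softmax
#' probability assigned to the animal's actual choice.  Strictly negative
#' for any finite inverse temperature (every choice probability is in
#' (0, 1)).
#'
#' @inheritParams replay_log
#' @param by_day If `TRUE`, return the per-day log-likelihood vector
#'   instead of the total.
#' @return Total log-likelihood (scalar) or per-day vector.
#' @export
set_log_likelihood <- function(log, params, model = c("nrl", "wam"),
                               by_day = FALSE) {
  model <- match_model(model[1])
  params_match_model(params, model)
  enc <- encode_set_log(log)
  check_params_cover(params, enc)
  if (by_day) {
    out <- replay_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
                      params$alpha, weights_matrix(params, model),
                      params$beta, params$decay, model == "wam", FALSE)
    setNames(out$day_ll, enc$days)
  } else {
    ll_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
           params$alpha, weights_matrix(params, model),
           params$beta, params$decay, model == "wam")
  }
}
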