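#' Draw one offered pair of options
#'
#' Each trial offers two options on two distinct arms; both odors and both
#' LED colors are always present, one per option.  The unordered arm pair
#' is drawn uniformly from the 6 possible pairs, then odor labels `{1, 2}`
#' and LED labels `{1, 2}` are assigned to the two options uniformly and
#' independently.  Uses the current R random-number state (seed it with
#' `set.seed()` for reproducibility).  Draw order: arm pair, odor
#' assignment, LED assignment.
#'
#' @return A one-row tibble with columns
#'   `arm_a, odor_a, led_a, arm_b, odor_b, led_b`.
#' @export
generate_offered_pair <- function() {
  as_tibble(draw_pair())
}

# plain-list fast path shared with the simulation loop; identical draws
draw_pair <- function() {
  arms <- sample.int(4L, 2L)
  odors <- sample.int(2L)
  leds <- sample.int(2L)
  list(arm_a = arms[1], odor_a = odors[1], led_a = leds[1],
       arm_b = arms[2], odor_b = odors[2], led_b = leds[2])
}

#' Which offered option is correct?
#'
#' Under the deterministic reward schedule exactly one of the two offered
#' options carries the set's correct feature on the relevant dimension.
#'
#' @param pair Offered pair(s): a data frame with columns
#'   `arm_a, odor_a, led_a, arm_b, odor_b, led_b` (vectorized over rows).
#' @param relevant_dimension `"odor"` or `"led"`.
#' @param correct_feature The rewarded feature index, 1 or 2.
#' @return Character vector of `"a"`/`"b"`.
#' @export
correct_choice <- function(pair, relevant_dimension, correct_feature) {
  relevant_dimension <- match.arg(relevant_dimension, c("odor", "led"))
  fa <- if (relevant_dimension == "odor") pair$odor_a else pair$led_a
  fb <- if (relevant_dimension == "odor") pair$odor_b else pair$led_b
  if (any(fa == fb)) {
    abort("invalid trial: both options carry the same feature on the relevant dimension")
  }
  ifelse(fa == correct_feature, "a",
         ifelse(fb == correct_feature, "b",
                NA_character_))
}

#' Simulate an artificial agent on a protocol
#'
#' Generates a full behavioral log by running the chosen model in
#' generative mode: at each trial the decision index is computed from the
#' current values, option a is chosen with its softmax probability, the
#' reward follows the deterministic schedule, and the chosen option's
#' values are updated with the day's learning rate.  Values are reset to
#' zero at the start of every set and carried across days within a set
#' (multiplied by the overnight `decay` of the set's parameters at each
#' day boundary).
#'
#' The log is fully reproducible from `(protocol, params, seed)`.  Per
#' trial the draw order is: arm pair, odor assignment, LED assignment,
#' choice.
#'
#' @param protocol A protocol tibble from [maze_protocol()] (or rows of
#'   [set_spec()] with a `group` column).
#' @param model `"nrl"` or `"wam"`.
#' @param params A single [set_params()] used for every set, or a named
#'   list of `set_params` keyed by `set_label`.  The per-set `alpha`
#'   length must equal that set's `n_days`.
#' @param seed Integer seed.
#' @return A behavioral-log tibble with columns
#'   `group, set_label, day, trial, arm_a, odor_a, led_a, arm_b, odor_b,
#'   led_b, chosen, reward`, carrying the generating parameters in the
#'   `"params"` attribute.
#' @export
#' @examples
#' prot <- maze_protocol("odor_first", n_days = c(2, 2, 2), trials_per_day = 50)
#' pars <- set_params(alpha = c(0.3, 0.3), beta = 5, weights = c(0.2, 0.6, 0.2))
#' log <- simulate_agent(prot, "wam", pars, seed = 1)
#' daily_success_rate(log)
simulate_agent <- function(protocol, model = c("nrl", "wam"), params, seed) {
  model <- match_model(model[1])
  withr::local_seed(as.integer(seed))
  params_by_set <- resolve_params(protocol, model, params)

  rows <- vector("list", nrow(protocol))
  for (s in seq_len(nrow(protocol))) {
    spec <- protocol[s, ]
    p <- params_by_set[[spec$set_label]]
    tpd <- spec$trials_per_day[[1]]
    values <- if (model == "nrl") nrl_values() else wam_values()
    n_set <- sum(tpd)
    feat <- matrix(NA_integer_, n_set, 6)
    day_col <- rep(seq_len(spec$n_days), tpd)
    trial_col <- unlist(lapply(tpd, seq_len), use.names = FALSE)
    chosen_col <- character(n_set)
    reward_col <- integer(n_set)
    r <- 0L
    for (d in seq_len(spec$n_days)) {
      if (d > 1L) values <- values * p$decay
      for (t in seq_len(tpd[d])) {
        pair <- draw_pair()
        index <- if (model == "nrl") {
          nrl_decision_index(values, pair)
        } else {
          wam_decision_index(values, p$weights[d, ], pair)
        }
        p_a <- choice_probability(index, p$beta)
        chosen <- if (stats::runif(1) < p_a) "a" else "b"
        corr <- correct_choice(pair, spec$relevant_dimension, spec$correct_feature)
        reward <- as.integer(chosen == corr)
        ch <- if (chosen == "a") {
          list(arm = pair$arm_a, odor = pair$odor_a, led = pair$led_a)
        } else {
          list(arm = pair$arm_b, odor = pair$odor_b, led = pair$led_b)
        }
        values <- if (model == "nrl") {
          nrl_update(values, ch, reward, p$alpha[d])
        } else {
          wam_update(values, ch, reward, p$alpha[d])
        }
        r <- r + 1L
        feat[r, ] <- c(pair$arm_a, pair$odor_a, pair$led_a,
                       pair$arm_b, pair$odor_b, pair$led_b)
        chosen_col[r] <- chosen
        reward_col[r] <- reward
      }
    }
    rows[[s]] <- tibble(
      group = spec$group, set_label = spec$set_label,
      day = day_col, trial = trial_col,
      arm_a = feat[, 1], odor_a = feat[, 2], led_a = feat[, 3],
      arm_b = feat[, 4], odor_b = feat[, 5], led_b = feat[, 6],
      chosen = chosen_col, reward = reward_col
    )
  }
  out <- list_rbind(rows)[, log_columns]
  attr(out, "params") <- params_by_set
  attr(out, "model") <- model
  out
}

resolve_params <- function(protocol, model, params) {
  if (inherits(params, "set_params")) {
    params <- setNames(rep(list(params), nrow(protocol)), protocol$set_label)
  }
  if (!all(protocol$set_label %in% names(params))) {
    abort("`params` must name every set in the protocol.")
  }
  for (s in seq_len(nrow(protocol))) {
    lab <- protocol$set_label[s]
    p <- params[[lab]]
    params_match_model(p, model)
    if (length(p$alpha) != protocol$n_days[s]) {
      abort(sprintf("set %s: %d alphas supplied for %d days.",
                    lab, length(p$alpha), protocol$n_days[s]))
    }
  }
  params[protocol$set_label]
}

#' Simulate a cohort of agents
#'
#' Runs [simulate_agent()] once per animal with per-animal seeds and
#' stacks the logs with an `animal` identifier column.
#'
#' @inheritParams simulate_agent
#' @param n_animals Number of agents.
#' @param seed Base seed; animal `i` uses `seed + i`.
#' @param params Shared [set_params()] (or named list per set), or a list
#'   of length `n_animals` with one spec per animal.
#' @return A behavioral-log tibble with a leading `animal` column.
#' @export
simulate_cohort <- function(protocol, model, params, n_animals, seed) {
  per_animal <- is.list(params) && !inherits(params, "set_params") &&
    length(params) == n_animals && is.null(names(params))
  logs <- map(seq_len(n_animals), function(i) {
    p <- if (per_animal) params[[i]] else params
    log <- simulate_agent(protocol, model, p, seed = seed + i)
    mutate(log, animal = sprintf("agent%02d", i), .before = 1)
  })
  list_rbind(logs)
}
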