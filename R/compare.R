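#' Deterministic (no-exploration) model fit by day
#'
#' Fraction of each day's choices matching the model's deterministic
#' prediction -- the sign of the decision index computed from the
#' accumulated values, with no softmax noise.  A zero index is a tie and
#' contributes 0.5, so the fraction equals
#' `(matches + 0.5 * ties) / trials`.
#'
#' On deterministic-reward logs the NRL can only predict correct choices
#' (options lacking the correct feature keep value 0), so on days without
#' ties its deterministic fit equals the day's success rate.
#'
#' @inheritParams replay_log
#' @return A tibble per day: `day, n_trials, n_ties, fraction`.
#' @export
deterministic_fit <- function(log, params, model = c("nrl", "wam")) {
  model <- match_model(model[1])
  if (nrow(log) == 0) abort("empty log: deterministic fit is undefined.")
  pred <- replay_log(log, params, model)
  pred |>
    mutate(chosen = log$chosen) |>
    group_by(day) |>
    summarise(
      n_trials = dplyr::n(),
      n_ties = sum(deterministic_pick == "tie"),
      fraction = (sum(deterministic_pick == chosen) + 0.5 * n_ties) / n_trials,
      .groups = "drop"
    )
}

#' AIC-style comparison of the WAM and the NRL on one set
#'
#' Computes the score `ln L_WAM - ln L_NRL - d`, where the likelihoods
#' are summed over the *included* days and `d = 2 N` is the difference in
#' parameter count over the `N` included days (the WAM spends 3 free
#' parameters per day, the NRL 1; both share one inverse temperature per
#' set, which cancels).  Following the original analysis, only days on
#' which the NRL's deterministic fit exceeds 0.5 (strictly) are included.
#' A positive score favors the WAM.  Note the score is a log-likelihood
#' difference minus the parameter-count difference, without the
#' conventional factor of 2.
#'
#' @param fit_wam,fit_nrl `maze_fit` objects for the same set log.
#' @return A one-row tibble: `set_label, aic_score, n_days_included, d,
#'   ll_wam, ll_nrl, no_comparable_days`.  With zero included days the
#'   score is `NA` and `no_comparable_days` is `TRUE`.
#' @export
aic_compare <- function(fit_wam, fit_nrl) {
  stopifnot(inherits(fit_wam, "maze_fit"), inherits(fit_nrl, "maze_fit"))
  if (fit_wam$model != "wam" || fit_nrl$model != "nrl") {
    abort("`fit_wam` must be a WAM fit and `fit_nrl` an NRL fit.")
  }
  if (!identical(fit_wam$set_label, fit_nrl$set_label) ||
      fit_wam$n_trials != fit_nrl$n_trials) {
    abort("the two fits must be on the same set log.")
  }
  det_nrl <- deterministic_fit(fit_nrl$data, fit_nrl$params, "nrl")
  included <- det_nrl$fraction > 0.5
  n_inc <- sum(included)
  days <- sort(unique(fit_nrl$data$day))
  if (n_inc == 0) {
    return(tibble(set_label = fit_wam$set_label, aic_score = NA_real_,
                  n_days_included = 0L, d = 0L, ll_wam = NA_real_,
                  ll_nrl = NA_real_, no_comparable_days = TRUE))
  }
  keep <- as.character(days[included])
  ll_wam <- sum(fit_wam$per_day_ll[keep])
  ll_nrl <- sum(fit_nrl$per_day_ll[keep])
  tibble(
    set_label = fit_wam$set_label,
    aic_score = ll_wam - ll_nrl - 2 * n_inc,
    n_days_included = as.integer(n_inc), d = 2L * n_inc,
    ll_wam = ll_wam, ll_nrl = ll_nrl, no_comparable_days = FALSE
  )
}

#' Within-day 90/10 cross-validation
#'
#' For each day of a single-set log: refit the model on the set truncated
#' at that day's first `ceiling(0.9 n)` trials (all earlier days intact,
#' later days excluded), then predict the day's remaining test trials by
#' the fitted model's maximum-probability choice (ties score 0.5) and
#' report the matched fraction.  Test trials are never seen during
#' fitting.  Days too short to leave a nonempty test split are skipped
#' with a warning.
#'
#' @inheritParams grid_initialize
#' @return A tibble per evaluated day: `day, n_train, n_test, fraction`.
#' @export
cross_validate <- function(log, model = c("nrl", "wam"), config = fit_config()) {
  model <- match_model(model[1])
  days <- sort(unique(log$day))
  out <- map(days, function(d) {
    day_log <- filter(log, day == d)
    n <- nrow(day_log)
    n_train <- ceiling(0.9 * n)
    n_test <- n - n_train
    if (n_test == 0) {
      warn(sprintf("day %s: %d trials leave no test split; skipped.", d, n))
      return(NULL)
    }
    train <- bind_rows(filter(log, day < d), head(day_log, n_train))
    fit <- fit_set(train, model, config)
    # replay train + test with the fitted parameters; score the tail
    eval_log <- bind_rows(train, tail(day_log, n_test))
    pred <- replay_log(eval_log, fit$params, model)
    test_pred <- tail(pred, n_test)
    test_chosen <- tail(day_log$chosen, n_test)
    pick <- ifelse(test_pred$p_choose_a > 0.5, "a",
                   ifelse(test_pred$p_choose_a < 0.5, "b", "tie"))
    tibble(
      day = d, n_train = n_train, n_test = n_test,
      fraction = (sum(pick == test_chosen) + 0.5 * sum(pick == "tie")) / n_test
    )
  })
  list_rbind(out)
}

#' Full model comparison on one set
#'
#' Fits both models, then assembles the AIC-style score, the per-day
#' 90/10 cross-validation fractions, the per-day deterministic fits of
#' both models and the daily success rate.
#'
#' @inheritParams grid_initialize
#' @param cross_validation If `FALSE`, skip the (refitting-heavy)
#'   cross-validation step.
#' @return An object of class `maze_comparison`: a list with `$aic`
#'   (see [aic_compare()]), `$by_day` (per-day tibble with success rate,
#'   deterministic fits and CV fractions for both models), `$fit_wam`,
#'   `$fit_nrl`.
#' @export
compare_models <- function(log, config = fit_config(), cross_validation = TRUE) {
  fit_wam <- fit_set(log, "wam", config)
  fit_nrl <- fit_set(log, "nrl", config)
  det_w <- deterministic_fit(log, fit_wam$params, "wam")
  det_n <- deterministic_fit(log, fit_nrl$params, "nrl")
  by_day <- daily_success_rate(log) |>
    select(-dplyr::any_of("set_label")) |>
    left_join(det_w |> select(day, det_fit_wam = fraction), by = "day") |>
    left_join(det_n |> select(day, det_fit_nrl = fraction), by = "day")
  if (cross_validation) {
    cv_w <- cross_validate(log, "wam", config)
    cv_n <- cross_validate(log, "nrl", config)
    by_day <- by_day |>
      left_join(cv_w |> select(day, cv_wam = fraction), by = "day") |>
      left_join(cv_n |> select(day, cv_nrl = fraction), by = "day")
  }
  structure(
    list(set_label = unique(log$set_label), aic = aic_compare(fit_wam, fit_nrl),
         by_day = by_day, fit_wam = fit_wam, fit_nrl = fit_nrl),
    class = "maze_comparison"
  )
}

#' @export
print.maze_comparison <- function(x, ...) {
  cat(sprintf("<maze_comparison: set %s>\n", x$set_label))
  print(x$aic, ...)
  print(x$by_day, ...)
  invisible(x)
}

#' @export
tidy.maze_comparison <- function(x, ...) x$by_day

#' @export
glance.maze_comparison <- function(x, ...) x$aic
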