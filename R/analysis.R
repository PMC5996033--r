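#' Daily success rate
#'
#' Fraction of rewarded trials per day, grouped by any of `animal`,
#' `set_label` present in the log.
#'
#' @param log Behavioral log.
#' @return A tibble with the grouping columns plus `day, n_trials,
#'   success_rate`.
#' @export
daily_success_rate <- function(log) {
  if (nrow(log) == 0) abort("empty log: success rate is undefined.")
  keys <- intersect(c("animal", "set_label", "day"), names(log))
  set_order <- unique(log$set_label)
  log |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    summarise(n_trials = dplyr::n(), success_rate = mean(reward),
              .groups = "drop") |>
    arrange(dplyr::across(dplyr::any_of("animal")),
            match(set_label, set_order), day)
}

#' First day reaching the learning criterion
#'
#' Learning of a set is declared on the first day whose success rate
#' reaches the criterion (default 75%, inclusive).  Animals that never
#' reach it get `NA`.
#'
#' @param rates Per-day success rates from [daily_success_rate()]
#'   (columns `day`, `success_rate`, ordered by day; grouped by any
#'   `animal`/`set_label` columns present).
#' @param threshold Criterion success rate, default 0.75.
#' @return A tibble with the grouping columns and `criterion_day`
#'   (`NA` integer if never reached).
#' @export
criterion_day <- function(rates, threshold = 0.75) {
  keys <- intersect(c("animal", "set_label"), names(rates))
  rates |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    arrange(day, .by_group = TRUE) |>
    summarise(
      criterion_day = if (any(success_rate >= threshold)) {
        day[which(success_rate >= threshold)[1]]
      } else {
        NA_integer_
      },
      .groups = "drop"
    )
}

#' Early/late stage split of a learning set
#'
#' The first day whose success rate reaches the stage threshold (default
#' 70%, inclusive) starts the late stage; that day and all following days
#' are late, all earlier days early.  The crossing is permanent: later
#' dips do not revert days to early.  If the threshold is never reached
#' all days are early and the set is flagged.
#'
#' @inheritParams criterion_day
#' @param threshold Stage threshold, default 0.70.
#' @return The input with `stage` (`"early"`/`"late"`) and
#'   `never_crossed` columns added.
#' @export
stage_split <- function(rates, threshold = 0.70) {
  keys <- intersect(c("animal", "set_label"), names(rates))
  rates |>
    group_by(dplyr::across(dplyr::all_of(keys))) |>
    arrange(day, .by_group = TRUE) |>
    mutate(
      stage = ifelse(cumsum(success_rate >= threshold) > 0, "late", "early"),
      never_crossed = !any(success_rate >= threshold)
    ) |>
    ungroup()
}

#' Choice-by-correct-arm matrix
#'
#' Counts how often each arm was chosen, against the arm that was correct
#' on the trial.  Correct choices sit on the diagonal; a spatial bias
#' shows as a disproportionate column.  The matrix total equals the trial
#' count and, with the deterministic reward schedule, the diagonal total
#' equals the rewarded-trial count.
#'
#' @param log Behavioral log (typically one day of one set; grouping
#'   columns among `animal`, `set_label`, `day` are preserved).
#' @return A tibble in long form: grouping columns plus
#'   `correct_arm, chosen_arm, n`.  Use [choice_matrix_wide()] for the
#'   4 x 4 layout of a single day.
#' @export
choice_matrix <- function(log) {
  # deterministic schedule: the correct option is the chosen one iff rewarded
  chosen_arm <- ifelse(log$chosen == "a", log$arm_a, log$arm_b)
  other_arm <- ifelse(log$chosen == "a", log$arm_b, log$arm_a)
  correct_arm <- ifelse(log$reward == 1, chosen_arm, other_arm)
  keys <- intersect(c("animal", "set_label", "day"), names(log))
  log |>
    mutate(correct_arm = correct_arm, chosen_arm = chosen_arm) |>
    group_by(dplyr::across(dplyr::all_of(c(keys, "correct_arm", "chosen_arm")))) |>
    summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      correct_arm = 1:4, chosen_arm = 1:4, fill = list(n = 0L)
    )
}

#' @rdname choice_matrix
#' @param counts Output of [choice_matrix()] restricted to one day.
#' @return `choice_matrix_wide()`: a 4 x 4 integer matrix with rows =
#'   correct arm, columns = chosen arm.
#' @export
choice_matrix_wide <- function(counts) {
  stopifnot(nrow(counts) == 16)
  m <- matrix(0L, 4, 4, dimnames = list(correct = 1:4, chosen = 1:4))
  m[cbind(counts$correct_arm, counts$chosen_arm)] <- counts$n
  m
}

#' Per-day decision weights of a cohort of fitted WAM sets
#'
#' Gathers the per-day fitted weights of many animals' WAM fits into the
#' long format used by the aggregation and stage analyses.
#'
#' @param fits A tibble from [fit_experiment()] (columns `animal`,
#'   `set_label`, `model`, `fit`), or a list of `maze_fit`s (then animals
#'   are taken from the list names).
#' @return A tibble `animal, set_label, day, dimension, weight` with
#'   `dimension` in `location, odor, led`.
#' @export
cohort_weights <- function(fits) {
  if (inherits(fits, "data.frame")) {
    fits <- filter(fits, model == "wam")
    tab <- fits |>
      mutate(td = map(fit, tidy)) |>
      select(dplyr::any_of("animal"), td) |>
      tidyr::unnest(td)
  } else {
    tab <- imap(fits, function(f, nm) mutate(tidy(f), animal = nm, .before = 1)) |>
      list_rbind()
  }
  tab |>
    tidyr::pivot_longer(
      dplyr::all_of(c("w_location", "w_odor", "w_led")),
      names_to = "dimension", names_prefix = "w_", values_to = "weight"
    ) |>
    mutate(dimension = factor(dimension, dimension_levels)) |>
    select(dplyr::any_of("animal"), set_label, day, dimension, weight)
}

#' Aggregate decision weights across animals
#'
#' Mean and standard error of the fitted decision weights per set, day
#' and dimension.  Day cells with a single animal get an `NA` SEM and
#' are flagged; optionally, days observed in fewer than half of the
#' cohort's animals are dropped (mirroring group learning-curve plots
#' that only show days with at least half the animals).
#'
#' @param weights Long weight table from [cohort_weights()].
#' @param drop_below_half Drop set/day cells covered by fewer than half
#'   of the animals (default `TRUE`).
#' @return A tibble `set_label, day, dimension, n_animals, mean_weight,
#'   sem, single_animal`.
#' @export
aggregate_weights <- function(weights, drop_below_half = TRUE) {
  n_cohort <- length(unique(weights$animal))
  out <- weights |>
    group_by(set_label, day, dimension) |>
    summarise(
      n_animals = dplyr::n(),
      mean_weight = mean(weight),
      sem = if (dplyr::n() > 1) sd(weight) / sqrt(dplyr::n()) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(single_animal = n_animals == 1)
  if (drop_below_half) out <- filter(out, n_animals >= n_cohort / 2)
  out
}

#' Per-animal per-stage mean weights
#'
#' Joins the stage split onto the per-day weights and averages within
#' animal x set x stage x dimension -- the long-format table a
#' repeated-measures ANOVA of the weight dynamics consumes.
#'
#' @param weights Long weight table from [cohort_weights()].
#' @param stages Stage table from [stage_split()] (per animal, with
#'   `set_label, day, stage`).
#' @return A tibble `animal, set_label, stage, dimension, mean_weight,
#'   n_days`.
#' @export
stage_weight_table <- function(weights, stages) {
  keys <- intersect(c("animal", "set_label", "day"), names(stages))
  weights |>
    inner_join(select(stages, dplyr::all_of(c(keys, "stage"))), by = keys) |>
    group_by(dplyr::across(dplyr::any_of(c("animal", "set_label", "stage", "dimension")))) |>
    summarise(mean_weight = mean(weight), n_days = dplyr::n_distinct(day),
              .groups = "drop")
}
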