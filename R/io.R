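#' Read and write behavioral-log CSV files
#'
#' The log dialect is a comma-separated UTF-8 file with header columns
#' `group,set_label,day,trial,arm_a,odor_a,led_a,arm_b,odor_b,led_b,chosen,reward`
#' (an optional leading `animal` column is preserved); day and trial
#' indices are 1-based.  Reading validates every row against the trial
#' invariants (distinct arms/odors/LED colors across the two options,
#' legal feature indices, chronological ordering, unique
#' (set, day, trial) keys) with row-numbered diagnostics.  In strict mode
#' a reward inconsistent with the log's inferred reward rule aborts;
#' otherwise it warns, since real apparatus logs may contain errors.
#'
#' @param path File path.
#' @param strict Abort (`TRUE`, default) or warn on reward
#'   inconsistencies.
#' @return `read_maze_log()`: the validated log tibble.
#' @export
read_maze_log <- function(path, strict = TRUE) {
  header <- strsplit(readLines(path, n = 1), ",")[[1]]
  char_cols <- intersect(c("animal", "group", "set_label", "chosen"), header)
  spec <- do.call(readr::cols,
                  c(setNames(rep(list("c"), length(char_cols)), char_cols),
                    list(.default = readr::col_integer())))
  log <- readr::read_csv(path, show_col_types = FALSE, col_types = spec)
  missing_cols <- setdiff(log_columns, names(log))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if ("animal" %in% names(log)) {
    split(log, log$animal) |> map(validate_log)
  } else {
    validate_log(log)
  }
  check_reward_consistency(log, strict)
  log
}

# With the deterministic schedule, within one set's log the rewarded
# choices must all carry one feature of one dimension. Infer the rule
# from the rewarded trials and flag contradictions.
check_reward_consistency <- function(log, strict = TRUE) {
  groups <- split(log, paste(if ("animal" %in% names(log)) log$animal else "",
                             log$set_label))
  for (g in groups) {
    chosen_odor <- ifelse(g$chosen == "a", g$odor_a, g$odor_b)
    chosen_led <- ifelse(g$chosen == "a", g$led_a, g$led_b)
    consistent <- FALSE
    for (feat in list(chosen_odor, chosen_led)) {
      for (f in 1:2) {
        if (all((feat == f) == (g$reward == 1))) consistent <- TRUE
      }
    }
    if (!consistent) {
      msg <- sprintf(
        "set %s: rewards are not consistent with any single feature rule",
        unique(g$set_label))
      if (strict) abort(msg) else warn(msg)
    }
  }
  invisible(log)
}

#' @rdname read_maze_log
#' @param log Behavioral log tibble.
#' @return `write_maze_log()`: `path`, invisibly.
#' @export
write_maze_log <- function(log, path) {
  cols <- c(intersect("animal", names(log)), log_columns)
  readr::write_csv(log[, cols], path)
  invisible(path)
}

#' Serialize fitted parameters and fits to JSON
#'
#' Parameters and fit summaries round-trip through JSON with full double
#' precision (17 significant digits).
#'
#' @param x A [set_params()] or `maze_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(x, path) {
  if (inherits(x, "maze_fit")) {
    obj <- list(
      type = "maze_fit", set_label = x$set_label, model = x$model,
      params = params_to_list(x$params),
      log_likelihood = x$log_likelihood,
      per_day_ll = unname(x$per_day_ll), converged = x$converged,
      n_trials = x$n_trials, n_days = x$n_days,
      n_parameters = x$n_parameters, beta_at_bound = x$beta_at_bound
    )
  } else if (inherits(x, "set_params")) {
    obj <- c(list(type = "set_params"), params_to_list(x))
  } else {
    abort("`x` must be a set_params or maze_fit object.")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

params_to_list <- function(p) {
  list(alpha = p$alpha, beta = p$beta,
       weights = if (!is.null(p$weights)) unname(apply(p$weights, 1, c, simplify = FALSE)),
       decay = p$decay)
}

#' @rdname write_params
#' @return `read_params()`: the deserialized [set_params()].
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "set_params")) {
    abort("not a serialized set_params object.")
  }
  set_params(alpha = obj$alpha, beta = obj$beta,
             weights = if (!is.null(obj$weights)) do.call(rbind, as.list(as.data.frame(t(obj$weights)))) else NULL,
             decay = obj$decay)
}

#' Run the full pipeline on a simulated cohort
#'
#' Simulate a cohort, fit both models per animal and set, compare them,
#' and write the report tables: the behavioral log, per-fit JSON, the
#' success-rate, criterion, stage, choice-matrix and weight-dynamics
#' CSVs, and the AIC comparison table.  Re-running with the same
#' configuration and seed reproduces identical outputs.
#'
#' @param protocol A [maze_protocol()] tibble.
#' @param params Generating [set_params()] (shared or per set, see
#'   [simulate_agent()]).
#' @param n_animals Cohort size.
#' @param seed Base seed.
#' @param out_dir Output directory (created if needed).
#' @param model Generating model for the simulation.
#' @param fit_models Models to fit (default both; with only `"wam"` the
#'   AIC comparison is skipped with a notice).
#' @param config [fit_config()] used for all fits.
#' @param cross_validation Include the 90/10 CV columns (slow).
#' @return Invisibly, a list with the log, fits and report tables.
#' @export
run_pipeline <- function(protocol, params, n_animals, seed, out_dir,
                         model = "wam", fit_models = c("nrl", "wam"),
                         config = fit_config(), cross_validation = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- simulate_cohort(protocol, model, params, n_animals, seed)
  write_maze_log(log, file.path(out_dir, "log.csv"))

  fits <- fit_experiment(log, fit_models, config)
  for (i in seq_len(nrow(fits))) {
    write_params(fits$fit[[i]],
                 file.path(out_dir, sprintf("fit_%s_%s_%s.json",
                                            fits$animal[i], fits$set_label[i],
                                            fits$model[i])))
  }

  rates <- daily_success_rate(log)
  readr::write_csv(rates, file.path(out_dir, "success_rates.csv"))
  readr::write_csv(criterion_day(rates), file.path(out_dir, "criterion_days.csv"))
  stages <- stage_split(rates)
  readr::write_csv(stages, file.path(out_dir, "stages.csv"))
  readr::write_csv(choice_matrix(log), file.path(out_dir, "choice_matrices.csv"))

  report <- list(log = log, fits = fits, rates = rates, stages = stages)

  if (all(c("nrl", "wam") %in% fit_models)) {
    aic <- fits |>
      tidyr::pivot_wider(names_from = model, values_from = fit) |>
      mutate(cmp = map2(wam, nrl, aic_compare)) |>
      select(animal, set_label, cmp) |>
      tidyr::unnest(cmp, names_sep = "_")
    readr::write_csv(aic, file.path(out_dir, "aic_comparison.csv"))
    report$aic <- aic
  } else {
    message("single-model run: AIC comparison skipped.")
  }

  if ("wam" %in% fit_models) {
    weights <- cohort_weights(fits)
    readr::write_csv(weights, file.path(out_dir, "weights_by_day.csv"))
    readr::write_csv(aggregate_weights(weights),
                     file.path(out_dir, "weights_aggregate.csv"))
    readr::write_csv(stage_weight_table(weights, stages),
                     file.path(out_dir, "weights_by_stage.csv"))
    report$weights <- weights
  }

  if (cross_validation) {
    cv <- fits |>
      mutate(cv = pmap(list(animal, set_label, model), function(an, sl, m) {
        cross_validate(filter(log, animal == an, set_label == sl), m, config)
      })) |>
      select(animal, set_label, model, cv) |>
      tidyr::unnest(cv)
    readr::write_csv(cv, file.path(out_dir, "cross_validation.csv"))
    report$cv <- cv
  }
  invisible(report)
}
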