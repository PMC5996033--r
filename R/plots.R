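#' Plot daily success rates
#'
#' Learning curves per set (and per animal if present), with the chance
#' level and the 75% learning criterion marked.
#'
#' @param rates Output of [daily_success_rate()].
#' @param criterion Criterion line to draw (default 0.75).
#' @return A ggplot object.
#' @export
plot_success_rate <- function(rates, criterion = 0.75) {
  p <- ggplot2::ggplot(rates, ggplot2::aes(day, success_rate)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = criterion, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_grid(cols = ggplot2::vars(set_label), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "training day", y = "success rate")
  if ("animal" %in% names(rates)) {
    p + ggplot2::geom_line(ggplot2::aes(group = animal), alpha = 0.35) +
      ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1)
  } else {
    p + ggplot2::geom_line() + ggplot2::geom_point()
  }
}

#' Plot cohort weight dynamics
#'
#' Mean fitted decision weight per day and dimension with SEM ribbons,
#' faceted by set -- odor and LED weights by default (the location weight
#' is fitted too; include it with `dimensions`).
#'
#' @param agg Output of [aggregate_weights()].
#' @param dimensions Dimensions to draw.
#' @return A ggplot object.
#' @export
plot_weight_dynamics <- function(agg, dimensions = c("odor", "led")) {
  dat <- filter(agg, dimension %in% dimensions)
  ggplot2::ggplot(dat, ggplot2::aes(day, mean_weight, colour = dimension)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = mean_weight - sem, ymax = mean_weight + sem,
                   fill = dimension), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(cols = ggplot2::vars(set_label), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(odor = "black", led = "grey55",
                                            location = "steelblue"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "training day", y = "decision weight")
}

#' Plot a choice-by-correct-arm matrix
#'
#' @param counts Output of [choice_matrix()].
#' @return A ggplot tile plot; correct choices sit on the diagonal.
#' @export
plot_choice_matrix <- function(counts) {
  p <- ggplot2::ggplot(counts,
                       ggplot2::aes(chosen_arm, correct_arm, fill = n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = n), colour = "white") +
    ggplot2::scale_y_reverse(breaks = 1:4) +
    ggplot2::scale_x_continuous(breaks = 1:4) +
    ggplot2::labs(x = "chosen arm", y = "correct arm")
  if ("day" %in% names(counts) && length(unique(counts$day)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(day))
  }
  p
}

#' Deterministic model fit against success rate
#'
#' Scatter of each day's deterministic (no-exploration) model fit against
#' the day's success rate, for both models.  The NRL concentrates on the
#' diagonal on deterministic-reward logs; points above the diagonal are
#' mistakes the model explains.
#'
#' @param comparison A `maze_comparison` from [compare_models()], or its
#'   `$by_day` table.
#' @return A ggplot object.
#' @export
plot_deterministic_fit <- function(comparison) {
  by_day <- if (inherits(comparison, "maze_comparison")) comparison$by_day else comparison
  dat <- by_day |>
    tidyr::pivot_longer(dplyr::all_of(c("det_fit_wam", "det_fit_nrl")),
                        names_to = "model", names_prefix = "det_fit_",
                        values_to = "fit")
  ggplot2::ggplot(dat, ggplot2::aes(success_rate, fit, colour = model)) +
    ggplot2::geom_abline(linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::coord_equal(xlim = 0:1, ylim = 0:1) +
    ggplot2::labs(x = "success rate", y = "deterministic model fit")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a fitted set
#'
#' Per-day fitted learning rates (and decision weights for a WAM fit).
#'
#' @param object A `maze_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.maze_fit <- function(object, ...) {
  td <- tidy(object)
  long <- td |>
    tidyr::pivot_longer(dplyr::any_of(c("alpha", "w_location", "w_odor", "w_led")),
                        names_to = "parameter")
  ggplot2::ggplot(long, ggplot2::aes(day, value, colour = parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("%s fit, set %s (beta = %.2f)",
                      toupper(object$model), object$set_label,
                      object$params$beta),
      x = "training day", y = "estimate"
    )
}
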