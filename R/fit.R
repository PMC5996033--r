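#' Fitting configuration
#'
#' Controls the grid initialization and the constrained optimization used
#' by [fit_set()].  The grid shares one (learning rate, weight triple)
#' point across all days of a set to keep it tractable; the optimizer
#' then refines every day parameter jointly.
#'
#' @param grid_alpha_step Learning-rate grid spacing on `[0, 1]`
#'   (default 0.05).
#' @param grid_beta_step Inverse-temperature grid spacing on `[0, 30]`
#'   (default 1).
#' @param grid_weight_step Simplex-lattice spacing for the WAM weight
#'   grid (default 0.1: all nonnegative multiples of 0.1 summing to 1).
#' @param beta_bounds Bounds for the inverse temperature.
#' @param decay Overnight value retention in `[0, 1]` (1 = plain
#'   carry-over), used both in replay during fitting and in the returned
#'   parameters.
#' @param tol Relative convergence tolerance handed to the optimizer.
#' @param max_iter Iteration cap for the optimizer.
#' @param n_restarts Seeded random restarts added to the grid start; the
#'   best final likelihood wins.
#' @param restart_seed Seed for the restart draws (fixed so fits are
#'   deterministic).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(grid_alpha_step = 0.05, grid_beta_step = 1,
                       grid_weight_step = 0.1, beta_bounds = c(0, 30),
                       decay = 1, tol = 1e-8, max_iter = 500L,
                       n_restarts = 5L, restart_seed = 20331L) {
  stopifnot(grid_alpha_step > 0, grid_beta_step > 0, grid_weight_step > 0,
            length(beta_bounds) == 2, beta_bounds[1] < beta_bounds[2],
            decay >= 0, decay <= 1, tol > 0, max_iter >= 1, n_restarts >= 0)
  structure(
    list(grid_alpha_step = grid_alpha_step, grid_beta_step = grid_beta_step,
         grid_weight_step = grid_weight_step, beta_bounds = beta_bounds,
         decay = decay, tol = tol, max_iter = as.integer(max_iter),
         n_restarts = as.integer(n_restarts),
         restart_seed = as.integer(restart_seed)),
    class = "fit_config"
  )
}

# All simplex-lattice points with given step, rows in ascending
# lexicographic (w_l, w_o, w_c) order.
simplex_lattice <- function(step) {
  k <- round(1 / step)
  if (abs(k * step - 1) > 1e-8) {
    abort("`grid_weight_step` must divide 1 (e.g. 0.1, 0.05).")
  }
  pts <- list()
  for (i in 0:k) {
    for (j in 0:(k - i)) {
      pts[[length(pts) + 1L]] <- c(i, j, k - i - j) / k
    }
  }
  m <- do.call(rbind, pts)
  colnames(m) <- c("w_location", "w_odor", "w_led")
  m
}

#' Grid-search initialization of set parameters
#'
#' Exhaustive deterministic search over a thin parameter grid: learning
#' rate on `seq(0, 1, grid_alpha_step)`, inverse temperature on
#' `seq(beta_bounds[1], beta_bounds[2], grid_beta_step)` and, for the
#' WAM, decision weights on the simplex lattice with spacing
#' `grid_weight_step`.  One (alpha, weights) point is shared across all
#' days.  Ties resolve to the lexicographically smallest parameter
#' vector `(alpha, beta, w)`.
#'
#' @inheritParams replay_log
#' @param config A [fit_config()].
#' @return The best grid point as a [set_params()], with the achieved
#'   log-likelihood in attribute `"logLik"`.
#' @export
grid_initialize <- function(log, model = c("nrl", "wam"), config = fit_config()) {
  model <- match_model(model[1])
  enc <- encode_set_log(log)
  alpha_grid <- seq(0, 1, by = config$grid_alpha_step)
  beta_grid <- seq(config$beta_bounds[1], config$beta_bounds[2],
                   by = config$grid_beta_step)
  w_grid <- if (model == "wam") {
    simplex_lattice(config$grid_weight_step)
  } else {
    matrix(numeric(0), 0, 3)
  }
  best <- grid_search_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
                          alpha_grid, beta_grid, w_grid, config$decay,
                          model == "wam", enc$n_days)
  params <- set_params(
    alpha = rep(best$alpha, enc$n_days), beta = best$beta,
    weights = if (model == "wam") {
      matrix(best$w, enc$n_days, 3, byrow = TRUE)
    },
    decay = config$decay
  )
  attr(params, "logLik") <- best$ll
  params
}

# --- parameter vector packing -------------------------------------------
# theta layout: alpha_1..D, then for WAM (z_o_d, z_c_d) per day, then beta.
# Weights per day are softmax(0, z_o, z_c): the location coordinate is
# pinned at 0, giving a smooth bijection onto the simplex interior.
Z_BOUND <- 9

softmax3 <- function(z_o, z_c) {
  e <- exp(c(0, z_o, z_c) - max(0, z_o, z_c))
  e / sum(e)
}

weights_to_z <- function(w, eps = 1e-3) {
  w <- pmax(w, eps)
  w <- w / sum(w)
  pmin(pmax(c(log(w[2] / w[1]), log(w[3] / w[1])), -Z_BOUND), Z_BOUND)
}

pack_theta <- function(params, model) {
  d <- length(params$alpha)
  if (model == "nrl") {
    c(params$alpha, params$beta)
  } else {
    z <- t(apply(params$weights, 1, weights_to_z))
    c(params$alpha, as.vector(t(z)), params$beta)
  }
}

unpack_theta <- function(theta, model, n_days, decay) {
  alpha <- theta[seq_len(n_days)]
  beta <- theta[length(theta)]
  weights <- NULL
  if (model == "wam") {
    z <- matrix(theta[n_days + seq_len(2 * n_days)], n_days, 2, byrow = TRUE)
    weights <- t(apply(z, 1, function(r) softmax3(r[1], r[2])))
    colnames(weights) <- c("w_location", "w_odor", "w_led")
  }
  set_params(alpha = alpha, beta = beta, weights = weights, decay = decay)
}

theta_bounds <- function(model, n_days, beta_bounds) {
  if (model == "nrl") {
    list(lower = c(rep(0, n_days), beta_bounds[1]),
         upper = c(rep(1, n_days), beta_bounds[2]))
  } else {
    list(lower = c(rep(0, n_days), rep(-Z_BOUND, 2 * n_days), beta_bounds[1]),
         upper = c(rep(1, n_days), rep(Z_BOUND, 2 * n_days), beta_bounds[2]))
  }
}

#' Maximum-likelihood fit of one learning set
#'
#' Jointly maximizes the choice log-likelihood of one set's log over all
#' per-day parameters plus the set-level inverse temperature, under the
#' box constraints `alpha in [0, 1]`, `beta in [0, 30]` and, for the WAM,
#' per-day weights on the probability simplex (handled by a smooth
#' softmax reparameterization with the location coordinate pinned at 0).
#' Optimization is L-BFGS-B started from the [grid_initialize()] optimum
#' plus `n_restarts` seeded random starts; the reported solution is never
#' below the grid optimum (the exact grid point is kept if no start
#' improves on it).  Optimizer failure is reported via `converged =
#' FALSE` with the best parameters found, never an error.
#'
#' @inheritParams grid_initialize
#' @return An object of class `maze_fit`: a list with the fitted
#'   [set_params()] (`$params`), `$log_likelihood`, `$per_day_ll`,
#'   `$converged`, `$n_trials`, `$n_days`, `$n_parameters`,
#'   `$beta_at_bound`, `$model`, `$set_label` and the input log in
#'   `$data`.  Supports [tidy()], [glance()], [stats::logLik()] and
#'   [autoplot()][ggplot2::autoplot].
#' @export
#' @examples
#' prot <- maze_protocol("odor_first", n_days = c(2, 1, 1), trials_per_day = 60)
#' log <- simulate_agent(prot, "nrl", list(
#'   ODOR1 = set_params(c(0.3, 0.3), 5),
#'   ODOR2 = set_params(0.3, 5), LED = set_params(0.3, 5)
#' ), seed = 2)
#' fit <- fit_set(dplyr::filter(log, set_label == "ODOR1"), "nrl")
#' glance(fit)
fit_set <- function(log, model = c("nrl", "wam"), config = fit_config()) {
  model <- match_model(model[1])
  enc <- encode_set_log(log)
  n_days <- enc$n_days
  neg_ll <- function(theta) {
    p <- unpack_theta(theta, model, n_days, config$decay)
    -ll_cpp(enc$feat, enc$chosen, enc$reward, enc$day,
            p$alpha, weights_matrix(p, model), p$beta, config$decay,
            model == "wam")
  }
  grid_params <- grid_initialize(log, model, config)
  grid_ll <- attr(grid_params, "logLik")
  bounds <- theta_bounds(model, n_days, config$beta_bounds)

  starts <- list(pack_theta(grid_params, model))
  if (config$n_restarts > 0) {
    starts <- c(starts, withr::with_seed(config$restart_seed, {
      map(seq_len(config$n_restarts), function(i) {
        th <- stats::runif(length(bounds$lower),
                           pmax(bounds$lower, c(rep(0.02, n_days),
                                                rep(-2, length(bounds$lower) - n_days - 1),
                                                0.2)),
                           pmin(bounds$upper, c(rep(0.98, n_days),
                                                rep(2, length(bounds$lower) - n_days - 1),
                                                15)))
        th
      })
    }))
  }

  best_ll <- -Inf
  best_theta <- starts[[1]]
  converged <- FALSE
  for (th0 in starts) {
    res <- tryCatch(
      optim(th0, neg_ll, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = config$max_iter,
                           factr = config$tol / .Machine$double.eps)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) next
    if (-res$value > best_ll) {
      best_ll <- -res$value
      best_theta <- res$par
      converged <- res$convergence == 0
    }
  }
  # never return below the grid optimum
  if (best_ll < grid_ll) {
    params <- grid_params
    attr(params, "logLik") <- NULL
    best_ll <- grid_ll
  } else {
    params <- unpack_theta(best_theta, model, n_days, config$decay)
  }
  per_day <- set_log_likelihood(log, params, model, by_day = TRUE)
  structure(
    list(
      set_label = unique(log$set_label), model = model, params = params,
      log_likelihood = best_ll, per_day_ll = per_day,
      converged = converged, n_trials = nrow(log), n_days = n_days,
      n_parameters = n_parameters(model, n_days),
      beta_at_bound = params$beta >= config$beta_bounds[2] - 1e-6,
      config = config, data = log
    ),
    class = "maze_fit"
  )
}

#' Fit both models to every set of a (possibly multi-animal) log
#'
#' Convenience wrapper: splits the log by animal (if an `animal` column
#' is present) and set, and fits each requested model per set.
#'
#' @param log Behavioral log, possibly with an `animal` column.
#' @param models Character vector among `"nrl"`, `"wam"`.
#' @param config A [fit_config()].
#' @return A tibble with columns `animal` (if present), `set_label`,
#'   `model` and a `fit` list-column of `maze_fit` objects.
#' @export
fit_experiment <- function(log, models = c("nrl", "wam"), config = fit_config()) {
  models <- vapply(models, match_model, character(1))
  groups <- if ("animal" %in% names(log)) {
    split(log, log$animal)
  } else {
    list(log)
  }
  res <- imap(groups, function(alog, animal_id) {
    sets <- split_sets(alog)
    combos <- tidyr::expand_grid(set_label = names(sets), model = models)
    combos$fit <- pmap(combos, function(set_label, model) {
      fit_set(sets[[set_label]], model, config)
    })
    if ("animal" %in% names(log)) {
      mutate(combos, animal = animal_id, .before = 1)
    } else {
      combos
    }
  })
  list_rbind(unname(res))
}

#' @export
print.maze_fit <- function(x, ...) {
  cat(sprintf("<maze_fit: %s on set %s, %d trials / %d day(s)>\n",
              toupper(x$model), x$set_label, x$n_trials, x$n_days))
  cat(sprintf("  logLik %.3f | beta %.3f%s | converged: %s\n",
              x$log_likelihood, x$params$beta,
              if (x$beta_at_bound) " (at bound)" else "", x$converged))
  invisible(x)
}

#' @export
logLik.maze_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            nobs = object$n_trials, class = "logLik")
}

#' Tidy a fitted set
#'
#' @param x A `maze_fit`.
#' @param ... Unused.
#' @return One row per day: `day`, `alpha`, the decision weights (WAM)
#'   and the day's log-likelihood.
#' @export
tidy.maze_fit <- function(x, ...) {
  out <- tibble(
    set_label = x$set_label, model = x$model,
    day = sort(unique(x$data$day)),
    alpha = x$params$alpha, log_likelihood = unname(x$per_day_ll)
  )
  if (x$model == "wam") out <- bind_cols(out, as_tibble(x$params$weights))
  out
}

#' One-row fit summary
#'
#' @param x A `maze_fit`.
#' @param ... Unused.
#' @export
glance.maze_fit <- function(x, ...) {
  tibble(
    set_label = x$set_label, model = x$model,
    log_likelihood = x$log_likelihood, beta = x$params$beta,
    n_trials = x$n_trials, n_days = x$n_days,
    n_parameters = x$n_parameters, beta_at_bound = x$beta_at_bound,
    converged = x$converged
  )
}
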