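#' Model parameters for one learning set
#'
#' Both models use one learning rate per day and one inverse temperature
#' per set.  The weighted attention model (WAM) additionally carries one
#' triple of decision weights per day, `(w_location, w_odor, w_led)`,
#' nonnegative and summing to 1.  The NRL therefore has N + 1 free
#' parameters over an N-day set and the WAM 3N + 1 (per day: the learning
#' rate and two free weight coordinates), a difference of 2 per day.
#'
#' @param alpha Per-day learning rates, each in `[0, 1]`.
#' @param beta Inverse temperature, in `[0, 30]`, shared across the days
#'   of the set.  `beta = 0` is random choice; large `beta` approaches the
#'   deterministic policy.
#' @param weights WAM decision weights: a matrix or data frame with one
#'   row per day and columns `(w_location, w_odor, w_led)`, or a single
#'   length-3 vector recycled across days.  `NULL` for the NRL.
#' @param decay Overnight value retention factor in `[0, 1]` applied to
#'   the carried-over values at each day boundary; `1` (default) carries
#'   values over unchanged.
#'
#' @return An object of class `set_params`.
#' @export
#' @examples
#' set_params(alpha = c(0.3, 0.3), beta = 5, weights = c(0.2, 0.6, 0.2))
set_params <- function(alpha, beta, weights = NULL, decay = 1) {
  alpha <- as.numeric(alpha)
  if (any(alpha < 0 | alpha > 1)) abort("`alpha` must lie in [0, 1].")
  beta <- as.numeric(beta)
  if (length(beta) != 1 || beta < 0 || beta > 30) {
    abort("`beta` must be a single value in [0, 30].")
  }
  if (length(decay) != 1 || decay < 0 || decay > 1) {
    abort("`decay` must be a single value in [0, 1].")
  }
  if (!is.null(weights)) {
    if (is.null(dim(weights))) {
      weights <- matrix(as.numeric(weights), nrow = length(alpha), ncol = 3,
                        byrow = TRUE)
    } else {
      weights <- as.matrix(weights)
      storage.mode(weights) <- "double"
    }
    if (nrow(weights) != length(alpha) || ncol(weights) != 3) {
      abort("`weights` must supply one (w_location, w_odor, w_led) row per day.")
    }
    check_simplex(weights)
    colnames(weights) <- c("w_location", "w_odor", "w_led")
  }
  structure(
    list(alpha = alpha, beta = beta, weights = weights, decay = decay),
    class = "set_params"
  )
}

check_simplex <- function(w, tol = 1e-9) {
  if (any(w < -tol)) abort("decision weights must be nonnegative")
  if (any(abs(rowSums(w) - 1) > 1e-6)) {
    abort("decision weights must sum to 1 on every day")
  }
  invisible(w)
}

n_days.set_params <- function(p) length(p$alpha)

#' Number of free parameters of a model over a set
#'
#' @param model `"nrl"` or `"wam"`.
#' @param n_days Number of days in the set.
#' @return Integer count: `n_days + 1` for the NRL (per-day learning rate
#'   plus the set-level inverse temperature), `3 * n_days + 1` for the WAM
#'   (learning rate and two free weight coordinates per day, plus the
#'   inverse temperature).
#' @export
n_parameters <- function(model = c("nrl", "wam"), n_days) {
  model <- match.arg(model)
  n_days <- as.integer(n_days)
  if (model == "nrl") n_days + 1L else 3L * n_days + 1L
}

#' @export
print.set_params <- function(x, ...) {
  kind <- if (is.null(x$weights)) "NRL" else "WAM"
  cat(sprintf("<set_params: %s, %d day(s), beta = %.3f, decay = %g>\n",
              kind, length(x$alpha), x$beta, x$decay))
  df <- tibble(day = seq_along(x$alpha), alpha = x$alpha)
  if (!is.null(x$weights)) df <- bind_cols(df, as_tibble(x$weights))
  print(df, ...)
  invisible(x)
}

# Coerce model argument.
match_model <- function(model) match.arg(model, c("nrl", "wam"))

params_match_model <- function(params, model) {
  if (!inherits(params, "set_params")) abort("`params` must be a set_params object.")
  if (model == "wam" && is.null(params$weights)) {
    abort("WAM replay needs decision weights in `params`.")
  }
  invisible(params)
}
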