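# Independent reference implementations used as oracles.  Written as
# naive, literal loops over the update and decision rules, deliberately
# sharing no code with the package internals.

# Step-by-step replay of a single-set log.  `weights` is an
# n_days x 3 matrix (w_location, w_odor, w_led) for the WAM, NULL for
# the NRL.  Returns per-trial index, p(choose a) and log-likelihood.
oracle_replay <- function(log, alpha, weights = NULL, beta, decay = 1) {
  wam <- !is.null(weights)
  V <- array(0, dim = c(4, 2, 2))            # NRL combination values
  l <- rep(0, 4); o <- rep(0, 2); cc <- rep(0, 2)  # WAM feature values
  days <- sort(unique(log$day))
  n <- nrow(log)
  index <- p_a <- ll <- numeric(n)
  prev_day <- days[1]
  for (t in seq_len(n)) {
    row <- log[t, ]
    if (row$day != prev_day) {
      V <- V * decay
      l <- l * decay; o <- o * decay; cc <- cc * decay
      prev_day <- row$day
    }
    d <- match(row$day, days)
    if (wam) {
      w <- weights[d, ]
      index[t] <- w[1] * (l[row$arm_a] - l[row$arm_b]) +
        w[2] * (o[row$odor_a] - o[row$odor_b]) +
        w[3] * (cc[row$led_a] - cc[row$led_b])
    } else {
      index[t] <- V[row$arm_a, row$odor_a, row$led_a] -
        V[row$arm_b, row$odor_b, row$led_b]
    }
    p_a[t] <- 1 / (1 + exp(-beta * index[t]))
    ll[t] <- log(if (row$chosen == "a") p_a[t] else 1 - p_a[t])
    # update the chosen option
    if (row$chosen == "a") {
      arm <- row$arm_a; od <- row$odor_a; led <- row$led_a
    } else {
      arm <- row$arm_b; od <- row$odor_b; led <- row$led_b
    }
    a <- alpha[d]
    if (wam) {
      l[arm] <- l[arm] + a * (row$reward - l[arm])
      o[od] <- o[od] + a * (row$reward - o[od])
      cc[led] <- cc[led] + a * (row$reward - cc[led])
    } else {
      V[arm, od, led] <- V[arm, od, led] + a * (row$reward - V[arm, od, led])
    }
  }
  list(index = index, p_a = p_a, ll = ll, total_ll = sum(ll))
}

# Brute-force grid maximization of the log-likelihood, one shared
# (alpha, weights) across days, plain nested loops.
oracle_grid_max <- function(log, alpha_grid, beta_grid, weight_grid = NULL,
                            decay = 1) {
  n_days <- length(unique(log$day))
  best <- list(ll = -Inf)
  w_rows <- if (is.null(weight_grid)) list(NULL) else {
    lapply(seq_len(nrow(weight_grid)), function(i) weight_grid[i, ])
  }
  for (a in alpha_grid) {
    for (w in w_rows) {
      wm <- if (is.null(w)) NULL else matrix(w, n_days, 3, byrow = TRUE)
      for (b in beta_grid) {
        ll <- oracle_replay(log, rep(a, n_days), wm, b, decay)$total_ll
        if (ll > best$ll) best <- list(ll = ll, alpha = a, beta = b, w = w)
      }
    }
  }
  best
}

# A tiny fixed hand-built single-day log on set ODOR1 (odor 1 rewarded).
hand_log <- function() {
  tibble::tribble(
    ~arm_a, ~odor_a, ~led_a, ~arm_b, ~odor_b, ~led_b, ~chosen, ~reward,
    1L, 1L, 1L, 2L, 2L, 2L, "a", 1L,
    1L, 2L, 1L, 3L, 1L, 2L, "a", 0L,
    2L, 1L, 2L, 1L, 2L, 1L, "a", 1L,
    3L, 2L, 2L, 2L, 1L, 1L, "b", 1L,
    4L, 1L, 1L, 1L, 2L, 2L, "b", 0L
  ) |>
    dplyr::mutate(group = "odor_first", set_label = "ODOR1", day = 1L,
                  trial = dplyr::row_number(), .before = 1) |>
    dplyr::select(dplyr::all_of(wamaze:::log_columns))
}

# Default small simulation shared by several tests.
sim_one_set <- function(model = "wam", seed = 1, n_days = 2,
                        trials_per_day = 60, alpha = 0.3, beta = 5,
                        weights = c(0.2, 0.6, 0.2), set = "ODOR1") {
  prot <- maze_protocol("odor_first", n_days = c(n_days, 1, 1),
                        trials_per_day = trials_per_day)
  pars <- list(
    ODOR1 = set_params(rep(alpha, n_days), beta,
                       if (model == "wam") weights),
    ODOR2 = set_params(alpha, beta, if (model == "wam") weights),
    LED = set_params(alpha, beta, if (model == "wam") weights)
  )
  log <- simulate_agent(prot, model, pars, seed = seed)
  dplyr::filter(log, set_label == set)
}
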