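#' Initial value states
#'
#' The NRL learns one value per feature *combination* -- 4 arms x 2 odors
#' x 2 LED colors = 16 entries -- while the WAM learns one value per
#' feature: 4 locations, 2 odors, 2 LED colors.  Both start from all
#' zeros at the beginning of every learning set, so every value stays in
#' `[0, 1]` under the delta-rule update with binary reward.
#'
#' @return A named numeric vector: 16 entries `V<arm>.<odor>.<led>` for
#'   [nrl_values()], 8 entries `l1..l4, o1, o2, c1, c2` for [wam_values()].
#' @export
nrl_values <- function() {
  grid <- expand.grid(led = 1:2, odor = 1:2, arm = 1:4)
  setNames(numeric(16),
           paste0("V", grid$arm, ".", grid$odor, ".", grid$led))
}

#' @rdname nrl_values
#' @export
wam_values <- function() {
  setNames(numeric(8), c("l1", "l2", "l3", "l4", "o1", "o2", "c1", "c2"))
}

chosen_features <- function(chosen) {
  chosen <- as.list(chosen)
  stopifnot(all(c("arm", "odor", "led") %in% names(chosen)))
  arm <- as.integer(chosen$arm); odor <- as.integer(chosen$odor)
  led <- as.integer(chosen$led)
  stopifnot(arm %in% 1:4, odor %in% 1:2, led %in% 1:2)
  list(arm = arm, odor = odor, led = led)
}

#' Delta-rule value updates
#'
#' Rescorla-Wagner update `x <- x + alpha * (R - x)` applied after
#' feedback to the chosen option only.  The NRL updates the single
#' chosen combination entry; the WAM updates the three chosen feature
#' entries (its arm, its odor, its LED color).  Unchosen entries are
#' never touched.
#'
#' @param values State vector from [nrl_values()] / [wam_values()] (or a
#'   previous update).
#' @param chosen The chosen option, a list or named vector with `arm`,
#'   `odor`, `led`.
#' @param reward 0 or 1.
#' @param alpha Learning rate in `[0, 1]`.
#' @return The updated state vector.
#' @export
#' @examples
#' v <- nrl_update(nrl_values(), list(arm = 1, odor = 1, led = 1), 1, 0.3)
#' v[["V1.1.1"]]  # 0.3
nrl_update <- function(values, chosen, reward, alpha) {
  check_update_args(reward, alpha)
  ch <- chosen_features(chosen)
  key <- paste0("V", ch$arm, ".", ch$odor, ".", ch$led)
  values[key] <- values[key] + alpha * (reward - values[key])
  values
}

#' @rdname nrl_update
#' @export
wam_update <- function(values, chosen, reward, alpha) {
  check_update_args(reward, alpha)
  ch <- chosen_features(chosen)
  keys <- c(paste0("l", ch$arm), paste0("o", ch$odor), paste0("c", ch$led))
  values[keys] <- values[keys] + alpha * (reward - values[keys])
  values
}

check_update_args <- function(reward, alpha) {
  if (!reward %in% c(0, 1)) abort("`reward` must be 0 or 1.")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1].")
}

#' Decision indices
#'
#' The decision index of an offered pair is the value difference between
#' option a and option b.  For the NRL it is the difference of the two
#' combination values; for the WAM it is the weighted sum of per-dimension
#' value differences,
#' `w_l (l_i - l_i') + w_o (o_j - o_j') + w_c (c_k - c_k')`.
#' Its sign is the deterministic choice prediction (positive: a; negative:
#' b; zero: tie).
#'
#' @param values State vector ([nrl_values()] / [wam_values()] layout).
#' @param pair One offered pair: a list, one-row data frame or named
#'   vector with `arm_a, odor_a, led_a, arm_b, odor_b, led_b`.
#' @param weights Length-3 weight vector `(w_location, w_odor, w_led)` on
#'   the simplex (WAM only).
#' @return The scalar decision index.
#' @export
nrl_decision_index <- function(values, pair) {
  p <- as.list(pair)
  ka <- paste0("V", p$arm_a, ".", p$odor_a, ".", p$led_a)
  kb <- paste0("V", p$arm_b, ".", p$odor_b, ".", p$led_b)
  unname(values[ka] - values[kb])
}

#' @rdname nrl_decision_index
#' @export
wam_decision_index <- function(values, weights, pair) {
  check_simplex(matrix(as.numeric(weights), 1))
  p <- as.list(pair)
  dl <- values[paste0("l", p$arm_a)] - values[paste0("l", p$arm_b)]
  dod <- values[paste0("o", p$odor_a)] - values[paste0("o", p$odor_b)]
  dc <- values[paste0("c", p$led_a)] - values[paste0("c", p$led_b)]
  unname(weights[1] * dl + weights[2] * dod + weights[3] * dc)
}

#' Softmax choice probability
#'
#' Probability of choosing option a given a decision index, the logistic
#' `1 / (1 + exp(-beta * index))`.  Computed in a numerically stable form;
#' exact complement symmetry `p(index) + p(-index) = 1` holds.
#'
#' @param index Decision index (any real, vectorized).
#' @param beta Inverse temperature, `>= 0`.
#' @return Probability in `[0, 1]`.
#' @export
choice_probability <- function(index, beta) {
  if (length(beta) != 1 || beta < 0) abort("`beta` must be a single value >= 0.")
  plogis(beta * index)
}
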