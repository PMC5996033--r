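make_rates <- function(rates, set = "ODOR1") {
  tibble::tibble(set_label = set, day = seq_along(rates),
                 n_trials = 50L, success_rate = rates)
}

test_that("daily success rate is the rewarded fraction per day", {
  log <- hand_log()[1:4, ]
  log$reward <- c(1L, 0L, 1L, 1L)
  expect_equal(daily_success_rate(log)$success_rate, 0.75)

  full <- sim_one_set("wam", seed = 6, n_days = 2, trials_per_day = 30)
  rates <- daily_success_rate(full)
  expect_equal(rates$success_rate,
               tapply(full$reward, full$day, mean), ignore_attr = TRUE)
  all_win <- dplyr::mutate(hand_log(), reward = 1L)
  expect_equal(daily_success_rate(all_win)$success_rate, 1)
  expect_error(daily_success_rate(hand_log()[0, ]), "empty")

  # a beta = 0 agent hovers at chance
  rnd <- sim_one_set("wam", seed = 19, n_days = 1, trials_per_day = 1000,
                     beta = 0, weights = c(1, 1, 1) / 3)
  expect_lt(abs(daily_success_rate(rnd)$success_rate - 0.5), 0.05)
})

test_that("criterion day is the first day at or above threshold", {
  expect_equal(criterion_day(make_rates(c(0.5, 0.6, 0.8)))$criterion_day, 3L)
  expect_true(is.na(criterion_day(make_rates(rep(0.5, 4)))$criterion_day))
  # the boundary qualifies (>=)
  expect_equal(criterion_day(make_rates(c(0.5, 0.75)))$criterion_day, 2L)
  # grouped by animal and set
  rates <- dplyr::bind_rows(
    dplyr::mutate(make_rates(c(0.4, 0.8)), animal = "r1"),
    dplyr::mutate(make_rates(c(0.9, 0.2)), animal = "r2")
  )
  cd <- criterion_day(rates)
  expect_equal(cd$criterion_day[match(c("r1", "r2"), cd$animal)], c(2L, 1L))
})

test_that("stage split is a permanent crossing at 70%", {
  s <- stage_split(make_rates(c(0.5, 0.72, 0.6)))
  expect_identical(s$stage, c("early", "late", "late"))
  expect_false(any(s$never_crossed))
  # late from day 1 when the first day already qualifies
  s1 <- stage_split(make_rates(c(0.9, 0.5)))
  expect_identical(s1$stage, c("late", "late"))
  # never crossed: all early, flagged
  s2 <- stage_split(make_rates(c(0.5, 0.6)))
  expect_identical(s2$stage, c("early", "early"))
  expect_true(all(s2$never_crossed))
  # idempotent and stable under appending post-crossing days
  r3 <- make_rates(c(0.5, 0.72, 0.6, 0.4))
  s3 <- stage_split(r3)
  expect_identical(s3$stage[1:3], s$stage)
  expect_identical(stage_split(s3)$stage, s3$stage)
  # within a set, all early days precede all late days
  expect_true(all(diff(match(s3$stage, c("early", "late"))) >= 0))
})

test_that("choice matrices conserve trials and put rewards on the diagonal", {
  log <- sim_one_set("wam", seed = 13, n_days = 2, trials_per_day = 50)
  cm <- choice_matrix(log)
  expect_equal(sum(cm$n), nrow(log))
  diag_total <- sum(cm$n[cm$correct_arm == cm$chosen_arm])
  expect_equal(diag_total, sum(log$reward))
  m <- choice_matrix_wide(dplyr::filter(cm, day == 1))
  expect_equal(sum(m), sum(log$day == 1))
  # row sums = number of trials on which each arm was correct
  corr <- correct_choice(dplyr::filter(log, day == 1), "odor", 1L)
  corr_arm <- ifelse(corr == "a",
                     dplyr::filter(log, day == 1)$arm_a,
                     dplyr::filter(log, day == 1)$arm_b)
  expect_equal(unname(rowSums(m)), unname(table(factor(corr_arm, 1:4))),
               ignore_attr = TRUE)

  # a perfect performer is purely diagonal
  perfect <- dplyr::mutate(log, chosen = corr_all <- correct_choice(log, "odor", 1L),
                           reward = 1L)
  cm_p <- choice_matrix(perfect)
  expect_equal(sum(cm_p$n[cm_p$correct_arm != cm_p$chosen_arm]), 0)
})

test_that("a location-driven agent leaves a detectable spatial bias", {
  log <- sim_one_set("wam", seed = 23, n_days = 2, trials_per_day = 100,
                     alpha = 0.5, beta = 30, weights = c(1, 0, 0))
  cm <- choice_matrix(log)
  col_totals <- tapply(cm$n, cm$chosen_arm, sum)
  # an unbiased chooser picks each arm in ~1/4 of trials; the location
  # learner's arm preferences deviate far beyond sampling noise
  expect_lt(stats::chisq.test(col_totals, p = rep(0.25, 4))$p.value, 1e-3)
})

test_that("weight aggregation averages the simplex linearly", {
  w <- tibble::tibble(
    animal = rep(c("r1", "r2"), each = 6),
    set_label = "ODOR1",
    day = rep(rep(1:2, each = 3), 2),
    dimension = factor(rep(c("location", "odor", "led"), 4),
                       c("location", "odor", "led")),
    weight = c(0.2, 0.4, 0.4, 0.2, 0.4, 0.4,
               0.2, 0.6, 0.2, 0.2, 0.4, 0.4)
  )
  agg <- aggregate_weights(w)
  expect_equal(nrow(agg), 6L)
  o1 <- dplyr::filter(agg, day == 1, dimension == "odor")
  expect_equal(o1$mean_weight, 0.5)
  expect_equal(o1$sem, 0.1)
  # identical weights across animals: SEM 0
  d2 <- dplyr::filter(agg, day == 2)
  expect_equal(d2$sem, rep(0, 3))
  # the three dimension means per cell sum to 1
  sums <- agg |> dplyr::group_by(day) |>
    dplyr::summarise(s = sum(mean_weight))
  expect_equal(sums$s, c(1, 1))

  # single-animal cells are flagged, and cells seen by fewer than half
  # of the animals can be dropped
  w3 <- dplyr::bind_rows(w, tibble::tibble(
    animal = "r3", set_label = "ODOR1", day = 3,
    dimension = factor(c("location", "odor", "led"),
                       c("location", "odor", "led")),
    weight = c(0.1, 0.8, 0.1)
  ))
  agg_all <- aggregate_weights(w3, drop_below_half = FALSE)
  expect_true(all(agg_all$single_animal[agg_all$day == 3]))
  expect_true(all(is.na(agg_all$sem[agg_all$day == 3])))
  expect_false(3 %in% aggregate_weights(w3)$day)
})

test_that("stage weight tables join stages onto per-day weights", {
  rates <- dplyr::bind_rows(
    dplyr::mutate(make_rates(c(0.5, 0.8)), animal = "r1"),
    dplyr::mutate(make_rates(c(0.6, 0.9)), animal = "r2")
  )
  stages <- stage_split(rates)
  w <- tidyr::expand_grid(
    animal = c("r1", "r2"), set_label = "ODOR1", day = 1:2,
    dimension = factor(c("location", "odor", "led"),
                       c("location", "odor", "led"))
  ) |>
    dplyr::mutate(weight = ifelse(dimension == "odor", 0.6, 0.2))
  tab <- stage_weight_table(w, stages)
  expect_identical(sort(unique(tab$stage)), c("early", "late"))
  expect_equal(nrow(tab), 2 * 2 * 3)  # animal x stage x dimension
  expect_equal(tab$mean_weight[tab$dimension == "odor"], rep(0.6, 4))
})

test_that("a small fitted cohort recovers an odor-dominant attention profile", {
  prot <- maze_protocol("odor_first", n_days = c(2, 2, 1),
                        trials_per_day = 50)
  pars <- list(ODOR1 = set_params(rep(0.4, 2), 8, c(0.15, 0.7, 0.15)),
               ODOR2 = set_params(rep(0.4, 2), 8, c(0.15, 0.7, 0.15)),
               LED = set_params(0.4, 8, c(0.15, 0.7, 0.15)))
  cohort <- simulate_cohort(prot, "wam", pars, n_animals = 4, seed = 300)
  fits <- fit_experiment(dplyr::filter(cohort, set_label == "ODOR2"),
                         models = "wam")
  weights <- cohort_weights(fits)
  agg <- aggregate_weights(weights)
  mw <- tapply(agg$mean_weight, agg$dimension, mean)
  expect_gt(mw[["odor"]], mw[["led"]])
  expect_gt(mw[["odor"]], mw[["location"]])
})
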