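test_that("stage categories follow the T/N boundaries with ties to the lower stage", {
  expect_equal(stage_category(15, "T"), 1L)
  expect_equal(stage_category(c(20, 20.1, 50, 50.1), "T"), c(1L, 2L, 2L, 3L))
  expect_equal(stage_category(0, "N"), 0L)
  expect_equal(stage_category(c(1, 3, 4, 5, 9, 10), "N"),
               c(1L, 1L, 2L, 2L, 2L, 3L))
  expect_error(stage_category(-1, "T"), "nonnegative")
})

test_that("case classification applies the documented precedence", {
  rec <- make_records(
    mode = c("screen", "screen", "screen", "screen", "symptomatic", "none"),
    screen_age = 60, screen_diameter = c(15, 15, 15, 22, NA, NA),
    screen_nodes = c(0L, 2L, 0L, 1L, NA, NA),
    sympt_age = c(62, 63, 63, 63, 70, Inf),
    sympt_diameter = c(25, 25, 25, 25, 30, NA),
    sympt_nodes = c(0L, 5L, 0L, 2L, 1L, NA),
    ocd_age = c(61, 90, 90, 90, 90, 55))
  got <- classify_case(rec)
  expect_equal(as.character(got[1:5]),
               c("overdiagnosed",  # dies of other causes before sympt age
                 "n_shifted",      # N 1 -> 2 shift wins over the T shift
                 "t_shifted",      # T 1 vs 2, no N shift
                 "other_screen",   # same T and N categories
                 "symptomatic"))
  expect_true(is.na(got[6]))
})

test_that("lead time and survival difference are screen-only quantities", {
  rec <- make_records(mode = c("screen", "symptomatic"),
                      screen_age = c(60, NA), sympt_age = c(62.5, 70),
                      screen_death_age = c(80, NA),
                      sympt_death_age = c(76, 85))
  expect_equal(lead_time(rec), c(2.5, NA))
  expect_equal(survival_difference(rec), c(4, 0))
})

test_that("programme tallies conserve cases across categories", {
  out <- simulate_cohort(toy_params(), synthetic_life_table(),
                         list(none = programme_none(),
                              cur = programme_current()),
                         n = 20000, seed = 6)
  tn <- tally_programme(out$none)
  expect_equal(tn$overdiagnosed + tn$n_shifted + tn$t_shifted +
                 tn$other_screen, 0)
  expect_equal(tn$symptomatic, tn$total_cases)
  expect_equal(tn$avg_lead_time, 0)
  tc <- tally_programme(out$cur)
  expect_equal(tc$symptomatic + tc$overdiagnosed + tc$n_shifted +
                 tc$t_shifted + tc$other_screen, tc$total_cases)
  expect_equal(tc$overdiagnosed + tc$n_shifted + tc$t_shifted +
                 tc$other_screen, tc$screen_detected)
  expect_true(all(lead_time(out$cur)[out$cur$mode == "screen"] >= 0))
})

test_that("per-round breakdown conserves screen detections and attributes intervals", {
  prog <- programme_current()
  rec <- simulate_cohort(toy_params(), synthetic_life_table(), prog,
                         n = 20000, seed = 7)
  br <- per_round_breakdown(rec, prog)
  expect_equal(sum(br$screen_detected), sum(rec$mode == "screen"))
  expect_equal(br$screen_detected,
               br$overdiagnosed + br$n_shifted + br$t_shifted + br$other_screen)
  expect_true(all(br$mammograms >= br$screen_detected))
  expect_lte(sum(br$interval_cancers), sum(rec$mode == "symptomatic"))
  # interval cancers arise only after an attended screen
  expect_true(all(br$interval_cancers[br$mammograms == 0] == 0))
})

test_that("life-expectancy metrics do the per-round arithmetic", {
  prog <- screening_programme(c(60, 62), "two rounds")
  rec <- make_records(mode = c(rep("screen", 2), rep("none", 998)),
                      screen_age = c(60, 60, rep(NA, 998)),
                      screen_round = c(1L, 1L, rep(NA, 998)),
                      screen_diameter = 10, screen_nodes = 0L,
                      sympt_age = c(65, 65, rep(Inf, 998)),
                      sympt_death_age = c(80, 81, rep(NA, 998)),
                      screen_death_age = c(81, 83, rep(NA, 998)),
                      death_age = 90, ocd_age = 90, mammograms = 1L)
  # round 1: two detections with survival differences 1 and 2 years;
  # exactly 1000 mammograms at round 1 (998 attend + 2 detections)
  lem <- life_expectancy_metrics(rec, prog)
  expect_equal(lem$per_round$mammograms[1], 1000)
  expect_equal(lem$per_round$days_per_mammogram[1], 365.25 * 3 / 1000)
  # 3.65 days per mammogram corresponds to ~100 mammograms per life year
  expect_equal(365.25 / lem$per_round$days_per_mammogram[1],
               lem$per_round$mammograms_per_life_year[1])
  expect_equal(lem$total_days_per_woman, 365.25 * 3 / 1000)
})

test_that("programme comparison reports percent changes", {
  t1 <- structure(list(per = 1e6, bc_deaths = 41182, mammograms_k = 0,
                       total_cases = 151376, symptomatic = 151376,
                       overdiagnosed = 0, n_shifted = 0, t_shifted = 0,
                       other_screen = 0, screen_detected = 0,
                       avg_lead_time = 0, avg_surv_diff = 0),
                  class = "programme_tally")
  t2 <- t1; t2$bc_deaths <- 33550
  cmp <- compare_programmes(t1, t2)
  expect_equal(cmp$change_pct[cmp$metric == "bc_deaths"], -18.53,
               tolerance = 1e-3)
  expect_true(all(compare_programmes(t1, t1)$change_pct %in% c(0, NA)))
})

test_that("parameter vectors propagate the supplied covariance", {
  theta <- c(a = 1, b = 2, c = 0.5)
  d0 <- sample_parameter_vectors(theta, diag(0, 3), 5)
  expect_true(all(d0 == matrix(rep(c(1, 2, 0.5), each = 5), 5, 3)))
  set.seed(9)
  Sigma <- matrix(c(0.04, 0.01, 0, 0.01, 0.09, 0, 0, 0, 0.01), 3, 3)
  draws <- sample_parameter_vectors(theta, Sigma, 1e4)
  expect_lt(norm(cov(draws) - Sigma, "F") / norm(Sigma, "F"), 0.05)
  expect_true(all(draws > 0))
  expect_error(sample_parameter_vectors(theta, matrix(c(1, 2, 2, 1), 2, 2)[c(1, 2, 1), c(1, 2, 1)], 5))
  bad <- diag(c(1, 1, 1)); bad[1, 2] <- bad[2, 1] <- 2
  expect_error(sample_parameter_vectors(theta, bad, 5), "semi-definite")
})

test_that("run-level confidence intervals are percentile intervals", {
  expect_equal(ci_from_runs(rep(3, 10)), c(lo = 3, hi = 3))
  set.seed(10)
  ci <- ci_from_runs(runif(1e4))
  expect_equal(unname(ci), c(0.05, 0.95), tolerance = 0.01)
  expect_error(ci_from_runs(1), "at least two")
})
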