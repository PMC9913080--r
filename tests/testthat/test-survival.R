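test_that("post-diagnosis survival starts at 1, decreases, and orders by stage", {
  sp <- default_nh_params()$survival
  expect_equal(bc_survival_fn(0, 15, 0, sp), 1)
  tt <- seq(0, 30, 0.5)
  S <- bc_survival_fn(tt, 25, 2, sp)
  expect_true(all(diff(S) < 0))
  # small node-negative tumours have better survival at every horizon
  expect_true(all(bc_survival_fn(tt[-1], 15, 0, sp) >
                    bc_survival_fn(tt[-1], 60, 5, sp)))
  expect_error(bc_survival_fn(-1, 15, 0, sp), "nonnegative")
})

test_that("Kaplan-Meier of sampled survival reproduces the model curve", {
  skip_if_not_installed("survival")
  sp <- default_nh_params()$survival
  d <- 25; nod <- 2
  set.seed(8)
  draws <- sample_bc_survival(rep(d, 1e5), rep(nod, 1e5), sp)
  cens <- 50
  km <- survival::survfit(
    survival::Surv(pmin(draws, cens), draws <= cens) ~ 1)
  grid <- seq(1, 40, by = 1)
  S_km <- summary(km, times = grid)$surv
  S_mod <- bc_survival_fn(grid, d, nod, sp)
  expect_lt(max(abs(S_km - S_mod)), 0.01)
})

test_that("cured fraction never dies of breast cancer and couples monotonically", {
  sp <- default_nh_params()$survival
  cure <- plogis(sp$cure_intercept + sp$cure_size * 15 + sp$cure_slope_nodes * 0)
  expect_identical(sample_bc_survival(15, 0, sp, u = cure / 2), Inf)
  t1 <- sample_bc_survival(15, 0, sp, u = 0.99)
  t2 <- sample_bc_survival(15, 0, sp, u = 0.999)
  expect_lt(t2, t1)  # larger uniform = earlier death under inverse-survival draws
  # shared uniform gives a better outcome for the better stage
  u <- 0.995
  expect_gt(sample_bc_survival(10, 0, sp, u = u),
            sample_bc_survival(60, 8, sp, u = u))
})

test_that("outcome resolution matches the hand-enumerated ordering truth table", {
  # all six orderings of screen age (s), symptomatic age (y), other-cause
  # death (o); breast-cancer survival draws of 4 years from detection
  cases <- list(
    #    s    y    o    expected mode, death age, cause
    list(c(60, 62, 70), "screen",      64, "breast cancer"),
    list(c(60, 70, 62), "screen",      62, "other"),        # s<o<y: overdiagnosis-type
    list(c(62, 60, 70), "symptomatic", 64, "breast cancer"),# y first (s>y impossible live, still resolved)
    list(c(70, 60, 62), "symptomatic", 62, "other"),
    list(c(62, 70, 60), "none",        60, "other"),
    list(c(70, 62, 60), "none",        60, "other"))
  for (cs in cases) {
    v <- cs[[1]]
    out <- resolve_outcome(sympt_age = v[2], screen_age = v[1],
                           bc_surv_sympt = 4, bc_surv_screen = 4,
                           other_cause_age = v[3])
    expect_equal(out$mode, cs[[2]])
    expect_equal(out$death_age, cs[[3]])
    expect_equal(out$death_cause, cs[[4]])
  }
})

test_that("resolution stores both counterfactual all-cause death ages", {
  out <- resolve_outcome(sympt_age = 62, screen_age = 60, bc_surv_sympt = 10,
                         bc_surv_screen = 25, other_cause_age = 80)
  expect_equal(out$sympt_death_age, 72)   # 62 + 10 < 80
  expect_equal(out$screen_death_age, 80)  # cured past other-cause death
  # no screen detection -> screen counterfactual undefined
  out2 <- resolve_outcome(62, Inf, 10, Inf, 80)
  expect_true(is.na(out2$screen_death_age))
  expect_equal(out2$mode, "symptomatic")
  # death ages truncate at the terminal age
  out3 <- resolve_outcome(100, Inf, Inf, Inf, 200, terminal_age = 111)
  expect_equal(out3$death_age, 111)
})
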