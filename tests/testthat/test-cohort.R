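test_that("cohort simulation is deterministic given the seed", {
  p <- toy_params(); lt <- synthetic_life_table()
  a <- simulate_cohort(p, lt, programme_current(), n = 3000, seed = 99)
  b <- simulate_cohort(p, lt, programme_current(), n = 3000, seed = 99)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c_ <- simulate_cohort(p, lt, programme_current(), n = 3000, seed = 100)
  expect_false(identical(a$onset_age, c_$onset_age))
})

test_that("no screening means no mammograms and no screen detections", {
  rec <- simulate_cohort(toy_params(), synthetic_life_table(),
                         programme_none(), n = 5000, seed = 1)
  expect_equal(count_mammograms(rec), 0)
  expect_false(any(rec$mode == "screen"))
  expect_true(all(is.infinite(rec$screen_age)))
})

test_that("mammogram counting includes the detection round and stops at exit", {
  p <- toy_params()
  p$sensitivity <- sensitivity_params(intercept = 40, slope = 1)  # certain detection
  rec <- simulate_cohort(p, synthetic_life_table(), programme_current(),
                         n = 5000, seed = 2)
  sc <- rec$mode == "screen"
  expect_true(any(sc))
  expect_equal(rec$mammograms[sc], rec$screen_round[sc])
  # women with no breast cancer attend every round before death
  ages <- programme_current()$ages
  no_bc <- rec$mode == "none"
  expect_equal(rec$mammograms[no_bc],
               vapply(rec$death_age[no_bc],
                      function(d) sum(ages < d), numeric(1)))
  # nobody is examined after symptomatic diagnosis
  sym <- rec$mode == "symptomatic"
  expect_true(all(rec$mammograms[sym] <=
                    findInterval(rec$sympt_age[sym], ages)))
})

test_that("records are internally consistent", {
  rec <- simulate_cohort(default_nh_params(), synthetic_life_table(),
                         programme_current(), n = 20000, seed = 3)
  expect_true(all(rec$death_age <= 111))
  expect_true(all(rec$mode %in% c("screen", "symptomatic", "none")))
  sc <- rec$mode == "screen"
  expect_true(all(rec$screen_age[sc] < rec$sympt_age[sc]))
  expect_true(all(rec$screen_diameter[sc] >= 0.5))
  expect_true(all(rec$sympt_diameter[rec$mode != "none"] >= 0.5))
  # realised death age equals the minimum of the candidate ages
  expect_true(all(rec$death_age[sc] == pmin(rec$screen_death_age[sc], 111)))
  sym <- rec$mode == "symptomatic"
  expect_true(all(rec$death_age[sym] == pmin(rec$sympt_death_age[sym], 111)))
})

test_that("programmes simulated together share latent histories", {
  out <- simulate_cohort(toy_params(), synthetic_life_table(),
                         list(none = programme_none(),
                              cur = programme_current(),
                              ext = programme_extended()),
                         n = 10000, seed = 4)
  expect_identical(out$none$onset_age, out$cur$onset_age)
  expect_identical(out$cur$sympt_age, out$ext$sympt_age)
  expect_identical(out$cur$ocd_age, out$ext$ocd_age)
  # with common random numbers, extending a programme never delays detection
  expect_true(all(out$ext$screen_age <= out$cur$screen_age))
})

test_that("with screening disabled the realised outcome equals the symptomatic counterfactual", {
  rec <- simulate_cohort(toy_params(), synthetic_life_table(),
                         programme_none(), n = 5000, seed = 5)
  cases <- rec$mode != "none"
  expect_equal(rec$death_age[cases], rec$sympt_death_age[cases])
})
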