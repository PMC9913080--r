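test_that("sphere size conversion is exact and round-trips", {
  expect_equal(size_convert(0.5, "diameter"), pi / 6 * 0.125)
  expect_equal(size_convert(pi / 6, "volume"), 1)
  expect_equal(size_convert(size_convert(20, "diameter"), "volume"), 20)
  expect_error(size_convert(0, "diameter"), "positive")
  expect_error(size_convert(-3, "volume"), "positive")
})

test_that("exponential growth has the right doubling behaviour", {
  g <- default_nh_params()$growth
  r <- 1.7
  expect_equal(volume_at(0, r, g), g$v0)
  expect_equal(volume_at(r * log(2), r, g), 2 * g$v0)
  # diameter doubles (volume x8) after three volume doublings
  expect_equal(size_convert(volume_at(3 * r * log(2), r, g), "volume"),
               2 * size_convert(volume_at(0, r, g), "volume"))
  expect_error(volume_at(-0.1, r, g), "nonnegative")
})

test_that("closed-form symptomatic cumulative hazard agrees with quadrature", {
  g <- default_nh_params()$growth
  for (r in c(0.3, 1, 4)) {
    expect_identical(sympt_cum_hazard(0, r, g), 0)
    tt <- seq(0.5, 12, by = 0.5)
    expect_true(all(diff(sympt_cum_hazard(tt, r, g)) > 0))
    for (t in c(1, 5, 10)) {
      quad <- integrate(function(u) g$eta * volume_at(u, r, g), 0, t,
                        rel.tol = 1e-12)$value
      lam <- sympt_cum_hazard(t, r, g)
      expect_lt(abs(lam - quad) / lam, 1e-8)
    }
  }
})

test_that("inverse growth rates reproduce the gamma moments", {
  g <- default_nh_params()$growth
  set.seed(7)
  r <- sample_inv_growth_rate(1e6, g)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - g$shape / g$rate) / (g$shape / g$rate), 0.01)
  expect_lt(abs(var(r) - g$shape / g$rate^2) / (g$shape / g$rate^2), 0.03)
})

test_that("symptomatic-interval sampling inverts its cumulative hazard", {
  g <- default_nh_params()$growth
  expect_identical(sample_sympt_interval(2, g, E = 0), 0)
  set.seed(11)
  r <- sample_inv_growth_rate(1000, g)
  E <- rexp(1000)
  t <- sample_sympt_interval(r, g, E = E)
  expect_lt(max(abs(sympt_cum_hazard(t, r, g) - E)), 1e-10)
})

test_that("symptomatic volumes match a grid-hazard simulation oracle", {
  g <- default_nh_params()$growth
  n <- 1e5
  set.seed(19)
  r <- sample_inv_growth_rate(n, g)
  vols <- volume_at(sample_sympt_interval(r, g), r, g)
  # oracle: discretise the hazard on a fine time grid (right Riemann sum
  # of eta*V over steps dt) and invert the resulting step CDF; the
  # partial sums are geometric, so the first grid index with H_k >= E is
  # k = ceil((r/dt) log(1 + E (e^{dt/r}-1)/(eta v0 dt e^{dt/r})))
  set.seed(20)
  r2 <- sample_inv_growth_rate(n, g)
  dt <- 0.005
  E2 <- rexp(n)
  a <- exp(dt / r2)
  k <- ceiling((r2 / dt) * log1p(E2 * (a - 1) / (g$eta * g$v0 * dt * a)))
  vols2 <- volume_at(k * dt, r2, g)
  D <- suppressWarnings(ks.test(vols, vols2)$statistic)
  expect_lt(unname(D), 0.01)
})
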