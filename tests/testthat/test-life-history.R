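test_that("thermal increments subtract the base and halt above T_max", {
  expect_equal(thermal_increment(26, 12, 35), 14)
  expect_equal(thermal_increment(10, 12, 35), 0)
  expect_equal(thermal_increment(36, 12, 35), 0)
  expect_equal(thermal_increment(c(10, 26, 36), 12, 35), c(0, 14, 0))
})

test_that("threshold draws have the stated moments and stay positive", {
  expect_equal(draw_threshold(30, 0), 720)
  set.seed(42)
  x <- draw_threshold(30, 0.05, n = 1e5)
  se_mean <- 36 / sqrt(1e5)
  expect_lt(abs(mean(x) - 720), 3 * se_mean)
  expect_lt(abs(sd(x) - 36) / 36, 0.05)
  expect_true(all(x > 0))
  # heavy-variation draws are truncated positive, never zero or below
  set.seed(43)
  expect_true(all(draw_threshold(1, 2, n = 1e4) > 0))
})

test_that("transitions trigger at the inclusive threshold boundary", {
  expect_false(transition_due(719.9, 720))
  expect_true(transition_due(720, 720))
  # constant 26 C accumulation: first hour with cumulative >= 720 is 52
  acc <- cumsum(rep(thermal_increment(26, 12, 35), 60))
  expect_identical(which(acc >= 720)[1], 52L)
})

test_that("hourly transition probability reproduces expected development rate", {
  expect_equal(hourly_transition_probability(10, 12, 35, 30), 0)
  expect_equal(hourly_transition_probability(26, 12, 35, 30), 14 / 720)
  # mean geometric waiting time 1/p matches the deterministic mode in expectation
  p <- hourly_transition_probability(26, 12, 35, 30)
  expect_equal(1 / p, 720 / 14, tolerance = 1e-12)
})

test_that("mortality quadratics evaluate to the printed coefficients", {
  expect_equal(mu_temperature("adult_mature", 25),
               0.00049 * 625 - 0.0187 * 25 + 0.1846, tolerance = 1e-12)
  expect_equal(mu_temperature("adult_mature", 25), 0.02335, tolerance = 1e-10)
  # eggs and larvae share a curve, symmetric about its vertex at 18.125 C
  expect_equal(mu_temperature("egg", 18.125 + 5), mu_temperature("larva", 18.125 - 5),
               tolerance = 1e-12)
  # pupal curve dips marginally below zero at its vertex (T = 20.7): the raw
  # quadratic evaluates to -4.5e-5 and the returned value clamps to zero
  co <- mortality_quadratics()["p", ]
  raw <- co[["a2"]] * 20.7^2 + co[["a1"]] * 20.7 + co[["a0"]]
  expect_equal(raw, -4.5e-5, tolerance = 1e-9)
  expect_identical(mu_temperature("pupa", 20.7), 0)
  expect_true(all(mu_temperature("pupa", seq(0, 40, 0.1)) >=
                    mu_temperature("pupa", 20.7)))
})

test_that("daily natural mortality composes additively and saturates", {
  expect_equal(daily_natural_mortality("egg", 10, 0), mu_temperature("egg", 10))
  # near the vertex the quadratic contributes almost nothing
  expect_equal(daily_natural_mortality("egg", 18.125, 0.05), 0.05, tolerance = 1e-4)
  # cold-snap mechanism: adults at 0 C with the maximum optimum mortality
  expect_equal(daily_natural_mortality("adult_mature", 0, 0.134), 0.134 + 0.1846,
               tolerance = 1e-12)
  # non-decreasing away from the vertex and in M_star
  for (stage in c("egg", "pupa", "adult_mature")) {
    vertex <- c(egg = 18.125, pupa = 20.7, adult_mature = 0.0187 / (2 * 0.00049))[[stage]]
    offsets <- seq(0, 15, 1)
    up <- daily_natural_mortality(stage, vertex + offsets, 0.02)
    down <- daily_natural_mortality(stage, vertex - offsets, 0.02)
    expect_true(all(diff(up) >= -1e-12))
    expect_true(all(diff(down) >= -1e-12))
  }
  m <- sapply(seq(0, 1, 0.1), function(ms) daily_natural_mortality("larva", 30, ms))
  expect_true(all(diff(m) >= 0))
})

test_that("hourly death probabilities compound back to the daily rate", {
  expect_equal(hourly_death_probability(0), 0)
  expect_equal(hourly_death_probability(1), 1)
  p <- hourly_death_probability(0.15)
  expect_equal(p, 1 - 0.85^(1 / 24), tolerance = 1e-15)
  expect_equal(1 - (1 - p)^24, 0.15, tolerance = 1e-12)
  for (d in c(0.001, 0.0465, 0.134, 0.5, 0.999))
    expect_equal(1 - (1 - hourly_death_probability(d))^24, d, tolerance = 1e-12)
  # the raw-exponent variant exceeds the daily rate, hence the default rule
  expect_gt(hourly_death_probability(0.15, literal_exponent = TRUE), 0.15)
})

test_that("egg-count draws match the requested moments and clamp at zero", {
  expect_identical(daily_eggs(5, 0, n = 10), rep(5L, 10))
  set.seed(7)
  x <- daily_eggs(20, 3.57, n = 1e5)
  expect_lt(abs(mean(x) - 20), 3 * sqrt(3.57 / 1e5) + 0.05)  # + rounding slack
  set.seed(8)
  y <- daily_eggs(0.2, 3.57, n = 1e5)
  expect_true(all(y >= 0L))
  expect_gt(mean(y), 0.2)  # truncation at zero inflates the mean
})

test_that("sterilization is a daily Bernoulli with geometric persistence", {
  expect_true(all(sterilization_event(1, n = 100)))
  expect_false(any(sterilization_event(0, n = 100)))
  set.seed(9)
  fertile <- rep(TRUE, 2e4)
  for (d in 1:3) {
    fertile[fertile] <- !sterilization_event(0.5, n = sum(fertile))
    expect_lt(abs(mean(fertile) - 0.5^d), 4 * sqrt(0.5^d * (1 - 0.5^d) / 2e4))
  }
})
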