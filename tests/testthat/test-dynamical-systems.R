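test_that("logistic map reproduces the exact recurrence and warns on the absorbing orbit", {
  expect_warning(
    s <- generate_map(system_spec("logistic", initial_state = 0.5,
                                  n_samples = 4, transient = 0)),
    "absorbing"
  )
  expect_equal(s$values[1:2], c(1, 0))
  expect_equal(s$sampling_interval, 1)
})

test_that("Henon map from the origin lands on (1, 0) first", {
  s <- generate_map(system_spec("henon", initial_state = c(0, 0),
                                n_samples = 1, transient = 0))
  expect_equal(s$values, 1)
})

test_that("diverging orbits are reported with the iterate index", {
  expect_error(
    generate_map(system_spec("henon", initial_state = c(50, 50),
                             n_samples = 10, transient = 0)),
    "diverged at iterate"
  )
})

test_that("R = 4 logistic orbit follows the arcsine invariant density", {
  s <- generate_map(system_spec("logistic", n_samples = 1e5, seed = 11))
  brks <- seq(0, 1, length.out = 21)
  obs <- table(cut(s$values, brks))
  p <- diff(2 / pi * asin(sqrt(brks)))   # closed-form invariant measure
  expected <- 1e5 * p
  sigma <- sqrt(1e5 * p * (1 - p))
  expect_true(all(abs(obs - expected) < 3 * sigma))
})

test_that("map orbits are bit-reproducible given identical specs", {
  a <- generate_map(system_spec("henon", seed = 7))
  b <- generate_map(system_spec("henon", seed = 7))
  expect_identical(a$values, b$values)
})

test_that("Rossler trajectory stays bounded on the attractor", {
  s <- fixture_rossler()
  expect_true(all(abs(s$values) < 20))
  expect_equal(s$sampling_interval, 0.05)
  expect_length(s$values, 10000)
})

test_that("RK4 integration converges at order >= 3.5", {
  x_at <- function(dt) {
    spec <- system_spec("rossler", initial_state = c(1, 1, 1),
                        n_samples = round(10 / dt) + 1, transient = 0,
                        dt = dt)
    tail(generate_flow(spec)$values, 1)
  }
  e1 <- abs(x_at(0.05) - x_at(0.0125))
  e2 <- abs(x_at(0.025) - x_at(0.0125))
  order <- log2(e1 / e2)
  expect_gt(order, 3.5)
})

test_that("a zero-transient single sample returns the initial x", {
  s <- generate_flow(system_spec("rossler", initial_state = c(0.3, 0.1, 0.2),
                                 n_samples = 1, transient = 0))
  expect_equal(s$values[1], 0.3)
})

test_that("the Rossler flow is dissipative along the trajectory", {
  states <- generate_flow(system_spec("rossler", seed = 3), coords = "all")
  # divergence of the vector field: a + (x - c)
  div <- 0.2 + (states[, "x"] - 5.7)
  expect_lt(mean(div), 0)
})

test_that("system_spec validates its invariants", {
  expect_error(system_spec("logistic", initial_state = 1.5), "open interval")
  expect_error(system_spec("rossler", dt = -1), "dt")
  expect_error(system_spec("henon", n_samples = 0), "n_samples")
  expect_error(generate_map(system_spec("rossler")), "generate_flow")
})
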