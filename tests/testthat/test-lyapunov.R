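test_that("Wolf reports a near-zero exponent for a limit cycle", {
  t <- (0:4999) * 0.05
  emb <- embed_delay(scalar_series(sin(2 * pi * t / 3),
                                   sampling_interval = 0.05),
                     tau = 15, m = 2)
  est <- wolf_lle(emb)
  expect_lt(abs(est$lambda1), 0.005)
})

test_that("Wolf tracks the logistic expansion rate", {
  emb <- embed_delay(fixture_logistic(), tau = 1, m = 1)
  est <- wolf_lle(emb)
  expect_equal(est$lambda1, log(2), tolerance = 0.1)
  expect_true(est$diagnostics$reliable)
  expect_gte(est$diagnostics$n_segments, 10)
})

test_that("the Rosenstein curve of the logistic map rises at ln 2 per iterate", {
  emb <- embed_delay(fixture_logistic(), tau = 1, m = 1)
  crv <- rosenstein_curve(emb, max_steps = 15)
  est <- rosenstein_lle(crv)
  expect_equal(est$lambda1, log(2), tolerance = 0.05 * log(2))
  expect_false(est$diagnostics$low_confidence)
})

test_that("an exactly linear divergence curve is fitted to machine precision", {
  tt <- seq(0, 2, by = 0.1)
  curve <- tibble::tibble(step = seq_along(tt) - 1, time = tt,
                          mean_log_dist = 0.3 * tt - 4,
                          n_pairs = rep(100L, length(tt)))
  curve <- structure(curve, class = c("divergence_curve", class(curve)),
                     sampling_interval = 0.1, n_pairs = 100L, theiler = 1L)
  est <- rosenstein_lle(curve, sat_frac = 1)
  expect_equal(est$lambda1, 0.3, tolerance = 1e-12)
  expect_equal(est$diagnostics$fit_window, c(1, length(tt)))
})

test_that("white-noise divergence saturates essentially immediately", {
  set.seed(5)
  emb <- embed_delay(scalar_series(rnorm(3000)), tau = 1, m = 3)
  crv <- rosenstein_curve(emb, max_steps = 20)
  y <- crv$mean_log_dist
  expect_gt(y[3], y[1] + 0.8 * (max(y) - y[1]))
})

test_that("a constant series has no usable neighbours for divergence tracking", {
  ser <- scalar_series(rep(c(0, 0), 400))
  emb <- embed_delay(ser, tau = 1, m = 2)
  expect_error(rosenstein_curve(emb), "no nonzero-distance neighbour")
})

test_that("Sano-Sawada recovers the exact log-contraction of a linear map", {
  # noise-free geometric orbit x_{n+1} = x_n / 2: every local least-squares
  # fit reproduces the Jacobian exactly
  x <- scalar_series(0.5^(1:1050))
  sp <- sano_sawada_spectrum(embed_delay(x, tau = 1, m = 1), n_exponents = 1)
  expect_equal(sp$exponents[1], log(0.5), tolerance = 0.02)
})

test_that("the Rossler spectrum contains the flow's zero exponent", {
  emb <- embed_delay(fixture_rossler(), tau = 27, m = 3)
  sp <- sano_sawada_spectrum(emb, n_exponents = 3)
  expect_lt(abs(sp$exponents[2]), 0.03)
  expect_gt(sp$exponents[1], 0)
})

test_that("the Henon spectrum satisfies the analytic Jacobian constraints", {
  sp <- sano_sawada_spectrum(fixture_henon_embedding(), n_exponents = 2)
  expect_equal(sum(sp$exponents), log(0.3), tolerance = 0.15 * abs(log(0.3)))
  expect_gt(sp$exponents[1], 0)
  expect_lt(sp$exponents[2], 0)
  expect_identical(sp$exponents, sort(sp$exponents, decreasing = TRUE))
})

test_that("all three estimators are invariant under positive affine scaling", {
  x <- fixture_henon()
  y <- scalar_series(3.7 * x$values + 11, sampling_interval = 1)
  e1 <- embed_delay(x, 1, 2)
  e2 <- embed_delay(y, 1, 2)
  expect_equal(wolf_lle(e1)$lambda1, wolf_lle(e2)$lambda1, tolerance = 1e-6)
  r1 <- rosenstein_lle(rosenstein_curve(e1, max_steps = 20))
  r2 <- rosenstein_lle(rosenstein_curve(e2, max_steps = 20))
  expect_equal(r1$lambda1, r2$lambda1, tolerance = 1e-6)
  s1 <- sano_sawada_spectrum(e1, n_exponents = 2)
  s2 <- sano_sawada_spectrum(e2, n_exponents = 2)
  expect_equal(s1$exponents, s2$exponents, tolerance = 1e-6)
})

test_that("method estimates agree on the classical fixtures", {
  emb <- fixture_henon_embedding()
  wolf <- wolf_lle(emb)$lambda1
  ros <- rosenstein_lle(rosenstein_curve(emb, max_steps = 20))$lambda1
  sano <- sano_sawada_spectrum(emb, n_exponents = 2)$exponents[1]
  expect_true(all(sign(c(wolf, ros, sano)) == 1))
  expect_equal(ros, sano, tolerance = 0.2 * abs(sano))
})

test_that("KS entropy sums the strictly positive exponents", {
  expect_equal(ks_entropy(c(0.5, -1)), 0.5)
  expect_equal(ks_entropy(c(0.1, 0.2, -3)), 0.3)
  expect_equal(ks_entropy(c(-0.2, -1)), 0)
  sp <- lyapunov_spectrum(c(0.4, 0.01, -2), zero_tol = 0.02)
  expect_equal(sp$ks_entropy, 0.4)
})

test_that("attractor classification follows the sign taxonomy", {
  expect_equal(classify_attractor(c(-0.5))$class, "stable fixed point")
  expect_equal(classify_attractor(c(0.001, -0.8), zero_tol = 0.01)$class,
               "stable limit cycle")
  cl <- classify_attractor(c(0.1, 0.0, -0.7))
  expect_equal(cl$class, "strange attractor")
  expect_equal(cl$signs, "+0-")
  expect_equal(classify_attractor(c(0.0, 0.0, -0.5), zero_tol = 0.01)$class,
               "stable 2-torus")
  expect_equal(classify_attractor(c(0.5, 0.4, 0.3, -1))$class, "unclassified")
})

test_that("estimators reject undersized embeddings", {
  emb <- embed_delay(scalar_series(rnorm(100)), 1, 2)
  expect_error(wolf_lle(emb), "500")
  expect_error(rosenstein_curve(emb), "500")
  expect_error(sano_sawada_spectrum(emb), "1000")
})
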