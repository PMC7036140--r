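test_that("embed_delay reproduces the backward-lag construction exactly", {
  emb <- embed_delay(scalar_series(1:5), tau = 1, m = 2)
  expect_equal(emb$points,
               matrix(c(2, 3, 4, 5, 1, 2, 3, 4), ncol = 2))
  expect_equal(nrow(emb$points), 5 - (2 - 1) * 1)

  one <- embed_delay(scalar_series(1:10), tau = 3, m = 1)
  expect_equal(one$points[, 1], as.double(1:10))

  expect_error(embed_delay(scalar_series(1:10), tau = 4, m = 3),
               "too short")
})

test_that("the first embedding coordinate reproduces the tail of the source", {
  x <- fixture_henon()
  emb <- embed_delay(x, tau = 3, m = 4)
  expect_identical(emb$points[, 1], tail(x$values, nrow(emb$points)))
})

test_that("mutual information matches a brute-force histogram oracle", {
  set.seed(8)
  x <- cumsum(rnorm(600))
  mi <- mutual_information_delay(scalar_series(x), tau_max = 10)
  for (tau in c(1, 4, 9))
    expect_equal(mi$mi_curve$mi[tau], oracle_mi(x, tau), tolerance = 1e-10)
})

test_that("iid noise carries no delay information and selects tau = 1", {
  set.seed(4)
  mi <- mutual_information_delay(scalar_series(rnorm(1e4)), tau_max = 20)
  expect_equal(mi$chosen_tau, 1L)
  # every MI value sits at the permutation bias floor
  expect_true(all(mi$mi_curve$mi <= mi$bias_floor))
})

test_that("shuffling a structured series collapses its MI to the bias floor", {
  x <- generate_map(system_spec("henon", n_samples = 10000, seed = 6))$values
  mi_orig <- mutual_information_delay(scalar_series(x), tau_max = 5)
  set.seed(10)
  mi_shuf <- mutual_information_delay(scalar_series(sample(x)), tau_max = 5)
  expect_gt(mi_orig$mi_curve$mi[1], 10 * mi_shuf$bias_floor)
  expect_true(all(mi_shuf$mi_curve$mi <= mi_shuf$bias_floor))
})

test_that("a periodic sawtooth has an MI local maximum at its period", {
  P <- 25
  set.seed(12)
  x <- rep(seq_len(P) / P, length.out = 4000) + rnorm(4000, 0, 1e-6)
  mi <- mutual_information_delay(scalar_series(x), tau_max = 40)
  v <- mi$mi_curve$mi
  expect_gt(v[P], v[P - 1])
  expect_gt(v[P], v[P + 1])
})

test_that("delay selection lands on lag 1 for the strongly chaotic maps", {
  expect_equal(mutual_information_delay(fixture_henon())$chosen_tau, 1L)
  expect_equal(mutual_information_delay(fixture_logistic())$chosen_tau, 1L)
})

test_that("FNN chooses the known dimensions of the benchmark signals", {
  # Henon is two-dimensional
  fh <- false_nearest_neighbors(fixture_henon(), tau = 1, m_max = 6)
  expect_equal(fh$chosen_m, 2L)
  expect_true(fh$converged)

  # a sine embeds in the plane (quarter-period delay)
  t <- (0:4999) * 0.05
  fs <- false_nearest_neighbors(scalar_series(sin(2 * pi * t / 3),
                                              sampling_interval = 0.05),
                                tau = 15, m_max = 6)
  expect_equal(fs$chosen_m, 2L)

  # white noise never converges: m_max with a warning flag
  set.seed(3)
  expect_warning(
    fw <- false_nearest_neighbors(scalar_series(rnorm(5000)), tau = 1,
                                  m_max = 6),
    "never fell below"
  )
  expect_equal(fw$chosen_m, 6L)
  expect_false(fw$converged)
})

test_that("FNN fractions agree with the direct-definition oracle", {
  x <- fixture_henon()$values[1:800]
  f <- false_nearest_neighbors(scalar_series(x), tau = 1, m_max = 3)
  for (m in 1:3)
    expect_equal(f$fnn_curve$fraction[m], oracle_fnn_fraction(x, 1, m),
                 tolerance = 1e-12)
})

test_that("FNN fraction is non-increasing on deterministic map fixtures", {
  for (fix in list(fixture_henon(), fixture_logistic())) {
    f <- false_nearest_neighbors(fix, tau = 1, m_max = 6)
    expect_true(all(diff(f$fnn_curve$fraction) <= 1e-12))
  }
})

test_that("degenerate inputs are rejected", {
  expect_error(mutual_information_delay(scalar_series(rep(1, 500)),
                                        tau_max = 10), "zero-variance")
  expect_error(mutual_information_delay(scalar_series(rnorm(50)),
                                        tau_max = 20), "too short")
  expect_error(false_nearest_neighbors(scalar_series(rnorm(20)), tau = 5,
                                       m_max = 5), "too short")
})
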