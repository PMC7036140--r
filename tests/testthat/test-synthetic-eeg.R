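test_that("synthetic EEG is bit-identical under the same seed", {
  spec <- synthetic_eeg_spec(seed = 5, sharpwave_channels = "F7",
                             sharpwave_amplitude = 8)
  a <- generate_synthetic_eeg(spec)
  b <- generate_synthetic_eeg(spec)
  expect_identical(a$data, b$data)
  expect_equal(dim(a$data), c(2500, 21))
  expect_identical(colnames(a$data), eeg_channels_1020())
})

test_that("without sharp waves the background is homogeneous across channels", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 3))
  sds <- apply(rec$data, 2, sd)
  expect_lt(max(sds) / min(sds) - 1, 0.1)
})

test_that("channels are statistically exchangeable when events are disabled", {
  # KS on temporally subsampled (approximately independent) values;
  # alpha = 0.01, >= 95% of pairs across 20 seeds
  set.seed(99)
  pass <- 0; total <- 0
  for (s in 1:20) {
    rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = s))
    pairs <- replicate(10, sample(21, 2))
    sub <- seq(1, nrow(rec$data), by = 25)
    for (p in 1:10) {
      pv <- suppressWarnings(
        ks.test(rec$data[sub, pairs[1, p]], rec$data[sub, pairs[2, p]])$p.value)
      total <- total + 1
      if (pv > 0.01) pass <- pass + 1
    }
  }
  expect_gte(pass / total, 0.95)
})

test_that("focal sharp waves dominate the kurtosis of the focal channel", {
  adj <- c("C3", "F3", "Fp1", "T3")   # montage neighbours of F7
  hits <- 0
  for (s in 1:50) {
    spec <- synthetic_eeg_spec(sharpwave_channels = "F7",
                               sharpwave_amplitude = 8, sharpwave_rate = 1,
                               seed = s)
    rec <- generate_synthetic_eeg(spec)
    k <- apply(rec$data, 2, excess_kurtosis_free)
    non_adj <- setdiff(colnames(rec$data), c("F7", adj))
    if (k["F7"] > max(k[non_adj])) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("sharp-wave bleed reaches montage neighbours at reduced amplitude", {
  spec0 <- synthetic_eeg_spec(seed = 21)
  spec1 <- synthetic_eeg_spec(sharpwave_channels = "F7",
                              sharpwave_amplitude = 10, sharpwave_rate = 2,
                              seed = 21)
  base <- generate_synthetic_eeg(spec0)
  ev <- generate_synthetic_eeg(spec1)
  delta <- abs(ev$data - base$data)
  # the focal channel receives the events, neighbours a fraction,
  # distant channels nothing
  expect_gt(max(delta[, "F7"]), 0)
  expect_gt(max(delta[, "F3"]), 0)
  expect_lt(max(delta[, "F3"]), max(delta[, "F7"]))
  expect_equal(max(delta[, "O2"]), 0)
})

test_that("spec validation rejects malformed montages", {
  expect_error(synthetic_eeg_spec(channel_names = c("A", "B")), "21")
  expect_error(synthetic_eeg_spec(sharpwave_channels = "XX"), "subset")
  expect_error(synthetic_eeg_spec(bleed = 0.5), "bleed")
})
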