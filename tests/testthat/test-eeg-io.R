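test_that("CSV recordings round-trip bit-exactly", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 1, duration_s = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording(path, label = rec$label)
  expect_identical(back$data, rec$data)
  expect_equal(back$fs, rec$fs)
})

test_that("scrambled CSV channel order is restored to canonical order", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 2, duration_s = 1))
  tb <- tibble::as_tibble(as.data.frame(rec$data))
  set.seed(1)
  tb <- tb[, sample(ncol(tb))]
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, path)
  back <- read_recording(path, fs = 250)
  expect_identical(colnames(back$data), eeg_channels_1020())
  expect_identical(back$data[, "F7"], rec$data[, "F7"])
})

test_that("a missing montage channel is reported by name", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 3, duration_s = 1))
  tb <- tibble::as_tibble(as.data.frame(rec$data))
  tb$T3 <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tb, path)
  expect_error(read_recording(path, fs = 250), "T3")
})

test_that("CSV without time column requires fs", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 4, duration_s = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::as_tibble(as.data.frame(rec$data)), path)
  expect_error(read_recording(path), "fs is required")
  ok <- read_recording(path, fs = 250)
  expect_equal(ok$fs, 250)
})

test_that("EDF recordings are read with header rate and scrambled order restored", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 5, duration_s = 1))
  set.seed(2)
  perm <- sample(21)
  data <- rec$data[, perm]
  labels <- paste0("EEG ", colnames(data), "-REF")
  path <- withr::local_tempfile(fileext = ".edf")
  write_test_edf(path, data, fs = 250, labels = labels)
  back <- read_recording(path)
  expect_identical(colnames(back$data), eeg_channels_1020())
  expect_equal(back$fs, 250)
  # 16-bit quantization: values match within one digitization step
  step <- apply(rec$data, 2, function(v) diff(range(v))) / 65535
  for (ch in c("F7", "O2", "Cz"))
    expect_lt(max(abs(back$data[, ch] - rec$data[, ch])), 2 * step[ch])
})

test_that("non-montage EDF channels are dropped with a message", {
  rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 6, duration_s = 1))
  data <- cbind(rec$data, ECG = rnorm(nrow(rec$data)))
  path <- withr::local_tempfile(fileext = ".edf")
  write_test_edf(path, data, fs = 250,
                 labels = c(paste0("EEG ", colnames(rec$data)), "ECG"))
  expect_message(back <- read_recording(path), "ECG")
  expect_equal(ncol(back$data), 21)
})
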