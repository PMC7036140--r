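# benchmark fixtures, generated once per test session
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fixture_logistic <- function()
  fixture("logistic", generate_map(system_spec("logistic", seed = 1)))

fixture_henon <- function()
  fixture("henon", generate_map(system_spec("henon", seed = 2)))

fixture_rossler <- function()
  fixture("rossler", generate_flow(system_spec("rossler", seed = 3)))

fixture_henon_embedding <- function()
  fixture("henon_emb", embed_delay(fixture_henon(), tau = 1, m = 2))

# a small channel_metrics table built by hand, for averaging/trend tests
fake_metric_table <- function(label, value, metric = "lzc") {
  chans <- eeg_channels_1020()
  tb <- tibble::tibble(channel = chans)
  tb[[metric]] <- rep_len(value, length(chans))
  structure(tb, class = c("channel_metrics", class(tb)),
            label = label, fs = 250, diagnostics = list())
}

# minimal 16-bit EDF writer used only to exercise the reader
write_test_edf <- function(path, data, fs, labels = colnames(data)) {
  ns <- ncol(data)
  n_rec <- 1L
  spr <- nrow(data)
  pad <- function(s, w) formatC(as.character(s), width = -w)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(as.character(256 + ns * 256), 8); wr("", 44)
  wr(as.character(n_rec), 8); wr(format(spr / fs), 8)
  wr(as.character(ns), 4)
  dig_min <- -32768; dig_max <- 32767
  phys_min <- apply(data, 2, min); phys_max <- apply(data, 2, max)
  phys_max <- ifelse(phys_max == phys_min, phys_min + 1, phys_max)
  for (i in 1:ns) wr(labels[i], 16)
  for (i in 1:ns) wr("test", 80)
  for (i in 1:ns) wr("uV", 8)
  for (i in 1:ns) wr(format(phys_min[i], digits = 6), 8)
  for (i in 1:ns) wr(format(phys_max[i], digits = 6), 8)
  for (i in 1:ns) wr(as.character(dig_min), 8)
  for (i in 1:ns) wr(as.character(dig_max), 8)
  for (i in 1:ns) wr("", 80)
  for (i in 1:ns) wr(as.character(spr), 8)
  for (i in 1:ns) wr("", 32)
  for (i in 1:ns) {
    dig <- round((data[, i] - phys_min[i]) /
                   (phys_max[i] - phys_min[i]) * (dig_max - dig_min) + dig_min)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}
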