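#' Multichannel EEG recording
#'
#' A samples-by-channels matrix with a sampling rate and a label
#' (typically the recording year in the longitudinal workflow).
#'
#' @param data numeric matrix, one column per channel, with column
#'   names.
#' @param fs sampling rate in Hz.
#' @param label recording label.
#' @param channel_names channel labels; default the column names.
#' @return An `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, label = "", channel_names = NULL) {
  data <- as.matrix(data)
  channel_names <- channel_names %||% colnames(data)
  if (is.null(channel_names))
    abort("channel names are required (column names or channel_names=)")
  if (length(channel_names) != ncol(data))
    abort("channel_names length must match the number of columns")
  if (!all(is.finite(data)))
    abort("recording contains missing or non-finite samples")
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  colnames(data) <- channel_names
  structure(
    list(data = data, channel_names = channel_names, fs = fs,
         label = as.character(label)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.3g s)%s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs,
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
as_tibble.eeg_recording <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$data))
  dplyr::bind_cols(tibble(time = (seq_len(nrow(x$data)) - 1) / x$fs), out)
}

match_montage_channels <- function(found, wanted) {
  # case-insensitive, order-free; EDF labels like "EEG Fp1-REF" match on
  # any token equal to a montage label
  tokens <- lapply(found, function(lab)
    toupper(unlist(strsplit(lab, "[^[:alnum:]]+"))))
  idx <- vapply(wanted, function(ch) {
    hit <- which(vapply(seq_along(found), function(i)
      toupper(found[i]) == toupper(ch) ||
        any(tokens[[i]] == toupper(ch)), NA))
    if (length(hit) == 0) NA_integer_ else hit[1]
  }, 0L)
  idx
}

#' Read a multichannel EEG recording
#'
#' Supports numeric CSV (header row of channel names, optional leading
#' `time` column) and 16-bit EDF.  Channels are matched to the standard
#' montage case-insensitively and order-free, reordered to canonical
#' order; non-montage channels are dropped with a message.  Missing
#' montage channels are an error naming them.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"edf"`.
#' @param fs sampling rate in Hz, required for CSV without a time
#'   column; EDF carries its own.
#' @param label recording label; default the file name.
#' @param channels montage labels expected; default
#'   [eeg_channels_1020()].
#' @return An `eeg_recording` in canonical channel order.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           fs = NULL, label = NULL,
                           channels = eeg_channels_1020()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  label <- label %||% sub("\\.[^.]+$", "", basename(path))
  if (format == "csv") read_recording_csv(path, fs, label, channels)
  else read_recording_edf(path, label, channels)
}

read_recording_csv <- function(path, fs, label, channels) {
  # base read.csv: its strtod parsing is correctly rounded, so %.17g
  # output read back is bit-exact
  df <- utils::read.csv(path, check.names = FALSE)
  nm <- names(df)
  time_col <- which(tolower(nm) %in% c("time", "t"))[1]
  if (!is.na(time_col)) {
    if (is.null(fs)) {
      dt <- stats::median(diff(df[[time_col]]))
      fs <- 1 / dt
    }
    df <- df[, -time_col, drop = FALSE]
  }
  if (is.null(fs))
    abort("fs is required for CSV recordings without a time column")
  idx <- match_montage_channels(names(df), channels)
  if (anyNA(idx))
    abort(paste0("missing montage channels: ",
                 paste(channels[is.na(idx)], collapse = ", ")))
  extra <- setdiff(seq_along(df), idx)
  if (length(extra))
    message("dropping non-montage channels: ",
            paste(names(df)[extra], collapse = ", "))
  data <- as.matrix(df[, idx, drop = FALSE])
  colnames(data) <- channels
  eeg_recording(data, fs = fs, label = label)
}

#' Write a recording to CSV
#'
#' First column `time` in seconds, then one column per channel; the
#' numeric formatting round-trips doubles exactly, so a written
#' recording reads back bit-identical.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  tb <- as_tibble(rec)
  lines <- c(paste(names(tb), collapse = ","),
             do.call(paste, c(lapply(tb, function(col)
               sprintf("%.17g", col)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

read_ascii <- function(con, n) {
  trimws(rawToChar(readBin(con, "raw", n)))
}

# Minimal 16-bit EDF reader: header + per-signal headers + contiguous
# int16 data records, scaled to physical units.  Annotation and other
# non-montage signals are dropped.
read_recording_edf <- function(path, label, channels) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                      # version
  read_ascii(con, 80); read_ascii(con, 80)  # patient / recording id
  read_ascii(con, 8); read_ascii(con, 8)    # start date / time
  read_ascii(con, 8)                      # header length
  read_ascii(con, 44)                     # reserved
  n_records <- as.integer(read_ascii(con, 8))
  record_dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  if (!is.finite(ns) || ns < 1) abort("invalid EDF header")
  labels <- vapply(seq_len(ns), function(i) read_ascii(con, 16), "")
  for (i in seq_len(ns)) read_ascii(con, 80)   # transducer
  for (i in seq_len(ns)) read_ascii(con, 8)    # physical dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(read_ascii(con, 8)), 0)
  for (i in seq_len(ns)) read_ascii(con, 80)   # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(read_ascii(con, 8)), 0L)
  for (i in seq_len(ns)) read_ascii(con, 32)   # reserved

  idx <- match_montage_channels(labels, channels)
  if (anyNA(idx))
    abort(paste0("missing montage channels: ",
                 paste(channels[is.na(idx)], collapse = ", ")))
  extra <- setdiff(seq_len(ns), idx)
  if (length(extra))
    message("dropping non-montage channels: ",
            paste(labels[extra], collapse = ", "))
  if (length(unique(spr[idx])) != 1)
    abort("montage channels have inconsistent sampling rates in this EDF")
  fs <- spr[idx[1]] / record_dur

  raw_sig <- lapply(seq_len(ns), function(i) vector("list", n_records))
  for (rec_i in seq_len(n_records)) {
    for (sig in seq_len(ns)) {
      raw_sig[[sig]][[rec_i]] <- readBin(con, "integer", n = spr[sig],
                                         size = 2, signed = TRUE,
                                         endian = "little")
    }
  }
  data <- vapply(idx, function(sig) {
    dig <- unlist(raw_sig[[sig]])
    gain <- (phys_max[sig] - phys_min[sig]) / (dig_max[sig] - dig_min[sig])
    (dig - dig_min[sig]) * gain + phys_min[sig]
  }, numeric(n_records * spr[idx[1]]))
  colnames(data) <- channels
  eeg_recording(data, fs = fs, label = label)
}
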