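#' Specification of a synthetic 21-channel EEG recording
#'
#' Describes a surrogate interictal EEG segment: per-channel 1/f-shaped
#' ("pink") band-limited Gaussian background, with optional focal
#' sharp-wave transients — biphasic Gaussian-derivative pulses of
#' 70-200 ms width — injected into designated channels and bleeding at
#' reduced amplitude into montage-adjacent channels.  Defaults mirror a
#' routine clinical segment: 21 channels of the 10-20 montage, 250 Hz,
#' 10 s.
#'
#' @param channel_names exactly 21 unique labels; default
#'   [eeg_channels_1020()].
#' @param fs sampling rate in Hz.
#' @param duration_s segment duration in seconds.
#' @param background_amplitude background SD per channel (signal units,
#'   nominally microvolts).
#' @param background_exponent spectral exponent beta of the 1/f^beta
#'   background power spectrum.
#' @param band passband in Hz for the background (flat below the lower
#'   edge, zero above the upper).
#' @param sharpwave_channels subset of `channel_names` receiving sharp
#'   waves.
#' @param sharpwave_rate expected events per second per focal channel.
#' @param sharpwave_amplitude event peak amplitude as a multiple of the
#'   channel background SD.
#' @param sharpwave_width_ms range of event widths, milliseconds.
#' @param bleed fraction of the event amplitude reaching
#'   montage-adjacent channels (<= 0.25 by design).
#' @param seed integer seed; identical seeds give bit-identical
#'   recordings.
#' @return A `synthetic_eeg_spec` list.
#' @export
synthetic_eeg_spec <- function(channel_names = eeg_channels_1020(),
                               fs = 250, duration_s = 10,
                               background_amplitude = 10,
                               background_exponent = 2,
                               band = c(0.5, 45),
                               sharpwave_channels = character(),
                               sharpwave_rate = 1,
                               sharpwave_amplitude = 0,
                               sharpwave_width_ms = c(70, 200),
                               bleed = 0.25,
                               seed = NULL) {
  channel_names <- as.character(channel_names)
  if (length(channel_names) != 21 || anyDuplicated(channel_names))
    abort("channel_names must be exactly 21 unique labels")
  if (!all(sharpwave_channels %in% channel_names))
    abort("sharpwave_channels must be a subset of channel_names")
  check_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  check_scalar(duration_s, "duration_s", lower = 0, open_lower = TRUE)
  check_scalar(background_amplitude, "background_amplitude", lower = 0,
               open_lower = TRUE)
  check_scalar(sharpwave_rate, "sharpwave_rate", lower = 0)
  check_scalar(sharpwave_amplitude, "sharpwave_amplitude", lower = 0)
  check_scalar(bleed, "bleed", lower = 0, upper = 0.25)
  structure(
    list(channel_names = channel_names, fs = fs, duration_s = duration_s,
         background_amplitude = background_amplitude,
         background_exponent = background_exponent, band = band,
         sharpwave_channels = as.character(sharpwave_channels),
         sharpwave_rate = sharpwave_rate,
         sharpwave_amplitude = sharpwave_amplitude,
         sharpwave_width_ms = sharpwave_width_ms, bleed = bleed,
         seed = seed),
    class = "synthetic_eeg_spec"
  )
}

# band-limited 1/f^beta Gaussian noise of length n, unit SD
pink_background <- function(n, fs, beta, band) {
  white <- rnorm(n)
  spec <- fft(white)
  freq <- seq_len(n) - 1
  freq <- pmin(freq, n - freq) * fs / n
  gain <- numeric(n)
  inband <- freq > 0 & freq <= band[2]
  gain[inband] <- pmax(freq[inband], band[1])^(-beta / 2)
  x <- Re(fft(spec * gain, inverse = TRUE)) / n
  x / sd(x)
}

# biphasic Gaussian-derivative pulse, peak amplitude 1, support ~width
sharp_wave_pulse <- function(width_s, fs) {
  sigma <- width_s / 6
  t <- seq(-3 * sigma, 3 * sigma, by = 1 / fs)
  g <- -t * exp(-t^2 / (2 * sigma^2))
  g / max(abs(g))
}

#' Generate a synthetic multichannel EEG recording
#'
#' Seeded and reproducible: the same spec with the same seed yields a
#' bit-identical recording.  Background noise is independent across
#' channels; each sharp-wave event is added to the designated channels
#' at full amplitude and to their montage neighbours at the `bleed`
#' fraction.
#'
#' @param spec a [synthetic_eeg_spec()].
#' @return An `eeg_recording` (samples x 21 matrix with channel names,
#'   `fs`, and a label).
#' @examples
#' rec <- generate_synthetic_eeg(synthetic_eeg_spec(seed = 1, duration_s = 2))
#' dim(rec$data)
#' @export
generate_synthetic_eeg <- function(spec) {
  stopifnot(inherits(spec, "synthetic_eeg_spec"))
  n <- round(spec$fs * spec$duration_s)
  C <- length(spec$channel_names)
  with_seed(spec$seed, {
    data <- vapply(seq_len(C), function(ch)
      spec$background_amplitude *
        pink_background(n, spec$fs, spec$background_exponent, spec$band),
      numeric(n))
    colnames(data) <- spec$channel_names
    if (length(spec$sharpwave_channels) && spec$sharpwave_amplitude > 0 &&
        spec$sharpwave_rate > 0) {
      montage <- standard_montage_1020()
      focal_known <- all(spec$channel_names %in% montage$channel)
      neighbours <- if (focal_known)
        montage_adjacent(montage, spec$sharpwave_channels) else character()
      n_events <- rpois(1, spec$sharpwave_rate * spec$duration_s)
      if (n_events > 0) {
        onsets <- runif(n_events, 0, spec$duration_s)
        widths <- runif(n_events, spec$sharpwave_width_ms[1],
                        spec$sharpwave_width_ms[2]) / 1000
        signs <- sample(c(-1, 1), n_events, replace = TRUE)
        for (ev in seq_len(n_events)) {
          pulse <- signs[ev] * sharp_wave_pulse(widths[ev], spec$fs)
          i0 <- round(onsets[ev] * spec$fs)
          idx <- i0 + seq_along(pulse)
          ok <- idx >= 1 & idx <= n
          if (!any(ok)) next
          for (ch in spec$sharpwave_channels) {
            amp <- spec$sharpwave_amplitude * sd(data[, ch])
            data[idx[ok], ch] <- data[idx[ok], ch] + amp * pulse[ok]
          }
          for (ch in neighbours) {
            amp <- spec$bleed * spec$sharpwave_amplitude * sd(data[, ch])
            data[idx[ok], ch] <- data[idx[ok], ch] + amp * pulse[ok]
          }
        }
      }
    }
    eeg_recording(data, fs = spec$fs,
                  label = sprintf("synthetic_seed%s",
                                  spec$seed %||% "NA"))
  })
}
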