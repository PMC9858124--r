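# EMG preprocessing: quality screening, anti-aliased downsampling to 510 Hz
# (raw-EMG modality), and tremor-band envelope extraction at 50 Hz.

#' Automated EMG quality screen
#'
#' Deterministic stand-in for visual inspection: estimates the SNR as the
#' ratio (in dB) of power inside the EMG carrier band to power outside it
#' (the 4-10 Hz tremor band is excluded from the "outside" pool, since
#' tremor-band envelope energy is signal, not noise), and flags hard
#' clipping as three or more consecutive samples pinned at the amplitude
#' extreme. A recording is accepted iff SNR >= `snr_min_db` and no clipping.
#'
#' @param rec A `signal_recording` with modality `"emg-raw"`.
#' @param snr_min_db Acceptance threshold in dB (default 6).
#' @param carrier_band EMG carrier band in Hz (default `c(20, 450)`).
#' @param tremor_band Band excluded from the noise pool (default `c(4, 10)`).
#' @return A `quality_report`: `subject_id`, `channel`, `snr_estimate_db`,
#'   `clipping`, `accepted`.
#' @export
quality_screen <- function(rec, snr_min_db = 6, carrier_band = c(20, 450),
                           tremor_band = c(4, 10)) {
  stopifnot(inherits(rec, "signal_recording"), rec$modality == "emg-raw")
  x <- rec$samples - mean(rec$samples)
  n <- length(x)
  p <- abs(fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * rec$fs / n
  half <- freqs <= rec$fs / 2
  freqs <- freqs[half]; p <- p[half]
  in_band <- freqs >= carrier_band[1] & freqs <= carrier_band[2]
  out_band <- !in_band & !(freqs >= tremor_band[1] & freqs <= tremor_band[2])
  snr <- 10 * log10(sum(p[in_band]) / max(sum(p[out_band]), 1e-300))

  extreme <- abs(rec$samples) >= max(abs(rec$samples)) * (1 - 1e-12)
  r <- rle(extreme)
  clipping <- any(r$values & r$lengths >= 3L)

  structure(list(subject_id = rec$subject_id, channel = rec$channel,
                 snr_estimate_db = snr, clipping = clipping,
                 accepted = (snr >= snr_min_db) && !clipping),
            class = "quality_report")
}

# Fourier-domain resampling to an arbitrary output length: the spectrum is
# truncated at the new Nyquist frequency (ideal brick-wall anti-aliasing)
# and inverse-transformed at the new length. Exact for band-limited input;
# assumes approximate periodicity, so a few samples at each end carry edge
# leakage (negligible for 60-s recordings).
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(real = numeric(n_out), imaginary = numeric(n_out))
  nyq <- min(n, n_out)
  h <- nyq %/% 2
  Y[1:(h + 1)] <- X[1:(h + 1)]
  if (h >= 1) {
    lo_src <- n - h + 1 + (nyq %% 2 == 0)
    lo_dst <- n_out - h + 1 + (nyq %% 2 == 0)
    if (lo_src <= n) Y[lo_dst:n_out] <- X[lo_src:n]
  }
  if (nyq %% 2 == 0) {
    if (n_out < n) {
      Y[h + 1] <- X[h + 1] + X[n - h + 1]  # fold the split Nyquist bin
    } else {
      Y[h + 1] <- X[h + 1] / 2
      Y[n_out - h + 1] <- X[h + 1] / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Anti-aliased downsampling of a recording
#'
#' Rational-rate resampling in the Fourier domain (brick-wall low-pass at
#' the new Nyquist frequency built in), producing exactly
#' `round(n * target_fs / fs)` samples. With the defaults this takes the
#' 2042 Hz EMG to exactly 510 Hz, so one-second windows are exactly 510
#' samples.
#'
#' @param rec A `signal_recording` (or numeric vector with `fs`).
#' @param target_fs Output rate in Hz (default 510). Must be below the input
#'   rate; upsampling is not supported here.
#' @param fs Input rate for bare vectors.
#' @return The resampled recording (same class as input).
#' @export
downsample_emg <- function(rec, target_fs = 510, fs = NULL) {
  if (inherits(rec, "signal_recording")) {
    out <- rec
    out$samples <- downsample_emg(rec$samples, target_fs, rec$fs)
    out$fs <- target_fs
    return(out)
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
  if (target_fs >= fs) stop("target_fs must be below the input rate")
  fft_resample(as.numeric(rec), round(length(rec) * target_fs / fs))
}

#' Tremor-band EMG envelope at 50 Hz
#'
#' Full-wave rectification, zero-lag 4-10 Hz Butterworth band-pass at the
#' input rate (shared with the kinematic branch), then anti-aliased
#' downsampling to `envelope_fs`. The result carries the tremor burst rhythm
#' of the interference signal.
#'
#' @param rec A `signal_recording` with modality `"emg-raw"` (any rate).
#' @param band Envelope band in Hz (default `c(4, 10)`).
#' @param envelope_fs Output rate in Hz (default 50).
#' @return A `signal_recording` with modality `"emg-envelope"` at
#'   `envelope_fs`.
#' @export
emg_envelope <- function(rec, band = c(4, 10), envelope_fs = 50) {
  stopifnot(inherits(rec, "signal_recording"), rec$modality == "emg-raw")
  env <- bandpass_tremor(abs(rec$samples), rec$fs, band)
  out <- rec
  out$samples <- downsample_emg(env, envelope_fs, rec$fs)
  out$fs <- envelope_fs
  out$modality <- "emg-envelope"
  out
}
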