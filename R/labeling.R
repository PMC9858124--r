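# Window labelling by tremor-band PSD peak, balanced dataset assembly, and
# stratified splitting.

#' Periodogram of one window with tremor-band peak
#'
#' Single-taper (periodic Hann window) periodogram with density scaling
#' (power per Hz), one-sided. The peak power and frequency are the maximum
#' over the bins whose centre frequency lies in `band` (inclusive). A 1-s
#' window at 50 Hz gives ~1 Hz resolution, i.e. seven candidate bins in
#' 4-10 Hz.
#'
#' @param window Numeric vector, one analysis window.
#' @param fs Sampling rate in Hz.
#' @param band Tremor band in Hz (default `c(4, 10)`).
#' @return A `spectral_summary`: `freqs`, `psd`, `band`, `peak_freq`,
#'   `peak_power`.
#' @export
window_psd <- function(window, fs, band = c(4, 10)) {
  n <- length(window)
  stopifnot(n >= 2)
  taper <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))  # periodic Hann
  xw <- (window - mean(window)) * taper
  spec <- abs(stats::fft(xw))^2 / (fs * sum(taper^2))
  nb <- n %/% 2 + 1
  psd <- spec[1:nb]
  # one-sided density: double every bin except DC (and Nyquist when n even)
  dbl <- 2:(nb - as.integer(n %% 2 == 0))
  psd[dbl] <- 2 * psd[dbl]
  freqs <- (0:(nb - 1)) * fs / n
  in_band <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(in_band)) stop("no frequency bin falls inside the tremor band")
  k <- in_band[which.max(psd[in_band])]
  structure(list(freqs = freqs, psd = psd, band = band,
                 peak_freq = freqs[k], peak_power = psd[k]),
            class = "spectral_summary")
}

# Tremor-band peak power for every row of a window set.
window_peak_powers <- function(ws, band = c(4, 10)) {
  apply(ws$x, 1, function(w) window_psd(w, ws$fs, band)$peak_power)
}

#' Calibrate the tremor labelling threshold
#'
#' The decision threshold on the tremor-band PSD peak is set to a quantile
#' (default the 99th percentile) of the peak-power distribution observed in
#' no-tremor calibration windows, following the practice of estimating
#' tremor thresholds from data of healthy subjects. Windows of subjects
#' without tremor then exceed the threshold at a rate of about
#' `1 - quantile` by construction.
#'
#' @param peak_powers Numeric vector of tremor-band peak powers from
#'   no-tremor windows, or a list of `spectral_summary` objects.
#' @param quantile Calibration quantile in (0, 1] (default 0.99).
#' @param min_windows Minimum calibration-set size (default 30).
#' @return A `label_threshold`: `value`, `quantile`, `n`, plus summary
#'   statistics of the calibration distribution.
#' @export
calibrate_threshold <- function(peak_powers, quantile = 0.99,
                                min_windows = 30) {
  if (is.list(peak_powers)) {
    peak_powers <- vapply(peak_powers, function(s) s$peak_power, numeric(1))
  }
  if (!length(peak_powers)) stop("empty calibration set")
  if (length(peak_powers) < min_windows) {
    stop("need at least ", min_windows, " no-tremor windows to calibrate")
  }
  value <- as.numeric(stats::quantile(peak_powers, quantile, names = FALSE))
  structure(list(value = value, quantile = quantile, n = length(peak_powers),
                 calibration_median = stats::median(peak_powers),
                 calibration_max = max(peak_powers)),
            class = "label_threshold")
}

#' @export
print.label_threshold <- function(x, ...) {
  cat(sprintf(
    "Tremor labelling threshold: %.4g (q%.2f of %d no-tremor peak powers)\n",
    x$value, x$quantile, x$n))
  invisible(x)
}

#' Label windows by tremor-band PSD peak threshold
#'
#' A window is labelled `"tremor"` iff its tremor-band peak power is
#' strictly greater than the threshold (a peak exactly at the threshold is
#' `"no_tremor"`). The statistic may be computed from a parallel window set
#' (`stat_ws`) aligned row-for-row with `ws`: the kinematic pipeline labels
#' from the band-pass-filtered angle while the classifiers see the
#' unfiltered angle, and raw-EMG windows inherit the label of their
#' time-aligned envelope window.
#'
#' @param ws The `window_set` to label.
#' @param threshold A `label_threshold` from [calibrate_threshold()].
#' @param stat_ws Optional aligned `window_set` from which the PSD statistic
#'   is computed (defaults to `ws` itself). Must have the same number of
#'   windows.
#' @param band Tremor band in Hz (default `c(4, 10)`).
#' @return A `labeled_window_set`: `ws` plus `labels` (character,
#'   `"tremor"`/`"no_tremor"`), `peak_power` per window, and the threshold.
#' @export
label_windows <- function(ws, threshold, stat_ws = NULL, band = c(4, 10)) {
  stopifnot(inherits(ws, "window_set"), inherits(threshold, "label_threshold"))
  if (is.null(stat_ws)) stat_ws <- ws
  if (nrow(stat_ws$x) != nrow(ws$x)) {
    stop("stat_ws must be window-aligned with ws (same number of windows)")
  }
  pk <- window_peak_powers(stat_ws, band)
  ws$labels <- ifelse(pk > threshold$value, "tremor", "no_tremor")
  ws$peak_power <- pk
  ws$threshold <- threshold
  class(ws) <- c("labeled_window_set", "window_set")
  ws
}

# Row subset of a (labeled) window set.
subset_windows <- function(ws, idx) {
  out <- ws
  out$x <- ws$x[idx, , drop = FALSE]
  for (f in c("subject", "trial", "start", "design_label", "labels",
              "peak_power")) {
    if (!is.null(ws[[f]])) out[[f]] <- ws[[f]][idx]
  }
  out
}

#' Assemble a balanced dataset
#'
#' Uniform subsample without replacement of exactly `n_per_class` windows
#' from each class, so the final dataset is perfectly balanced (e.g. 9000 +
#' 9000 one-second kinematic instances, or 4000 + 4000 per EMG modality).
#'
#' @param lws A `labeled_window_set`.
#' @param n_per_class Windows to keep per class.
#' @param seed Integer seed for the subsample.
#' @return The balanced `labeled_window_set`.
#' @export
assemble_balanced <- function(lws, n_per_class, seed = 1L) {
  stopifnot(inherits(lws, "labeled_window_set"))
  idx_by_class <- split(seq_along(lws$labels), lws$labels)
  for (cl in c("tremor", "no_tremor")) {
    avail <- length(idx_by_class[[cl]])
    if (is.null(idx_by_class[[cl]]) || avail < n_per_class) {
      stop(sprintf("class '%s' has only %d windows; %d requested",
                   cl, if (is.null(idx_by_class[[cl]])) 0L else avail,
                   n_per_class))
    }
  }
  set.seed(seed)
  keep <- c(sample(idx_by_class$tremor, n_per_class),
            sample(idx_by_class$no_tremor, n_per_class))
  subset_windows(lws, sort(keep))
}

#' Stratified dataset split
#'
#' Random partition into train/test (70/30, the classical-model scheme) or
#' train/validation/test (70/15/15, the LSTM scheme), stratified by label so
#' class balance is preserved within +/- 1 window per partition. Partitions
#' are disjoint and exhaustive; the returned indices can be reused across
#' model families.
#'
#' @param lws A `labeled_window_set`.
#' @param scheme `"ml"` for 70/30 or `"lstm"` for 70/15/15, or a named
#'   numeric vector of fractions summing to 1.
#' @param seed Integer seed.
#' @return A named list of integer index vectors (`train`, `test`, and
#'   `validation` for the three-way scheme).
#' @export
split_windows <- function(lws, scheme = c("ml", "lstm"), seed = 1L) {
  stopifnot(inherits(lws, "labeled_window_set"))
  if (is.character(scheme)) {
    scheme <- match.arg(scheme)
    fractions <- switch(scheme,
                        ml = c(train = 0.70, test = 0.30),
                        lstm = c(train = 0.70, validation = 0.15, test = 0.15))
  } else {
    fractions <- scheme
    if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  }
  n <- length(lws$labels)
  if (any(fractions * n < 1)) {
    stop("a partition would receive less than one window")
  }
  set.seed(seed)
  parts <- stats::setNames(vector("list", length(fractions)),
                           names(fractions))
  for (cl in unique(lws$labels)) {
    idx <- sample(which(lws$labels == cl))
    sizes <- floor(fractions * length(idx))
    # distribute the remainder to the largest partitions first
    rem <- length(idx) - sum(sizes)
    if (rem > 0) {
      ord <- order(fractions, decreasing = TRUE)
      sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
    }
    at <- cumsum(c(0, sizes))
    for (j in seq_along(fractions)) {
      parts[[j]] <- c(parts[[j]], idx[(at[j] + 1):at[j + 1]])
    }
  }
  lapply(parts, sort)
}
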