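# Shared fixtures: small deterministic cohorts and signals built in code.

# Noise-free tremor configuration: fixed frequency/amplitude, no drift,
# no jitter, no distractor -- the relative wrist angle is a pure sinusoid.
clean_kin_config <- function(f = 6, amp = 5, seed = 42L) {
  cohort_config(n_patients = 1, n_healthy = 1, seed = seed,
                tremor_freq_range = c(f, f), tremor_amp_deg = c(amp, amp),
                kin_noise_sd_deg = 0, drift_sd_deg = 0, cycle_jitter = 0,
                physio_amp = 0)
}

# Small default-SNR cohort shared across labeling/model tests (10-s trials
# keep the suite fast). Cached per session.
small_cohort <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 7L, duration = 10) {
    key <- paste0("c", seed, "_", duration)
    if (is.null(cache[[key]])) {
      cfg <- cohort_config(trial_duration = duration, seed = seed)
      cache[[key]] <- generate_cohort(cfg)
    }
    cache[[key]]
  }
})

# Amplitude of frequency component f in a series (exact for on-bin f).
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  freqs <- (0:(n - 1)) * fs / n
  2 * abs(stats::fft(x))[which.min(abs(freqs - f))] / n
}

# A quick labelled window set from raw numbers, for split/balance tests.
toy_labeled_windows <- function(n, wl = 50, seed = 1L) {
  set.seed(seed)
  ws <- structure(list(x = matrix(stats::rnorm(n * wl), n, wl), fs = 50,
                       window_len = wl, modality = "kinematic-angle",
                       subject = rep("S", n), trial = rep(1L, n),
                       start = seq_len(n),
                       design_label = rep(c("tremor", "no_tremor"),
                                          length.out = n)),
                  class = "window_set")
  ws$labels <- ws$design_label
  class(ws) <- c("labeled_window_set", "window_set")
  ws
}
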