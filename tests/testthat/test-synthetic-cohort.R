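test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(tremor_amp_deg = c(50, 120)), "90")
  expect_error(cohort_config(emg_carrier_band = c(20, 1100)), "Nyquist")
  expect_error(cohort_config(tremor_freq_range = c(4, 30)), "Nyquist")
  expect_silent(validate_cohort_config(cohort_config()))
})

test_that("noise-free tremor kinematics are a pure sinusoid of the design amplitude", {
  cfg <- clean_kin_config(f = 6, amp = 5)
  qs <- simulate_kinematics(cfg, "tremor", "P01")
  ang <- quaternions_to_wrist_angle(qs)
  expect_equal(ang$fs, 50)
  expect_length(ang$angle, 3000)
  # exact 6 Hz bin at 60 s: amplitude 5 degrees, no other component
  expect_equal(fft_amplitude(ang$angle, 6, 50), 5, tolerance = 1e-9)
  spec <- abs(fft(ang$angle))^2
  p6 <- sum(spec[c(361, 3000 - 359)])  # 6 Hz bins (1-based, +/-)
  expect_gt(p6 / sum(spec[-1]), 0.999)
})

test_that("no-tremor stream with everything off is exactly flat", {
  cfg <- cohort_config(n_patients = 0, n_healthy = 1, kin_noise_sd_deg = 0,
                       drift_sd_deg = 0, cycle_jitter = 0, physio_amp = 0,
                       seed = 5)
  qs <- simulate_kinematics(cfg, "no_tremor", "H01")
  expect_equal(qs$hand_q, qs$forearm_q, tolerance = 1e-12)
  ang <- quaternions_to_wrist_angle(qs)
  expect_lt(max(abs(ang$angle)), 1e-9)
})

test_that("spectral fidelity: band power concentrates at the subject frequency", {
  # jitter on (default), sensor noise off: >= 99% of band-limited power of
  # the relative angle lies within f_t +/- 0.5 Hz
  cfg <- cohort_config(kin_noise_sd_deg = 0, drift_sd_deg = 0,
                       physio_amp = 0, seed = 21)
  qs <- simulate_kinematics(cfg, "tremor", "P03")
  f_t <- qs$params$f_t
  ang <- quaternions_to_wrist_angle(qs)$angle
  n <- length(ang)
  freqs <- (0:(n - 1)) * 50 / n
  spec <- abs(fft(ang - mean(ang)))^2
  half <- 2:(n / 2)
  band <- freqs[half] >= 1  # exclude residual DC leakage only
  near <- abs(freqs[half] - f_t) <= 0.5
  expect_gt(sum(spec[half][near]) / sum(spec[half][band]), 0.99)
})

test_that("EMG generator: broadband carrier, tremor-band envelope contrast", {
  cfg <- cohort_config(trial_duration = 20, seed = 9)
  pat <- simulate_emg(cfg, "tremor", "FCR", "P01")
  hea <- simulate_emg(cfg, "no_tremor", "FCR", "H01")
  # comparable total power at the common activation level
  expect_equal(mean(pat$samples^2), mean(hea$samples^2), tolerance = 0.2)
  # raw spectra are broadband: median in-band PSD well above out-of-band
  ps <- function(x, lo, hi) {
    n <- length(x); fr <- (0:(n - 1)) * cfg$emg_fs / n
    sp <- abs(fft(x))^2
    median(sp[fr >= lo & fr <= hi])
  }
  expect_gt(ps(pat$samples, 20, 450) / ps(pat$samples, 500, 1000), 10)
  # tremor envelope concentrates power at f_t; healthy has no such peak
  env_p <- emg_envelope(pat)
  env_h <- emg_envelope(hea)
  sp_p <- window_psd(env_p$samples, 50)
  expect_equal(sp_p$peak_freq, pat$params$f_t, tolerance = 1)
  band_power <- function(env) {
    n <- length(env$samples)
    fr <- (0:(n - 1)) * 50 / n
    sp <- abs(fft(env$samples - mean(env$samples)))^2
    sp[fr >= 4 & fr <= 10]
  }
  bp <- band_power(env_p); bh <- band_power(env_h)
  expect_gt(max(bp), 3 * median(bp))          # patient: sharp tremor peak
  expect_lt(max(bh) / max(bp), 0.25)          # healthy: no comparable peak
})

test_that("zero modulation depth leaves no tremor-band envelope peak", {
  cfg <- cohort_config(trial_duration = 20, emg_mod_depth = c(0, 0),
                       physio_amp = 0, seed = 13)
  rec <- simulate_emg(cfg, "tremor", "FCR", "P01")
  env <- emg_envelope(rec)
  # envelope fluctuations are residual noise: peak no sharper than 5x median
  sp <- window_psd(env$samples, 50)
  n <- length(env$samples)
  fr <- (0:(n - 1)) * 50 / n
  spec <- abs(fft(env$samples - mean(env$samples)))^2
  inb <- spec[fr >= 4 & fr <= 10]
  expect_lt(max(inb), 10 * median(inb))
})

test_that("generation is a pure function of the configuration", {
  cfg <- cohort_config(n_patients = 2, n_healthy = 1, trial_duration = 5,
                       seed = 42)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$kinematics[[1]]$hand_q, b$kinematics[[1]]$hand_q)
  expect_identical(a$emg[[1]]$samples, b$emg[[1]]$samples)
  # and per-operation too
  k1 <- simulate_kinematics(cfg, "tremor", "P01")
  k2 <- simulate_kinematics(cfg, "tremor", "P01")
  expect_identical(k1$hand_q, k2$hand_q)
})

test_that("cohort structure matches the recruitment design", {
  cfg <- cohort_config(n_patients = 12, n_healthy = 11, trial_duration = 2,
                       seed = 3)
  coh <- generate_cohort(cfg)
  expect_length(coh$kinematics, 23)
  expect_length(coh$emg, 46)
  expect_equal(sum(coh$manifest$class == "tremor"), 12)
  expect_equal(sum(coh$manifest$class == "no_tremor"), 11)
  # patients-only / controls-only edge cases
  coh0 <- generate_cohort(cohort_config(n_patients = 0, n_healthy = 2,
                                        trial_duration = 2, seed = 3),
                          "kinematics")
  expect_true(all(coh0$manifest$class == "no_tremor"))
})
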