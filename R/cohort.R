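# Virtual cohort configuration and generative models for kinematic and EMG
# recordings of tremor patients and healthy controls.

#' Cohort configuration
#'
#' Parameters of the virtual tremor cohort. Defaults reproduce the recording
#' conditions the pipeline is designed for: 60-s postural trials, hand and
#' forearm IMU quaternions at 50 Hz, bipolar surface EMG from the wrist
#' flexor (FCR) and extensor (ECR) at 2042 Hz, pathological tremor in the
#' 4-10 Hz band, a low-amplitude 8-12 Hz physiological-tremor distractor in
#' controls, and a 10%-MVC isometric activation level for healthy EMG.
#'
#' @param n_patients Number of tremor-class subjects (default 12).
#' @param n_healthy Number of no-tremor-class subjects (default 11).
#' @param n_trials Trials recorded per subject (default 1).
#' @param trial_duration Trial length in seconds (default 60).
#' @param tremor_freq_range Pathological tremor frequency interval in Hz
#'   from which each patient's tremor frequency is drawn (default `c(4, 10)`).
#' @param tremor_amp_deg Kinematic tremor amplitude interval in degrees of
#'   wrist flexion-extension, drawn per patient (default `c(2, 8)`; postural
#'   essential-tremor wrist oscillations of a few degrees).
#' @param emg_mod_depth EMG burst modulation-depth interval (fraction of the
#'   carrier amplitude removed between bursts), drawn per patient
#'   (default `c(0.6, 0.9)`).
#' @param physio_tremor_band Physiological tremor frequency interval in Hz
#'   for healthy subjects (default `c(8, 12)`).
#' @param physio_amp Amplitude of the physiological-tremor distractor as a
#'   fraction of the mean pathological amplitude (default 0.1). Set to 0 to
#'   disable the distractor.
#' @param imu_fs IMU quaternion sampling rate in Hz (default 50).
#' @param emg_fs EMG sampling rate in Hz (default 2042).
#' @param emg_carrier_band EMG interference-pattern carrier band in Hz
#'   (default `c(20, 450)`).
#' @param snr_db Additive measurement-noise level of the EMG channels in dB
#'   (default 20).
#' @param mvc_fraction Healthy isometric activation level as a fraction of
#'   maximum voluntary contraction (default 0.10).
#' @param kin_noise_sd_deg IMU angular sensor noise, standard deviation in
#'   degrees (default 0.1).
#' @param drift_sd_deg Standard deviation of the slow (< 1 Hz) postural
#'   drift of the wrist angle, in degrees (default 1.5).
#' @param cycle_jitter Cycle-to-cycle fractional jitter of the tremor
#'   frequency and amplitude (default 0.05), so the oscillation is not an
#'   unrealistically pure sinusoid.
#' @param fcr_ecr_phase Phase offset in radians between FCR and ECR burst
#'   trains (default `pi`, i.e. alternating flexor/extensor bursts; 0 gives
#'   co-contraction).
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   configuration, so a fixed seed gives bit-identical output.
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_patients = 12, n_healthy = 11, n_trials = 1,
                          trial_duration = 60,
                          tremor_freq_range = c(4, 10),
                          tremor_amp_deg = c(2, 8),
                          emg_mod_depth = c(0.6, 0.9),
                          physio_tremor_band = c(8, 12),
                          physio_amp = 0.1,
                          imu_fs = 50, emg_fs = 2042,
                          emg_carrier_band = c(20, 450),
                          snr_db = 20, mvc_fraction = 0.10,
                          kin_noise_sd_deg = 0.1, drift_sd_deg = 1.5,
                          cycle_jitter = 0.05, fcr_ecr_phase = pi,
                          seed = 1L) {
  cfg <- list(n_patients = n_patients, n_healthy = n_healthy,
              n_trials = n_trials, trial_duration = trial_duration,
              tremor_freq_range = tremor_freq_range,
              tremor_amp_deg = tremor_amp_deg,
              emg_mod_depth = emg_mod_depth,
              physio_tremor_band = physio_tremor_band,
              physio_amp = physio_amp,
              imu_fs = imu_fs, emg_fs = emg_fs,
              emg_carrier_band = emg_carrier_band,
              snr_db = snr_db, mvc_fraction = mvc_fraction,
              kin_noise_sd_deg = kin_noise_sd_deg,
              drift_sd_deg = drift_sd_deg,
              cycle_jitter = cycle_jitter,
              fcr_ecr_phase = fcr_ecr_phase,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 0, cfg$n_healthy >= 0, cfg$n_trials >= 1,
            cfg$trial_duration > 0)
  if (cfg$tremor_freq_range[1] <= 0 ||
      cfg$tremor_freq_range[2] >= cfg$imu_fs / 2 ||
      cfg$tremor_freq_range[2] >= 50 / 2) {
    stop("tremor_freq_range must lie inside (0, Nyquist) of both the IMU ",
         "rate and the 50 Hz envelope rate")
  }
  if (any(cfg$tremor_amp_deg < 0) || any(cfg$emg_mod_depth < 0) ||
      any(cfg$emg_mod_depth > 1) || cfg$physio_amp < 0) {
    stop("amplitudes must be non-negative (EMG modulation depth in [0, 1])")
  }
  if (cfg$emg_carrier_band[2] >= cfg$emg_fs / 2) {
    stop("emg_carrier_band upper edge must be below the EMG Nyquist rate")
  }
  # anatomical plausibility: worst-case tremor excursion plus drift and the
  # physiological distractor must stay within +/- 90 degrees of flexion
  worst <- max(cfg$tremor_amp_deg) * (1 + cfg$cycle_jitter) +
    6 * cfg$drift_sd_deg +
    cfg$physio_amp * mean(cfg$tremor_amp_deg) + 6 * cfg$kin_noise_sd_deg
  if (worst > 90) {
    stop("configured amplitudes can drive the wrist angle beyond 90 ",
         "degrees; reduce tremor_amp_deg or drift_sd_deg")
  }
  invisible(cfg)
}

# Deterministic per-subject/per-use seed derived from the cohort seed, so
# individual simulators can be called standalone yet match generate_cohort().
derive_seed <- function(seed, subject_id, salt = 0L) {
  h <- sum(utf8ToInt(as.character(subject_id)) * seq_along(utf8ToInt(as.character(subject_id))))
  as.integer((as.double(seed) * 48271 + h * 16807 + salt * 69621) %% 2147483647)
}

# Smooth noise in [-1, 1] used for cycle-to-cycle jitter and postural drift:
# white noise low-passed below `cutoff_hz`, rescaled to unit maximum.
smooth_noise <- function(n, fs, cutoff_hz) {
  x <- stats::rnorm(n + 4 * fs)
  bf <- signal::butter(2, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  y <- signal::filtfilt(bf, x)[(2 * fs + 1):(2 * fs + n)]
  m <- max(abs(y))
  if (m == 0) y else y / m
}

# Per-subject generative parameters, drawn once and shared between the
# kinematic and EMG simulators of the same subject.
draw_subject_params <- function(cfg, subject_class, subject_id) {
  set.seed(derive_seed(cfg$seed, subject_id, salt = 1L))
  if (subject_class == "tremor") {
    list(f_t = stats::runif(1, cfg$tremor_freq_range[1], cfg$tremor_freq_range[2]),
         kin_amp = stats::runif(1, cfg$tremor_amp_deg[1], cfg$tremor_amp_deg[2]),
         emg_depth = stats::runif(1, cfg$emg_mod_depth[1], cfg$emg_mod_depth[2]),
         f_physio = NA_real_)
  } else {
    list(f_t = NA_real_, kin_amp = 0, emg_depth = 0,
         f_physio = stats::runif(1, cfg$physio_tremor_band[1],
                                 cfg$physio_tremor_band[2]))
  }
}

# Jittered oscillation: instantaneous frequency f0 * (1 + j * s1(t)) and
# amplitude amp * (1 + j * s2(t)) with s1, s2 smooth in [-1, 1].
jittered_oscillation <- function(n, fs, f0, amp, jitter, phase0,
                                 half_wave = FALSE) {
  s1 <- smooth_noise(n, fs, 2)
  s2 <- smooth_noise(n, fs, 2)
  finst <- f0 * (1 + jitter * s1)
  phase <- phase0 + 2 * pi * cumsum(finst) / fs
  carrier <- if (half_wave) pmax(sin(phase), 0) else sin(phase)
  amp * (1 + jitter * s2) * carrier
}

#' Simulate a paired hand/forearm quaternion stream
#'
#' The forearm stream is a slow (< 1 Hz) postural drift; the hand stream is
#' the forearm composed with a rotation about the flexion-extension axis
#' (x). For tremor-class subjects the flexion angle carries a 4-10 Hz
#' oscillation with per-subject frequency and amplitude and cycle-to-cycle
#' jitter; for controls it carries drift, sensor noise and optionally a
#' low-amplitude 8-12 Hz physiological oscillation. Composition order is
#' `q_hand = q_forearm * q_rel` (relative rotation expressed in the forearm
#' frame), the exact inverse of [quaternions_to_wrist_angle()].
#'
#' @param cfg A [cohort_config()].
#' @param subject_class `"tremor"` or `"no_tremor"`.
#' @param subject_id Subject identifier (drives the per-subject seed).
#' @param trial Trial index (distinct trials get independent noise).
#' @param params Optional pre-drawn subject parameters (used by
#'   [generate_cohort()] so kinematics and EMG share the tremor frequency).
#' @return A `quaternion_stream` object: list with `hand_q`, `forearm_q`
#'   (n x 4 unit-quaternion matrices), `fs`, `subject_id`, `design_label`,
#'   and the generative `params`.
#' @export
simulate_kinematics <- function(cfg, subject_class = c("tremor", "no_tremor"),
                                subject_id = "S01", trial = 1L,
                                params = NULL) {
  subject_class <- match.arg(subject_class)
  validate_cohort_config(cfg)
  if (is.null(params)) params <- draw_subject_params(cfg, subject_class, subject_id)
  fs <- cfg$imu_fs
  n <- round(fs * cfg$trial_duration)
  set.seed(derive_seed(cfg$seed, subject_id, salt = 100L + trial))

  drift_fore <- vapply(1:3, function(i) {
    d <- smooth_noise(n, fs, 0.8)
    s <- stats::sd(d)
    if (s > 0) d * cfg$drift_sd_deg / s else d
  }, numeric(n))

  theta_drift <- {
    d <- smooth_noise(n, fs, 0.8)
    s <- stats::sd(d)
    if (s > 0) d * cfg$drift_sd_deg / s else d
  }
  noise <- stats::rnorm(n, 0, cfg$kin_noise_sd_deg)

  if (subject_class == "tremor") {
    osc <- jittered_oscillation(n, fs, params$f_t, params$kin_amp,
                                cfg$cycle_jitter, stats::runif(1, 0, 2 * pi))
  } else if (cfg$physio_amp > 0) {
    osc <- jittered_oscillation(n, fs, params$f_physio,
                                cfg$physio_amp * mean(cfg$tremor_amp_deg),
                                cfg$cycle_jitter, stats::runif(1, 0, 2 * pi))
  } else {
    osc <- numeric(n)
  }
  theta <- osc + theta_drift + noise

  q_forearm <- quat_multiply(
    quat_multiply(quat_from_axis_angle(c(1, 0, 0), drift_fore[, 1]),
                  quat_from_axis_angle(c(0, 1, 0), drift_fore[, 2])),
    quat_from_axis_angle(c(0, 0, 1), drift_fore[, 3]))
  q_rel <- quat_from_axis_angle(c(1, 0, 0), theta)
  q_hand <- quat_multiply(q_forearm, q_rel)

  structure(list(hand_q = quat_normalize(q_hand),
                 forearm_q = quat_normalize(q_forearm),
                 fs = fs, subject_id = subject_id, trial = trial,
                 design_label = subject_class, params = params),
            class = "quaternion_stream")
}

#' Simulate a bipolar surface EMG recording
#'
#' The carrier is zero-mean Gaussian noise band-limited to the EMG
#' interference band (default 20-450 Hz), the standard surrogate for
#' interference-pattern surface EMG. Tremor-class subjects amplitude-modulate
#' the carrier with a half-wave-rectified sinusoidal burst train at the
#' subject's tremor frequency (FCR and ECR in antiphase by default);
#' controls hold a constant isometric activation at `mvc_fraction` of MVC,
#' optionally with a shallow 8-12 Hz physiological modulation. Both classes
#' are scaled to the same root-mean-square level (the 10%-MVC analogue) and
#' receive additive white measurement noise at `snr_db`. Amplitude units are
#' fractions of MVC.
#'
#' @inheritParams simulate_kinematics
#' @param channel `"FCR"` (wrist flexor) or `"ECR"` (wrist extensor).
#' @return A `signal_recording` with `modality = "emg-raw"`.
#' @export
simulate_emg <- function(cfg, subject_class = c("tremor", "no_tremor"),
                         channel = c("FCR", "ECR"), subject_id = "S01",
                         trial = 1L, params = NULL) {
  subject_class <- match.arg(subject_class)
  channel <- match.arg(channel)
  validate_cohort_config(cfg)
  if (is.null(params)) params <- draw_subject_params(cfg, subject_class, subject_id)
  fs <- cfg$emg_fs
  n <- round(fs * cfg$trial_duration)
  set.seed(derive_seed(cfg$seed, subject_id,
                       salt = 200L + trial * 2L + (channel == "ECR")))

  bf <- signal::butter(4, cfg$emg_carrier_band / (fs / 2), type = "pass")
  carrier <- filtfilt_padded(bf, stats::rnorm(n + 2 * fs), fs)[(fs + 1):(fs + n)]
  carrier <- carrier / stats::sd(carrier)

  phase0 <- stats::runif(1, 0, 2 * pi) +
    if (channel == "ECR") cfg$fcr_ecr_phase else 0
  if (subject_class == "tremor") {
    depth <- params$emg_depth
    burst <- jittered_oscillation(n, fs, params$f_t, 1, cfg$cycle_jitter,
                                  phase0, half_wave = TRUE)
    m <- (1 - depth) + depth * burst
  } else if (cfg$physio_amp > 0) {
    m <- 1 + cfg$physio_amp *
      jittered_oscillation(n, fs, params$f_physio, 1, cfg$cycle_jitter, phase0)
    m <- pmax(m, 0)
  } else {
    m <- rep(1, n)
  }
  x <- carrier * m
  x <- x * cfg$mvc_fraction / sqrt(mean(x^2))  # common RMS activation level
  noise_sd <- sqrt(mean(x^2) / 10^(cfg$snr_db / 10))
  x <- x + stats::rnorm(n, 0, noise_sd)

  signal_recording(x, fs = fs, modality = "emg-raw", channel = channel,
                   subject_id = subject_id, design_label = subject_class,
                   trial = trial, params = params)
}

#' Construct a signal recording
#'
#' Light container for a single-channel sampled series with provenance.
#'
#' @param samples Numeric vector, all finite.
#' @param fs Sampling rate in Hz.
#' @param modality One of `"kinematic-angle"`, `"emg-raw"`, `"emg-envelope"`.
#' @param channel Channel name (`"wrist"`, `"FCR"`, `"ECR"`).
#' @param subject_id,design_label,trial,params Provenance metadata.
#' @return A `signal_recording` object.
#' @export
signal_recording <- function(samples, fs,
                             modality = c("kinematic-angle", "emg-raw",
                                          "emg-envelope"),
                             channel = "wrist", subject_id = NA_character_,
                             design_label = NA_character_, trial = 1L,
                             params = NULL) {
  modality <- match.arg(modality)
  if (!all(is.finite(samples))) stop("samples must all be finite")
  structure(list(samples = as.numeric(samples), fs = fs, modality = modality,
                 channel = channel, subject_id = subject_id,
                 design_label = design_label, trial = trial, params = params),
            class = "signal_recording")
}

#' Generate a virtual cohort
#'
#' Draws `n_patients` tremor-class and `n_healthy` control subjects and
#' simulates, per subject and trial, one paired-IMU quaternion stream and two
#' EMG channels (FCR, ECR). Per-subject generative parameters (tremor
#' frequency, amplitude, modulation depth) are drawn once and logged in the
#' manifest so recovery tests can compare against ground truth. The whole
#' cohort is a pure function of the configuration.
#'
#' @param cfg A [cohort_config()].
#' @param modalities Which signal families to simulate (subsetting saves time
#'   when only one pipeline branch is needed).
#' @return A list of class `tremor_cohort`: `kinematics` (list of
#'   `quaternion_stream`), `emg` (list of `signal_recording`), and `manifest`
#'   (data frame of subjects, classes and generative parameters).
#' @export
generate_cohort <- function(cfg, modalities = c("kinematics", "emg")) {
  validate_cohort_config(cfg)
  modalities <- match.arg(modalities, several.ok = TRUE)
  ids <- c(sprintf("P%02d", seq_len(cfg$n_patients)),
           sprintf("H%02d", seq_len(cfg$n_healthy)))
  classes <- rep(c("tremor", "no_tremor"), c(cfg$n_patients, cfg$n_healthy))

  kinematics <- list()
  emg <- list()
  rows <- list()
  for (i in seq_along(ids)) {
    params <- draw_subject_params(cfg, classes[i], ids[i])
    for (tr in seq_len(cfg$n_trials)) {
      key <- sprintf("%s_t%02d", ids[i], tr)
      if ("kinematics" %in% modalities) {
        kinematics[[key]] <- simulate_kinematics(cfg, classes[i], ids[i],
                                                 trial = tr, params = params)
      }
      if ("emg" %in% modalities) {
        emg[[paste0(key, "_FCR")]] <- simulate_emg(cfg, classes[i], "FCR",
                                                   ids[i], tr, params)
        emg[[paste0(key, "_ECR")]] <- simulate_emg(cfg, classes[i], "ECR",
                                                   ids[i], tr, params)
      }
    }
    rows[[i]] <- data.frame(subject_id = ids[i], class = classes[i],
                            f_t = params$f_t, kin_amp_deg = params$kin_amp,
                            emg_depth = params$emg_depth,
                            f_physio = params$f_physio,
                            snr_db = cfg$snr_db)
  }
  structure(list(kinematics = kinematics, emg = emg,
                 manifest = do.call(rbind, rows), config = cfg),
            class = "tremor_cohort")
}

#' @export
print.tremor_cohort <- function(x, ...) {
  m <- x$manifest
  cat("Virtual tremor cohort:", sum(m$class == "tremor"), "patients,",
      sum(m$class == "no_tremor"), "controls;",
      x$config$n_trials, "trial(s) x", x$config$trial_duration, "s\n")
  cat("  kinematic streams:", length(x$kinematics),
      " EMG recordings:", length(x$emg), "\n")
  invisible(x)
}
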