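# End-to-end dataset construction: cohort -> preprocessed windows ->
# PSD-threshold labels -> balanced, normalized, split datasets per modality.

#' Build the labelled kinematics dataset from a cohort
#'
#' For every quaternion stream: convert to the wrist flexion-extension
#' angle, segment into 1-s windows (classifier inputs, unfiltered), and in
#' parallel band-pass the angle to 4-10 Hz and segment identically (the
#' labelling path). The threshold is calibrated on the no-tremor windows
#' and applied to all; windows are then normalized to [0, 1] over the whole
#' pooled dataset.
#'
#' @param cohort A `tremor_cohort` with kinematic streams.
#' @param quantile Threshold calibration quantile (default 0.99).
#' @param band Tremor band in Hz (default `c(4, 10)`).
#' @param label_from_filtered Use the band-passed angle for the PSD
#'   statistic (default TRUE); the classifier windows stay unfiltered.
#' @return A normalized `labeled_window_set` with the threshold attached.
#' @export
build_kinematics_dataset <- function(cohort, quantile = 0.99,
                                     band = c(4, 10),
                                     label_from_filtered = TRUE) {
  stopifnot(inherits(cohort, "tremor_cohort"), length(cohort$kinematics) > 0)
  raw_sets <- list()
  stat_sets <- list()
  for (key in names(cohort$kinematics)) {
    ang <- quaternions_to_wrist_angle(cohort$kinematics[[key]])
    raw_sets[[key]] <- segment_windows(ang)
    stat_sets[[key]] <- if (label_from_filtered) {
      segment_windows(bandpass_tremor(ang, band = band))
    } else {
      raw_sets[[key]]
    }
  }
  raw <- bind_window_sets(raw_sets)
  stat <- bind_window_sets(stat_sets)
  pk <- window_peak_powers(stat, band)
  th <- calibrate_threshold(pk[stat$design_label == "no_tremor"], quantile)
  lws <- label_windows(raw, th, stat_ws = stat, band = band)
  normalize_global(lws)
}

#' Build the labelled EMG datasets from a cohort
#'
#' For every accepted EMG recording: downsample to 510 Hz (raw-EMG
#' modality), extract the 4-10 Hz envelope at 50 Hz (envelope modality),
#' and segment both into time-aligned 1-s windows (510 and 50 samples).
#' Labels are derived from the envelope PSD peaks; raw windows inherit the
#' label of their aligned envelope window. Each modality is normalized to
#' [0, 1] independently (the units differ).
#'
#' @param cohort A `tremor_cohort` with EMG recordings.
#' @param quantile Threshold calibration quantile (default 0.99).
#' @param band Tremor band in Hz (default `c(4, 10)`).
#' @param snr_min_db Quality-screen acceptance threshold in dB (default 6);
#'   `NULL` skips screening.
#' @param raw_fs Raw-EMG modality rate in Hz (default 510).
#' @param envelope_fs Envelope modality rate in Hz (default 50).
#' @return A list with `raw` and `envelope` normalized
#'   `labeled_window_set`s, the shared `threshold`, and the `quality` report
#'   table.
#' @export
build_emg_datasets <- function(cohort, quantile = 0.99, band = c(4, 10),
                               snr_min_db = 6, raw_fs = 510,
                               envelope_fs = 50) {
  stopifnot(inherits(cohort, "tremor_cohort"), length(cohort$emg) > 0)
  raw_sets <- list()
  env_sets <- list()
  qc <- list()
  for (key in names(cohort$emg)) {
    rec <- cohort$emg[[key]]
    if (!is.null(snr_min_db)) {
      rep <- quality_screen(rec, snr_min_db)
      qc[[key]] <- data.frame(recording = key, subject = rep$subject_id,
                              channel = rep$channel,
                              snr_db = rep$snr_estimate_db,
                              clipping = rep$clipping,
                              accepted = rep$accepted)
      if (!rep$accepted) next
    }
    ds <- downsample_emg(rec, raw_fs)
    env <- emg_envelope(ds, band, envelope_fs)
    raw_sets[[key]] <- segment_windows(ds)
    env_sets[[key]] <- segment_windows(env)
  }
  if (!length(raw_sets)) stop("no EMG recording passed the quality screen")
  raw <- bind_window_sets(raw_sets)
  env <- bind_window_sets(env_sets)
  stopifnot(nrow(raw$x) == nrow(env$x))  # aligned 1-s windows
  pk <- window_peak_powers(env, band)
  th <- calibrate_threshold(pk[env$design_label == "no_tremor"], quantile)
  env_l <- label_windows(env, th, band = band)
  raw_l <- label_windows(raw, th, stat_ws = env, band = band)
  list(raw = normalize_global(raw_l), envelope = normalize_global(env_l),
       threshold = th,
       quality = if (length(qc)) do.call(rbind, c(qc, make.row.names = FALSE)) else NULL)
}

#' Train and evaluate all four classifier families on one modality
#'
#' Splits the balanced dataset (70/30 for the classical families, 70/15/15
#' for the LSTM), tunes KNN/SVM/RF by 10-fold cross-validated grid search,
#' trains the LSTM with validation checkpointing, and scores every model on
#' its held-out test partition.
#'
#' @param lws A balanced, normalized `labeled_window_set`.
#' @param modality Modality tag for the reports.
#' @param families Model families to run.
#' @param seed Integer seed (splits, folds, initialisation).
#' @param cv_folds Cross-validation folds for the classical families.
#' @param lstm_args List of arguments forwarded to [train_lstm()]
#'   (`hidden_size`, `learning_rate`, `epochs`, `batch_size`).
#' @return A list with `models`, `reports` (one `metrics_report` per
#'   family) and the `splits` used.
#' @export
evaluate_modality <- function(lws, modality,
                              families = c("knn", "svm", "rf", "lstm"),
                              seed = 1L, cv_folds = 10,
                              lstm_args = list()) {
  splits_ml <- split_windows(lws, "ml", seed = seed)
  splits_lstm <- split_windows(lws, "lstm", seed = seed)
  models <- list()
  reports <- list()
  for (fam in families) {
    if (fam == "lstm") {
      tr <- splits_lstm$train; vl <- splits_lstm$validation
      te <- splits_lstm$test
      model <- do.call(train_lstm, c(
        list(x_train = lws$x[tr, , drop = FALSE], y_train = lws$labels[tr],
             x_val = lws$x[vl, , drop = FALSE], y_val = lws$labels[vl],
             seed = seed), lstm_args))
      pred <- predict(model, lws$x[te, , drop = FALSE])
      truth <- lws$labels[te]
    } else {
      tr <- splits_ml$train; te <- splits_ml$test
      model <- tune_classical(fam, lws$x[tr, , drop = FALSE],
                              lws$labels[tr], k = cv_folds, seed = seed)
      pred <- predict(model, lws$x[te, , drop = FALSE])
      truth <- lws$labels[te]
    }
    models[[fam]] <- model
    reports[[fam]] <- classification_metrics(confusion_counts(truth, pred),
                                             model = fam,
                                             modality = modality)
  }
  list(models = models, reports = reports,
       splits = list(ml = splits_ml, lstm = splits_lstm))
}

#' Run the full tremor-detection study on synthetic cohorts
#'
#' Generates kinematic and EMG cohorts, builds the three balanced labelled
#' datasets (wrist angle, EMG envelope, raw EMG), trains the four
#' classifier families per modality and returns the comparison report.
#' Dataset sizes follow the study design (9000 windows per class for
#' kinematics, 4000 per class and EMG modality) unless scaled down.
#'
#' @param seed Master seed.
#' @param n_per_class_kin,n_per_class_emg Balanced dataset sizes per class.
#' @param kin_trials,emg_trials Trials per subject for the two cohorts:
#'   the defaults (14 and 4) are the smallest counts whose 60-s trials cover
#'   9000/4000 windows per class from 12 patients and 11 controls.
#' @param families Model families to run: a character vector applied to all
#'   modalities, or a named list with one vector per modality
#'   (`kinematics`, `envelope`, `raw_emg`).
#' @param lstm_args Arguments forwarded to [train_lstm()]; by default the
#'   kinematics and envelope sequences (50 steps) use 35 hidden units and
#'   the raw-EMG sequences (510 steps) use 20, at learning rate 0.005.
#' @param cohort_args Overrides forwarded to [cohort_config()].
#' @return A list: `datasets`, `results` (per modality), `comparison`.
#' @export
run_tremor_study <- function(seed = 1L, n_per_class_kin = 9000,
                             n_per_class_emg = 4000, kin_trials = 14,
                             emg_trials = 4,
                             families = c("knn", "svm", "rf", "lstm"),
                             lstm_args = NULL, cohort_args = list()) {
  cfg_kin <- do.call(cohort_config,
                     c(list(n_trials = kin_trials, seed = seed), cohort_args))
  cfg_emg <- do.call(cohort_config,
                     c(list(n_trials = emg_trials, seed = seed), cohort_args))
  kin_cohort <- generate_cohort(cfg_kin, "kinematics")
  emg_cohort <- generate_cohort(cfg_emg, "emg")

  kin <- assemble_balanced(build_kinematics_dataset(kin_cohort),
                           n_per_class_kin, seed = seed)
  emg <- build_emg_datasets(emg_cohort)
  env <- assemble_balanced(emg$envelope, n_per_class_emg, seed = seed)
  raw <- assemble_balanced(emg$raw, n_per_class_emg, seed = seed)

  datasets <- list(kinematics = kin, envelope = env, raw_emg = raw)
  results <- list()
  for (mod in names(datasets)) {
    fams <- if (is.list(families)) families[[mod]] else families
    if (!length(fams)) next
    args <- lstm_args
    if (is.null(args)) {
      # long raw-EMG sequences train at a smaller hidden size to keep
      # single-CPU BPTT time proportionate
      args <- if (mod == "raw_emg") list(hidden_size = 20) else
        list(hidden_size = 35)
    }
    results[[mod]] <- evaluate_modality(datasets[[mod]], mod,
                                        families = fams, seed = seed,
                                        lstm_args = args)
  }
  reports <- unlist(lapply(results, `[[`, "reports"), recursive = FALSE)
  list(datasets = datasets, results = results,
       comparison = compare_reports(unname(reports)))
}
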