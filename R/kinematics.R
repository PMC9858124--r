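# Kinematic preprocessing: quaternion streams -> wrist flexion-extension
# angle -> tremor-band filtering -> one-second windows -> [0, 1] scaling.

#' Wrist flexion-extension angle from a paired quaternion stream
#'
#' Computes the relative orientation `q_rel = conj(q_forearm) * q_hand` and
#' decomposes it with the intrinsic X-Y'-Z'' Euler sequence; flexion-
#' extension is the first rotation (about the forearm mediolateral axis),
#' returned in degrees. This is the exact inverse of the composition used by
#' [simulate_kinematics()].
#'
#' @param qs A `quaternion_stream`.
#' @return An `angle_series`: list with `angle` (degrees), `fs`,
#'   `subject_id`, `trial`, `design_label`.
#' @export
quaternions_to_wrist_angle <- function(qs) {
  stopifnot(inherits(qs, "quaternion_stream"))
  if (nrow(qs$hand_q) != nrow(qs$forearm_q)) {
    stop("hand and forearm streams must have equal length")
  }
  q_rel <- quat_multiply(quat_conjugate(qs$forearm_q), qs$hand_q)
  euler <- quat_to_euler_xyz(q_rel)
  structure(list(angle = euler$roll, fs = qs$fs, subject_id = qs$subject_id,
                 trial = qs$trial, design_label = qs$design_label),
            class = "angle_series")
}

# filtfilt with odd-reflection end padding (as Matlab/scipy do) so that the
# forward-backward pass is free of edge transients. padlen defaults to 3 s
# of signal, enough for the 4-10 Hz band-pass transient to die out.
filtfilt_padded <- function(filt, x, fs, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) padlen <- min(n - 1L, 3L * round(fs))
  if (n <= 15L) stop("input too short to pad and filter (need > 15 samples)")
  pre <- 2 * x[1] - x[(padlen + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - padlen)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[(padlen + 1):(padlen + n)]
}

#' Zero-lag tremor-band band-pass filter
#'
#' Second-order Butterworth band-pass (default 4-10 Hz) applied forward and
#' backward, so the net phase shift is zero and tremor peaks are not
#' displaced in time. Accepts an `angle_series`, a `signal_recording`, or a
#' bare numeric vector with `fs` supplied.
#'
#' @param x Input series.
#' @param fs Sampling rate in Hz (taken from the object if it carries one).
#' @param band Pass band in Hz (default `c(4, 10)`).
#' @param order Butterworth design order (default 2; the bidirectional pass
#'   doubles the effective roll-off).
#' @return Same type as the input, filtered; length preserved.
#' @export
bandpass_tremor <- function(x, fs = NULL, band = c(4, 10), order = 2) {
  if (inherits(x, "angle_series")) {
    x$angle <- bandpass_tremor(x$angle, x$fs, band, order)
    return(x)
  }
  if (inherits(x, "signal_recording")) {
    x$samples <- bandpass_tremor(x$samples, x$fs, band, order)
    return(x)
  }
  if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
  if (fs <= 2 * band[2]) stop("sampling rate must exceed twice the band top")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filtfilt_padded(bf, x, fs)
}

#' Segment a series into fixed-length windows
#'
#' Cuts consecutive non-overlapping windows of `window_seconds` (default
#' 1 s); a trailing remainder shorter than one window is discarded. An
#' `overlap` fraction in [0, 1) is accepted for streaming-oriented use.
#'
#' @param x An `angle_series`, `signal_recording`, or numeric vector.
#' @param window_seconds Window length in seconds (default 1).
#' @param overlap Fractional overlap between consecutive windows (default 0).
#' @param fs,modality,subject_id,design_label Metadata for bare vectors.
#' @return A `window_set`: `x` (n_windows x window_len matrix), `fs`,
#'   `window_len`, `modality`, and per-window `subject`, `trial`, `start`
#'   (1-based sample index) and `design_label`.
#' @export
segment_windows <- function(x, window_seconds = 1, overlap = 0, fs = NULL,
                            modality = "kinematic-angle",
                            subject_id = NA_character_,
                            design_label = NA_character_) {
  trial <- 1L
  if (inherits(x, "angle_series")) {
    fs <- x$fs; subject_id <- x$subject_id; design_label <- x$design_label
    trial <- x$trial; samples <- x$angle
  } else if (inherits(x, "signal_recording")) {
    fs <- x$fs; subject_id <- x$subject_id; design_label <- x$design_label
    modality <- x$modality; trial <- x$trial; samples <- x$samples
  } else {
    if (is.null(fs)) stop("fs must be supplied for a bare numeric series")
    samples <- as.numeric(x)
  }
  stopifnot(overlap >= 0, overlap < 1)
  wl <- round(fs * window_seconds)
  step <- max(1L, round(wl * (1 - overlap)))
  n <- length(samples)
  if (n < wl) {
    warning("series shorter than one window; returning an empty window set")
    starts <- integer(0)
  } else {
    starts <- seq(1L, n - wl + 1L, by = step)
  }
  w <- if (length(starts)) {
    t(vapply(starts, function(s) samples[s:(s + wl - 1L)], numeric(wl)))
  } else {
    matrix(numeric(0), 0, wl)
  }
  structure(list(x = w, fs = fs, window_len = wl, modality = modality,
                 subject = rep(subject_id, length(starts)),
                 trial = rep(trial, length(starts)),
                 start = starts,
                 design_label = rep(design_label, length(starts))),
            class = "window_set")
}

#' Bind window sets row-wise
#'
#' @param sets A list of `window_set` objects with identical `fs`,
#'   `window_len` and `modality`.
#' @return One combined `window_set` (labels concatenated if all inputs are
#'   labelled).
#' @export
bind_window_sets <- function(sets) {
  stopifnot(length(sets) >= 1)
  wl <- unique(vapply(sets, function(s) s$window_len, numeric(1)))
  fs <- unique(vapply(sets, function(s) s$fs, numeric(1)))
  mod <- unique(vapply(sets, function(s) s$modality, character(1)))
  stopifnot(length(wl) == 1, length(fs) == 1, length(mod) == 1)
  out <- structure(list(
    x = do.call(rbind, lapply(sets, `[[`, "x")),
    fs = fs, window_len = wl, modality = mod,
    subject = unlist(lapply(sets, `[[`, "subject"), use.names = FALSE),
    trial = unlist(lapply(sets, `[[`, "trial"), use.names = FALSE),
    start = unlist(lapply(sets, `[[`, "start"), use.names = FALSE),
    design_label = unlist(lapply(sets, `[[`, "design_label"),
                          use.names = FALSE)), class = "window_set")
  labs <- lapply(sets, function(s) s$labels)
  if (all(!vapply(labs, is.null, logical(1)))) {
    out$labels <- unlist(labs, use.names = FALSE)
    class(out) <- c("labeled_window_set", "window_set")
  }
  out
}

#' Min-max normalization to [0, 1]
#'
#' Maps amplitudes affinely so the pooled minimum goes to 0 and the pooled
#' maximum to 1. By default the statistics are taken over the whole window
#' set (global normalization across all subjects before splitting, which
#' leaks test amplitudes into training -- use `stats` computed on the
#' training pool to avoid that). Stored statistics can be re-applied to
#' held-out data; values outside the original range then fall outside
#' [0, 1] and are deliberately not clipped.
#'
#' @param ws A `window_set`.
#' @param stats Optional `c(min, max)` from a previous call; when `NULL`,
#'   computed from `ws` itself.
#' @return The normalized `window_set`, with the mapping stored in
#'   `$norm_stats`.
#' @export
normalize_global <- function(ws, stats = NULL) {
  stopifnot(inherits(ws, "window_set"))
  if (is.null(stats)) stats <- c(min = min(ws$x), max = max(ws$x))
  if (diff(range(stats)) <= 0) {
    stop("degenerate amplitude range: max must exceed min")
  }
  ws$x <- (ws$x - stats[[1]]) / (stats[[2]] - stats[[1]])
  ws$norm_stats <- stats
  ws
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<%s> %d windows of %d samples (%g Hz, %s)\n",
              paste(class(x), collapse = "/"), nrow(x$x), x$window_len,
              x$fs, x$modality))
  if (!is.null(x$labels)) {
    print(table(x$labels))
  }
  invisible(x)
}
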