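# Seeded generator of synthetic anesthetic EEG with ground-truth depth.
# The signal is a depth-weighted mixture of band-limited noises whose
# composition follows the classic anesthetic spectrum: broadband/beta
# activity awake, alpha/theta dominance under moderate anesthesia, and
# high-amplitude delta with burst suppression when deep. Its key
# contract is that windowed dispersion entropy decreases with depth.

#' Piecewise-linear ground-truth depth trajectory
#'
#' @param times Changepoint times in seconds (increasing, starting at 0).
#' @param values Depth index at each changepoint, in `[0, 100]`.
#' @return Object of class `depth_trajectory`.
#' @examples
#' tr <- depth_trajectory(c(0, 100, 200, 600), c(97.7, 97.7, 50, 50))
#' depth_at(tr, c(0, 150, 400))
#' @export
depth_trajectory <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2L)
    stop("`times` and `values` must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (times[1] != 0) stop("trajectory must start at time 0")
  if (any(values < 0 | values > 100)) stop("depth values must lie in [0, 100]")
  structure(list(times = as.numeric(times), values = as.numeric(values)),
            class = "depth_trajectory")
}

#' @export
print.depth_trajectory <- function(x, ...) {
  cat(sprintf("Depth trajectory: %d changepoints over %.0f s (range %.1f-%.1f)\n",
              length(x$times), max(x$times), min(x$values), max(x$values)))
  invisible(x)
}

#' Constant-depth trajectory
#' @param depth Depth index in `[0, 100]`.
#' @param duration_s Duration in seconds.
#' @return A [depth_trajectory()].
#' @export
constant_trajectory <- function(depth, duration_s) {
  depth_trajectory(c(0, duration_s), c(depth, depth))
}

#' Interpolate a trajectory at given times
#' @param traj A [depth_trajectory()].
#' @param t Times in seconds (clamped to the trajectory's span).
#' @return Depth index values.
#' @export
depth_at <- function(traj, t) {
  stopifnot(inherits(traj, "depth_trajectory"))
  stats::approx(traj$times, traj$values, xout = t, rule = 2)$y
}

#' Randomized surgical-course trajectory
#'
#' Awake baseline at 97.7, induction ramp, a moderate plateau, a deep
#' plateau, return to moderate and an emergence ramp; plateau depths and
#' changepoint times are jittered per subject so every cohort member has
#' its own course while always visiting all three states.
#'
#' @param duration_s Recording duration (>= 600 s recommended).
#' @param seed Integer seed.
#' @return A [depth_trajectory()].
#' @export
random_trajectory <- function(duration_s, seed = 1) {
  set.seed(seed)
  moderate <- stats::runif(1, 48, 62)
  deep <- stats::runif(1, 15, 30)
  # fractions of the recording spent in each phase, jittered
  f <- c(awake = 0.10, ramp1 = 0.06, mod1 = 0.18, ramp2 = 0.05,
         deep = 0.28, ramp3 = 0.05, mod2 = 0.15, emerge = 0.13)
  f <- f * stats::runif(length(f), 0.8, 1.2)
  f <- f / sum(f)
  times <- cumsum(c(0, f)) * duration_s
  times[length(times)] <- duration_s   # guard cumsum round-off
  vals <- c(97.7, 97.7, moderate, moderate, deep, deep, moderate,
            moderate, stats::runif(1, 85, 95))
  depth_trajectory(times, vals)
}

# depth -> band mixture weights (rows: samples)
band_weights <- function(d) {
  lgs <- function(x) 1 / (1 + exp(-x))
  cbind(broad = 0.25 + 0.5 * lgs((d - 80) / 10),
        beta  = lgs((d - 75) / 8),
        alpha = exp(-((d - 60) / 18)^2),
        theta = exp(-((d - 42) / 15)^2),
        delta = lgs((45 - d) / 10))
}

bandpass_noise <- function(n, fs, lo, hi, order = 2) {
  w <- stats::rnorm(n)
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  out <- signal::filtfilt(bf, w)
  out / stats::sd(out)
}

#' Generate a synthetic anesthetic EEG recording
#'
#' Synthesizes a single-channel EEG whose spectral composition follows
#' the given depth trajectory (see the package vignette for the mixture
#' model). Below depth 30 a burst-suppression envelope progressively
#' gates the signal. The per-second ground truth and a noisy BIS-like
#' reference track are attached; regeneration with the same arguments is
#' bit-identical.
#'
#' @param duration_s Recording duration in seconds (>= 120).
#' @param trajectory A [depth_trajectory()]; default
#'   `random_trajectory(duration_s, seed)`.
#' @param fs Sampling rate (default 128 Hz).
#' @param seed Integer seed.
#' @param amp_uv Base RMS amplitude in microvolts (default 30).
#' @param reference_noise_sd Noise sd of the simulated reference index
#'   (default 2.5).
#' @return An [eeg_recording()] of subclass `synth_recording`, carrying
#'   `truth_depth` (per second), `truth_state`, the trajectory, the
#'   generator parameters, and (initially empty) artifact annotations.
#' @examples
#' rec <- synth_eeg(180, constant_trajectory(97.7, 180), seed = 1)
#' rec
#' @export
synth_eeg <- function(duration_s, trajectory = NULL, fs = 128, seed = 1,
                      amp_uv = 30, reference_noise_sd = 2.5) {
  if (duration_s < 120) stop("duration must be at least 120 s")
  if (is.null(trajectory)) trajectory <- random_trajectory(duration_s, seed)
  stopifnot(inherits(trajectory, "depth_trajectory"))
  if (max(trajectory$times) < duration_s)
    stop("trajectory does not cover the recording duration")
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  d <- depth_at(trajectory, t)
  w <- band_weights(d)
  w <- w / rowSums(w)
  bands <- cbind(
    broad = stats::rnorm(n),
    beta  = bandpass_noise(n, fs, 13, 30),
    alpha = bandpass_noise(n, fs, 8, 12),
    theta = bandpass_noise(n, fs, 4, 8),
    delta = bandpass_noise(n, fs, 0.5, 4))
  x <- rowSums(w * bands)
  # amplitude rises as anesthesia deepens
  amp <- 1 + 1.2 / (1 + exp(-(50 - d) / 12))
  x <- x * amp
  # burst suppression below depth 30: a slowly varying uniform process
  # gates the signal with probability increasing toward depth 0
  p_supp <- 0.8 / (1 + exp(-(25 - d) / 6))
  if (any(p_supp > 0.01)) {
    slow <- bandpass_noise(n, fs, 0.05, 0.3)
    u <- stats::pnorm(slow)
    env <- ifelse(u < p_supp, 0.12, 1)
    # soften envelope edges
    env <- as.numeric(stats::filter(env, rep(1 / 9, 9), sides = 2))
    env[is.na(env)] <- 1
    x <- x * env
  }
  x <- x * amp_uv + stats::rnorm(n, sd = 0.05 * amp_uv)
  nsec <- floor(duration_s)
  truth <- depth_at(trajectory, seq_len(nsec))   # value at each second mark
  bis <- pmin(pmax(truth + stats::rnorm(nsec, sd = reference_noise_sd), 0), 100)
  rec <- eeg_recording(x, fs = fs, channel = "synthCh1",
                       bis = bis, sqi = rep(100, nsec))
  attr(rec, "truth_depth") <- truth
  rec$trajectory <- trajectory
  rec$truth_state <- classify_state(truth)
  rec$annotations <- data.frame(kind = character(), start_s = numeric(),
                                end_s = numeric(), amplitude = numeric())
  rec$generator <- list(seed = seed, duration_s = duration_s, fs = fs,
                        amp_uv = amp_uv,
                        reference_noise_sd = reference_noise_sd)
  class(rec) <- c("synth_recording", class(rec))
  rec
}

#' @export
print.synth_recording <- function(x, ...) {
  NextMethod()
  st <- table(x$truth_state)
  cat(sprintf("  synthetic truth: %s; %d artifact events\n",
              paste(sprintf("%s %ds", names(st), st), collapse = ", "),
              nrow(x$annotations)))
  invisible(x)
}

#' Inject artifacts into a recording
#'
#' Adds operating-room-style contamination: `ecg` (a ~1.1 Hz spike
#' train), `emg` (random high-frequency bursts) and `line50` (50 Hz mains
#' sinusoid). `rate` scales event density; `rate = 0` returns the
#' recording unchanged. Every injected epoch is recorded in the
#' `annotations` field.
#'
#' @param rec A `synth_recording` (or any [eeg_recording()]).
#' @param kinds Subset of `c("ecg", "emg", "line50")`.
#' @param rate Nonnegative event-density multiplier (default 1).
#' @param seed Integer seed.
#' @return The recording with artifacts added and annotations appended.
#' @export
inject_artifacts <- function(rec, kinds = c("ecg", "emg", "line50"),
                             rate = 1, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  unknown <- setdiff(kinds, c("ecg", "emg", "line50"))
  if (length(unknown))
    stop(sprintf("unknown artifact kind(s): %s", paste(unknown, collapse = ", ")))
  if (rate < 0) stop("`rate` must be nonnegative")
  if (rate == 0 || length(kinds) == 0L) return(rec)
  set.seed(seed)
  fs <- rec$fs
  n <- length(rec$samples)
  dur <- n / fs
  x <- rec$samples
  ann <- list()
  if ("ecg" %in% kinds) {
    # QRS-like biphasic template, ~80 ms wide, at ~1.1 Hz
    tt <- seq(-0.04, 0.04, by = 1 / fs)
    template <- 6 * rate * (-tt / 0.02) * exp(-(tt / 0.02)^2 / 2)
    beat <- 0
    while (beat < dur - 0.1) {
      beat <- beat + stats::rnorm(1, 0.9, 0.05)
      i0 <- round(beat * fs)
      idx <- i0 + seq_along(template)
      ok <- idx >= 1 & idx <= n
      x[idx[ok]] <- x[idx[ok]] + template[ok]
    }
    ann[[length(ann) + 1L]] <- data.frame(kind = "ecg", start_s = 0,
                                          end_s = dur, amplitude = 6 * rate)
  }
  if ("emg" %in% kinds) {
    n_bursts <- stats::rpois(1, rate * dur / 60)    # ~rate bursts per minute
    if (n_bursts > 0) {
      starts <- sort(stats::runif(n_bursts, 0, dur - 3))
      for (s in starts) {
        len_s <- stats::runif(1, 0.5, 3)
        i0 <- round(s * fs) + 1L
        i1 <- min(n, round((s + len_s) * fs))
        amp <- stats::runif(1, 8, 15)
        burst <- bandpass_noise(i1 - i0 + 1L, fs, 30, 60) * amp
        # taper the burst so it starts and ends smoothly
        k <- length(burst)
        taper <- sin(pi * (seq_len(k) - 0.5) / k)^2
        x[i0:i1] <- x[i0:i1] + burst * taper
        ann[[length(ann) + 1L]] <- data.frame(kind = "emg", start_s = s,
                                              end_s = s + len_s, amplitude = amp)
      }
    }
  }
  if ("line50" %in% kinds) {
    t <- (seq_len(n) - 1L) / fs
    amp <- 3 * rate
    x <- x + amp * sin(2 * pi * 50 * t + stats::runif(1, 0, 2 * pi))
    ann[[length(ann) + 1L]] <- data.frame(kind = "line50", start_s = 0,
                                          end_s = dur, amplitude = amp)
  }
  rec$samples <- x
  new_ann <- do.call(rbind, ann)
  rec$annotations <- rbind(rec$annotations, new_ann)
  rec
}

#' Simulate the signal-quality index and reference blanking
#'
#' Builds a per-second SQI track as 100 minus the instantaneous artifact
#' load (from the recording's annotations), then forces SQI below 15
#' inside the given dropout spans. Wherever SQI < 15 the simulated
#' reference index is blanked (`NA`), emulating a monitor that stops
#' displaying, while the ground truth stays defined.
#'
#' @param rec A `synth_recording`.
#' @param dropout_spans Optional two-column matrix / list of `c(start,
#'   end)` spans in seconds.
#' @return The recording with updated `sqi` and `bis` tracks.
#' @export
simulate_sqi <- function(rec, dropout_spans = NULL) {
  stopifnot(inherits(rec, "synth_recording"))
  nsec <- length(rec$sqi)
  if (!is.null(dropout_spans)) {
    if (is.list(dropout_spans)) dropout_spans <- do.call(rbind, dropout_spans)
    dropout_spans <- matrix(as.numeric(dropout_spans), ncol = 2)
    if (any(dropout_spans[, 2] <= dropout_spans[, 1]))
      stop("malformed dropout span (end <= start)")
    if (nrow(dropout_spans) > 1) {
      o <- order(dropout_spans[, 1])
      ds <- dropout_spans[o, , drop = FALSE]
      if (any(ds[-1, 1] < ds[-nrow(ds), 2])) stop("overlapping dropout spans")
    }
    if (any(dropout_spans < 0) || any(dropout_spans > nsec))
      stop("dropout span outside the recording duration")
  }
  # artifact load per second: sum of event amplitudes covering the second,
  # transient events weighted fully, continuous ones lightly
  load <- rep(0, nsec)
  if (nrow(rec$annotations) > 0) {
    for (i in seq_len(nrow(rec$annotations))) {
      a <- rec$annotations[i, ]
      secs <- seq(max(0, floor(a$start_s)), min(nsec - 1, ceiling(a$end_s) - 1))
      wgt <- if (a$kind %in% c("ecg", "line50")) 0.3 else 1.5
      load[secs + 1L] <- load[secs + 1L] + wgt * a$amplitude
    }
  }
  sqi <- pmax(20, pmin(100, 100 - load))
  if (!is.null(dropout_spans)) {
    for (i in seq_len(nrow(dropout_spans))) {
      secs <- seq(floor(dropout_spans[i, 1]), ceiling(dropout_spans[i, 2]) - 1)
      secs <- secs[secs >= 0 & secs < nsec]
      sqi[secs + 1L] <- 5
    }
  }
  rec$sqi <- sqi
  rec$bis[sqi < 15] <- NA_real_
  rec
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject randomized depth trajectories, amplitudes and artifact
#' loads; deterministic for a given `(n_subjects, seed)`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param seed Master seed.
#' @param duration_s Per-subject duration (default 1200 s).
#' @param artifact_rate Artifact density passed to [inject_artifacts()]
#'   (default 1).
#' @return List of `synth_recording` objects.
#' @export
make_cohort <- function(n_subjects, seed = 1, duration_s = 1200,
                        artifact_rate = 1) {
  if (n_subjects < 2) stop("a cohort needs at least 2 subjects")
  set.seed(seed)
  seeds <- matrix(sample.int(2^30, n_subjects * 3), nrow = 3)
  amps <- stats::runif(n_subjects, 25, 35)
  lapply(seq_len(n_subjects), function(i) {
    tr <- random_trajectory(duration_s, seed = seeds[1, i])
    rec <- synth_eeg(duration_s, trajectory = tr, seed = seeds[2, i],
                     amp_uv = amps[i])
    rec <- inject_artifacts(rec, rate = artifact_rate, seed = seeds[3, i])
    rec <- simulate_sqi(rec)
    rec$subject_id <- i
    rec
  })
}
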