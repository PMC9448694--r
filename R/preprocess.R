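#' Single-channel EEG recording
#'
#' Container for a sampled EEG trace with optional per-second reference
#' index (BIS-like, 0-100) and signal-quality index (SQI, 0-100) tracks.
#' The auxiliary tracks hold one value per whole second of signal; `NA`
#' marks seconds where the reference monitor blanked its output.
#'
#' @param samples Numeric vector of EEG samples (microvolts).
#' @param fs Sampling rate in Hz (default 128).
#' @param channel Channel label.
#' @param bis Optional per-second reference index, values in `[0, 100]`
#'   or `NA`.
#' @param sqi Optional per-second signal-quality index in `[0, 100]`.
#' @return Object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(rnorm(1280), fs = 128)
#' rec
#' @export
eeg_recording <- function(samples, fs = 128, channel = "Ch1",
                          bis = NULL, sqi = NULL) {
  if (!is.numeric(samples) || length(samples) < 1L)
    stop("`samples` must be a non-empty numeric vector")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  nsec <- floor(length(samples) / fs)
  check_track <- function(x, nm, allow_na = FALSE) {
    if (is.null(x)) return(NULL)
    if (abs(length(x) - nsec) > 1L)
      stop(sprintf("`%s` must hold one value per second of signal (%d +/- 1), got %d",
                   nm, nsec, length(x)))
    bad <- !is.na(x) & (x < 0 | x > 100)
    if (any(bad)) stop(sprintf("`%s` values must lie in [0, 100]", nm))
    if (!allow_na && anyNA(x)) stop(sprintf("`%s` must not contain NA", nm))
    as.numeric(x)
  }
  structure(list(samples = as.numeric(samples), fs = fs, channel = channel,
                 bis = check_track(bis, "bis", allow_na = TRUE),
                 sqi = check_track(sqi, "sqi")),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %s, %.1f s at %g Hz (%d samples)%s%s\n",
              x$channel, length(x$samples) / x$fs, x$fs, length(x$samples),
              if (!is.null(x$bis)) ", with reference index" else "",
              if (!is.null(x$sqi)) ", with SQI" else ""))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) length(rec$samples) / rec$fs

#' Read an EEG recording from CSV
#'
#' Expects columns `time_s` and `eeg_uv`, optionally `bis` and `sqi`.
#' Auxiliary tracks are stored per second: their column carries the
#' second's value on every sample row of that second (blank/`NA` where the
#' monitor showed nothing); the first row of each second is taken.
#'
#' @param path CSV file path.
#' @param fs Sampling rate; if `NULL`, inferred from the `time_s` column.
#' @param channel Channel label to attach.
#' @return An [eeg_recording()].
#' @export
read_eeg_csv <- function(path, fs = NULL, channel = "Ch1") {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "eeg_uv") %in% names(df)))
    stop("CSV must contain columns time_s and eeg_uv")
  if (is.null(fs)) {
    dt <- stats::median(diff(df$time_s))
    if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time_s")
    fs <- round(1 / dt)
  }
  sec <- floor(df$time_s + 1e-9)
  pick_track <- function(nm) {
    if (!nm %in% names(df)) return(NULL)
    nsec <- floor(nrow(df) / fs)
    vapply(seq_len(nsec) - 1L, function(s) {
      v <- df[[nm]][sec == s]
      if (length(v) == 0L) NA_real_ else v[1L]
    }, numeric(1))
  }
  eeg_recording(df$eeg_uv, fs = fs, channel = channel,
                bis = pick_track("bis"), sqi = pick_track("sqi"))
}

#' Write an EEG recording to CSV
#'
#' Inverse of [read_eeg_csv()]: one row per sample, per-second tracks
#' repeated across their second.
#'
#' @param rec An [eeg_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_eeg_csv <- function(rec, path) {
  n <- length(rec$samples)
  t <- (seq_len(n) - 1L) / rec$fs
  df <- data.frame(time_s = t, eeg_uv = rec$samples)
  expand_track <- function(x) {
    if (is.null(x)) return(NULL)
    idx <- floor(t) + 1L
    out <- rep(NA_real_, n)
    ok <- idx <= length(x)
    out[ok] <- x[idx[ok]]
    out
  }
  if (!is.null(rec$bis)) df$bis <- expand_track(rec$bis)
  if (!is.null(rec$sqi)) df$sqi <- expand_track(rec$sqi)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Denoise an EEG recording (wavelet + nonlocal means)
#'
#' Decomposes the signal with a periodized db4 wavelet transform, applies
#' nonlocal-means smoothing ([nlm_smooth()]) to the detail coefficients of
#' every level, and reconstructs. The NLM bandwidth is
#' `lambda = bandwidth_k * sigma_hat` with `sigma_hat` the robust noise
#' scale `MAD(d1)/0.6745` estimated from the finest detail level.
#'
#' @param rec An [eeg_recording()].
#' @param levels Wavelet decomposition depth (default 4).
#' @param wavelet Wavelet family; only `"db4"` is built in.
#' @param patch NLM patch half-width in coefficients (default 5).
#' @param search NLM search half-width in coefficients (default 50).
#' @param bandwidth_k Multiplier `k` on the robust noise scale (default 0.7).
#' @param bypass If `TRUE`, return the recording unchanged.
#' @return A denoised [eeg_recording()] of identical length.
#' @examples
#' set.seed(1)
#' rec <- eeg_recording(sin(2 * pi * 10 * (0:1279) / 128) + rnorm(1280))
#' den <- denoise_eeg(rec)
#' @export
denoise_eeg <- function(rec, levels = 4, wavelet = "db4",
                        patch = 5, search = 50, bandwidth_k = 0.7,
                        bypass = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (isTRUE(bypass)) return(rec)
  if (!identical(wavelet, "db4"))
    stop("only the db4 wavelet is built in")
  if (length(rec$samples) < 2^levels * length(DB4_LO))
    stop("signal shorter than the wavelet filter support at the requested depth")
  dec <- dwt_pyramid(rec$samples, levels = levels)
  sigma_hat <- stats::mad(dec$details[[1]])  # MAD / 0.6745
  lambda <- bandwidth_k * sigma_hat
  dec$details <- lapply(dec$details, nlm_smooth, h = lambda,
                        patch = patch, search = search)
  out <- rec
  out$samples <- idwt_pyramid(dec)
  out
}

#' Sliding-window segmentation
#'
#' Cuts the recording into overlapping windows of `window_s` seconds with
#' `overlap_s` seconds of overlap (step `window_s - overlap_s`). The
#' number of windows is `floor((duration - window_s)/step) + 1`; a
#' trailing partial window is discarded. Windows are labeled by both
#' their start and end times; downstream per-window values are reported
#' at the window's end time (what a monitor shows when the window
#' completes).
#'
#' @param rec An [eeg_recording()].
#' @param window_s Window length in seconds (default 56).
#' @param overlap_s Overlap in seconds (default 55).
#' @return An object of class `segment_set`: list with `starts` (sample
#'   indices), `start_times`, `end_times` (seconds), `window_len`
#'   (samples), `window_s`, `overlap_s`, `fs`, and the recording's
#'   `samples`.
#' @examples
#' rec <- eeg_recording(rnorm(60 * 128))
#' seg <- segment_eeg(rec)      # 5 windows of 7168 samples
#' seg$start_times
#' @export
segment_eeg <- function(rec, window_s = 56, overlap_s = 55) {
  stopifnot(inherits(rec, "eeg_recording"))
  step_s <- window_s - overlap_s
  if (step_s <= 0) stop("`overlap_s` must be smaller than `window_s`")
  dur <- duration_s(rec)
  if (dur < window_s)
    stop(sprintf("recording (%.1f s) shorter than one window (%g s)", dur, window_s))
  wlen <- round(window_s * rec$fs)
  step <- step_s * rec$fs
  nwin <- floor((dur - window_s) / step_s) + 1L
  start_times <- (seq_len(nwin) - 1L) * step_s
  starts <- round(start_times * rec$fs) + 1L
  # guard float accumulation at the tail
  keep <- starts + wlen - 1L <= length(rec$samples)
  structure(list(starts = starts[keep],
                 start_times = start_times[keep],
                 end_times = start_times[keep] + window_s,
                 window_len = wlen, window_s = window_s,
                 overlap_s = overlap_s, fs = rec$fs,
                 samples = rec$samples),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("Segment set: %d windows of %g s (%d samples), overlap %g s\n",
              length(x$starts), x$window_s, x$window_len, x$overlap_s))
  invisible(x)
}

#' Extract one window from a segment set
#' @param seg A [segment_eeg()] result.
#' @param i Window number.
#' @return Numeric vector of `seg$window_len` samples.
#' @export
segment_window <- function(seg, i) {
  stopifnot(inherits(seg, "segment_set"), i >= 1, i <= length(seg$starts))
  seg$samples[seg$starts[i] + 0:(seg$window_len - 1L)]
}

#' Per-window signal-quality mask
#'
#' A window is flagged poor-quality when any second it covers has
#' SQI below `threshold` (monitors blank their index below SQI 15).
#'
#' @param rec An [eeg_recording()] with an `sqi` track.
#' @param seg A [segment_eeg()] result aligned with `rec`.
#' @param threshold SQI threshold (default 15).
#' @return Logical vector, `TRUE` where the window is good quality.
#' @export
sqi_mask <- function(rec, seg, threshold = 15) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(seg, "segment_set"))
  if (is.null(rec$sqi)) stop("recording has no SQI track")
  vapply(seq_along(seg$starts), function(i) {
    secs <- seq(floor(seg$start_times[i]), ceiling(seg$end_times[i]) - 1L)
    secs <- secs[secs >= 0 & secs < length(rec$sqi)]
    all(rec$sqi[secs + 1L] >= threshold)
  }, logical(1))
}
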