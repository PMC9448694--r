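#' Hierarchical dispersion-entropy feature table
#'
#' Runs the full feature extractor over a recording: optional denoising,
#' sliding-window segmentation, and [hde()] on every window. Each row is
#' one analysis window; columns are the node entropies `L<layer>.N<node>`
#' of the `k`-layer decomposition followed by the per-layer means
#' `L<layer>.mean`. The reference index (when the recording carries one)
#' is attached per window at the window's end time.
#'
#' @param rec An [eeg_recording()].
#' @param k Decomposition layers (default 3: 15 node features + 4 level
#'   means).
#' @param params [de_params()] for the entropy computation.
#' @param window_s,overlap_s Segmentation, see [segment_eeg()].
#' @param stride Keep every `stride`-th window (1 = all). Coarser strides
#'   give an evaluation grid without the ~98% sample overlap of
#'   neighbouring windows.
#' @param denoise Apply [denoise_eeg()] first (default `TRUE`).
#' @param denoise_args List of arguments passed on to [denoise_eeg()].
#' @param sqi_threshold Threshold for the per-window quality flag when the
#'   recording has an SQI track.
#' @return A `feature_table`: data.frame of features with attributes
#'   `end_times`, `start_times`, `reference` (per-window reference index,
#'   `NA` where the monitor was blank), `sqi_ok` (logical, `NULL` without
#'   an SQI track), `truth` (per-window planted depth for synthetic
#'   recordings), `k`, `params`.
#' @examples
#' rec <- eeg_recording(rnorm(70 * 128))
#' ft <- extract_features(rec, denoise = FALSE)
#' dim(ft)
#' @export
extract_features <- function(rec, k = 3, params = de_params(),
                             window_s = 56, overlap_s = 55, stride = 1,
                             denoise = TRUE, denoise_args = list(),
                             sqi_threshold = 15) {
  stopifnot(inherits(rec, "eeg_recording"))
  truth_track <- attr(rec, "truth_depth")   # set by the synthetic generator
  if (denoise) rec <- do.call(denoise_eeg, c(list(rec), denoise_args))
  seg <- segment_eeg(rec, window_s = window_s, overlap_s = overlap_s)
  keep <- seq(1L, length(seg$starts), by = as.integer(stride))
  rows <- lapply(keep, function(i) {
    h <- hde(segment_window(seg, i), k = k, params = params)
    c(h$node_entropy, h$level_mean)
  })
  mat <- do.call(rbind, rows)
  df <- as.data.frame(mat)
  end_times <- seg$end_times[keep]
  track_at <- function(x) {
    if (is.null(x)) return(NULL)
    idx <- pmin(round(end_times), length(x))
    x[idx]
  }
  attr(df, "start_times") <- seg$start_times[keep]
  attr(df, "end_times") <- end_times
  attr(df, "reference") <- track_at(rec$bis)
  attr(df, "truth") <- track_at(truth_track)
  attr(df, "sqi_ok") <- if (!is.null(rec$sqi)) {
    m <- sqi_mask(rec, seg, threshold = sqi_threshold)
    m[keep]
  } else NULL
  attr(df, "k") <- k
  attr(df, "params") <- params
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Column labels of a feature table by kind
#'
#' @param ft A [extract_features()] table (or anything with the same
#'   naming scheme).
#' @param layer Restrict to node features of one layer (`NULL` = all
#'   features).
#' @param nodes_only Drop the per-layer mean columns.
#' @return Character vector of column names.
#' @export
feature_labels <- function(ft, layer = NULL, nodes_only = FALSE) {
  nm <- colnames(ft)
  if (nodes_only) nm <- nm[!grepl("\\.mean$", nm)]
  if (!is.null(layer)) nm <- nm[grepl(sprintf("^L%d\\.N", layer), nm)]
  nm
}

#' Write/read feature tables as CSV
#'
#' The CSV carries the window end time, the reference index, the quality
#' flag and the planted truth (when available) as leading columns.
#'
#' @param ft A feature table.
#' @param path CSV path.
#' @return `path` invisibly (write); a `feature_table` (read).
#' @export
write_feature_csv <- function(ft, path) {
  meta <- data.frame(end_time_s = attr(ft, "end_times"))
  if (!is.null(attr(ft, "reference"))) meta$reference <- attr(ft, "reference")
  if (!is.null(attr(ft, "truth"))) meta$truth <- attr(ft, "truth")
  if (!is.null(attr(ft, "sqi_ok"))) meta$sqi_ok <- attr(ft, "sqi_ok")
  utils::write.csv(cbind(meta, as.data.frame(ft)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta_cols <- intersect(c("end_time_s", "reference", "truth", "sqi_ok"), names(df))
  ft <- df[, setdiff(names(df), meta_cols), drop = FALSE]
  attr(ft, "end_times") <- df$end_time_s
  attr(ft, "reference") <- df$reference
  attr(ft, "truth") <- df$truth
  attr(ft, "sqi_ok") <- df$sqi_ok
  class(ft) <- c("feature_table", "data.frame")
  ft
}

# bind feature tables from several recordings, tracking subject ids
bind_feature_tables <- function(fts, ids = seq_along(fts)) {
  out <- do.call(rbind, lapply(fts, as.data.frame))
  grab <- function(nm) {
    vals <- lapply(fts, attr, nm)
    if (any(vapply(vals, is.null, logical(1)))) return(NULL)
    do.call(c, vals)
  }
  attr(out, "end_times") <- grab("end_times")
  attr(out, "reference") <- grab("reference")
  attr(out, "truth") <- grab("truth")
  attr(out, "sqi_ok") <- grab("sqi_ok")
  attr(out, "subject") <- rep(ids, vapply(fts, nrow, integer(1)))
  class(out) <- c("feature_table", "data.frame")
  out
}
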