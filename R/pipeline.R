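# Pipeline configuration, end-to-end model fitting/prediction, and the
# disk-artifact runner.

#' Pipeline configuration
#'
#' All tunable parameters of the monitoring pipeline, grouped by stage.
#' Call with nested overrides, e.g.
#' `pipeline_config(entropy = list(k = 2), seed = 7)`; unspecified keys
#' keep their defaults. The configuration hash
#' ([config_hash()]) is embedded in every artifact so that models,
#' feature tables and reports produced under different configurations are
#' never silently mixed.
#'
#' Defaults: 56 s windows with 55 s overlap at 128 Hz; db4/4-level
#' wavelet + NLM denoising; dispersion entropy with m = 3, c = 5,
#' tau = 1 over a k = 3 decomposition; feature-graph edge threshold 0.5;
#' LS-SVM gamma = 1, sigma = 1; state cut-points 80/40. Training rows
#' are thinned to one window per `train_stride_s` seconds (overlapping
#' windows share ~98% of their samples, so denser rows add conditioning
#' problems, not information).
#'
#' @param preprocess,entropy,graph,model,simulate Named lists of
#'   stage-specific overrides.
#' @param seed Global seed.
#' @return Object of class `pipeline_config` (a nested list).
#' @export
pipeline_config <- function(preprocess = list(), entropy = list(),
                            graph = list(), model = list(),
                            simulate = list(), seed = 1) {
  defaults <- list(
    preprocess = list(window_s = 56, overlap_s = 55, denoise = TRUE,
                      levels = 4, wavelet = "db4", patch = 5, search = 50,
                      bandwidth_k = 0.7, sqi_threshold = 15),
    entropy = list(m = 3, c = 5, tau = 1, k = 3),
    graph = list(edge_threshold = 0.5, phi = NULL, enabled = TRUE),
    model = list(gamma = 1, sigma = 1, train_stride_s = 60,
                 predict_stride_s = 1, feature_set = "selected",
                 cut_awake = 80, cut_deep = 40),
    simulate = list(duration_s = 1200, n_subjects = 18, artifact_rate = 1),
    seed = 1
  )
  cfg <- defaults
  cfg$preprocess <- utils::modifyList(cfg$preprocess, preprocess)
  cfg$entropy <- utils::modifyList(cfg$entropy, entropy)
  cfg$graph <- utils::modifyList(cfg$graph, graph, keep.null = TRUE)
  cfg$model <- utils::modifyList(cfg$model, model)
  cfg$simulate <- utils::modifyList(cfg$simulate, simulate)
  cfg$seed <- seed
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  p <- cfg$preprocess
  if (p$overlap_s >= p$window_s)
    stop("invalid config: preprocess.overlap_s must be smaller than preprocess.window_s")
  e <- cfg$entropy
  if (e$m < 2 || e$c < 2 || e$tau < 1 || e$k < 0)
    stop("invalid config: entropy parameters out of range")
  if (cfg$graph$edge_threshold < 0 || cfg$graph$edge_threshold > 1)
    stop("invalid config: graph.edge_threshold must lie in [0, 1]")
  if (cfg$model$gamma <= 0 || cfg$model$sigma <= 0)
    stop("invalid config: model.gamma and model.sigma must be positive")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration (hash", substr(config_hash(x), 1, 8), ")\n")
  utils::str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Configuration hash
#'
#' Stable hash of a [pipeline_config()]; stored in every model and
#' report, and checked before prediction so that artifacts from
#' different configurations refuse to mix.
#'
#' @param config A [pipeline_config()].
#' @return Character scalar.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

config_de_params <- function(config) {
  de_params(m = config$entropy$m, c = config$entropy$c, tau = config$entropy$tau)
}

# features for one recording under a config; stride in seconds
config_features <- function(rec, config, stride_s = NULL) {
  p <- config$preprocess
  step_s <- p$window_s - p$overlap_s
  stride <- if (is.null(stride_s)) 1L else max(1L, round(stride_s / step_s))
  extract_features(rec, k = config$entropy$k, params = config_de_params(config),
                   window_s = p$window_s, overlap_s = p$overlap_s,
                   stride = stride, denoise = isTRUE(p$denoise),
                   denoise_args = list(levels = p$levels, wavelet = p$wavelet,
                                       patch = p$patch, search = p$search,
                                       bandwidth_k = p$bandwidth_k),
                   sqi_threshold = p$sqi_threshold)
}

#' Fit the depth-of-anesthesia model on a training cohort
#'
#' Runs the full training pipeline on a list of recordings that carry a
#' reference index: denoise, segment, extract hierarchical
#' dispersion-entropy features (thinned to one window per
#' `model.train_stride_s` seconds), drop poor-quality and blanked
#' windows, select features on the community graph, then train an LS-SVM
#' regressor (features -> reference index) and a one-vs-rest LS-SVM
#' classifier (features -> state from the reference cut-points).
#'
#' `model.feature_set` chooses the columns: `"selected"` (graph
#' selection, default), `"all"`, or `"layerK"` (node features of one
#' decomposition layer, e.g. `"layer2"`).
#'
#' @param train_recs List of [eeg_recording()]s with `bis` tracks.
#' @param config A [pipeline_config()].
#' @param verbose Print per-stage progress.
#' @return Object of class `doa_model`: regression and classification
#'   [lssvm_train()] machines, the [select_features()] audit, the feature
#'   labels in use, the config and its hash.
#' @export
fit_doa_model <- function(train_recs, config = pipeline_config(),
                          verbose = FALSE) {
  stopifnot(is.list(train_recs), length(train_recs) >= 1L)
  say <- function(...) if (verbose) message(sprintf(...))
  say("extracting features from %d training recordings", length(train_recs))
  fts <- lapply(train_recs, config_features, config = config,
                stride_s = config$model$train_stride_s)
  fit_doa_from_features(bind_feature_tables(fts), config, say)
}

# fit from an already-extracted (bound) training feature table
fit_doa_from_features <- function(ft, config, say = function(...) NULL) {
  ref <- attr(ft, "reference")
  if (is.null(ref)) stop("training recordings must carry a reference index track")
  keep <- !is.na(ref)
  if (!is.null(attr(ft, "sqi_ok"))) keep <- keep & attr(ft, "sqi_ok")
  X <- as.data.frame(ft)[keep, , drop = FALSE]
  y <- ref[keep]
  say("training rows: %d of %d windows", nrow(X), nrow(ft))
  fset <- config$model$feature_set
  selection <- NULL
  if (identical(fset, "selected") && isTRUE(config$graph$enabled)) {
    selection <- select_features(X, edge_threshold = config$graph$edge_threshold,
                                 phi = config$graph$phi, seed = config$seed)
    labels <- selection$selected
  } else if (grepl("^layer[0-9]+$", fset)) {
    labels <- feature_labels(X, layer = as.integer(sub("layer", "", fset)))
    if (length(labels) == 0L) stop("no features at the requested layer")
  } else {
    labels <- colnames(X)
  }
  say("features in use: %s", paste(labels, collapse = ", "))
  Xs <- X[, labels, drop = FALSE]
  reg <- lssvm_train(Xs, y, gamma = config$model$gamma,
                     sigma = config$model$sigma, mode = "regression")
  states <- classify_state(y)
  cls <- if (length(unique(states)) >= 2) {
    lssvm_train(Xs, states, gamma = config$model$gamma,
                sigma = config$model$sigma, mode = "classification")
  } else NULL
  h <- config_hash(config)
  attr(reg, "config_hash") <- h
  if (!is.null(cls)) attr(cls, "config_hash") <- h
  structure(list(regression = reg, classifier = cls, selection = selection,
                 feature_labels = labels, config = config,
                 config_hash = h, n_train = nrow(Xs)),
            class = "doa_model")
}

#' @export
print.doa_model <- function(x, ...) {
  cat(sprintf("DoA model: %d training windows, %d features (%s)\n",
              x$n_train, length(x$feature_labels),
              x$config$model$feature_set))
  cat("  features:", paste(x$feature_labels, collapse = ", "), "\n")
  cat("  config hash:", substr(x$config_hash, 1, 8), "\n")
  invisible(x)
}

#' Predict the depth-of-anesthesia index for a recording
#'
#' Runs the trained pipeline over a recording and returns one index
#' value per analysis window, labeled by the window's end time and
#' clipped to `[0, 100]`. Prediction continues straight through
#' poor-signal-quality spans (the quality flag is reported, not used to
#' blank the output). The classifier's state call is attached when the
#' model has one.
#'
#' @param model A [fit_doa_model()] model.
#' @param rec An [eeg_recording()].
#' @param config Must match the model's configuration; defaults to it.
#'   A differing configuration is an error.
#' @param stride_s Evaluation grid in seconds (default
#'   `model$config$model$predict_stride_s`).
#' @return data.frame with columns `time_s`, `index`, `state`, `sqi_ok`
#'   (when the recording has an SQI track), `reference` and `truth`
#'   (when available).
#' @export
predict_index <- function(model, rec, config = NULL, stride_s = NULL) {
  stopifnot(inherits(model, "doa_model"))
  if (is.null(config)) config <- model$config
  if (!identical(config_hash(config), model$config_hash))
    stop("configuration mismatch: model was trained under a different config hash")
  if (duration_s(rec) < config$preprocess$window_s)
    stop("recording shorter than one analysis window")
  if (is.null(stride_s)) stride_s <- config$model$predict_stride_s
  ft <- config_features(rec, config, stride_s = stride_s)
  X <- as.data.frame(ft)[, model$feature_labels, drop = FALSE]
  idx <- pmin(pmax(predict(model$regression, X), 0), 100)
  out <- data.frame(time_s = attr(ft, "end_times"), index = idx)
  out$state <- if (!is.null(model$classifier)) predict(model$classifier, X)
               else classify_state(idx)
  if (!is.null(attr(ft, "sqi_ok"))) out$sqi_ok <- attr(ft, "sqi_ok")
  if (!is.null(attr(ft, "reference"))) out$reference <- attr(ft, "reference")
  if (!is.null(attr(ft, "truth"))) out$truth <- attr(ft, "truth")
  out
}

#' Subject-wise train/test benchmark on a cohort
#'
#' Splits a cohort by subject, fits the model on the training subjects
#' and evaluates on the held-out subjects: Pearson correlation and RMSE
#' of the predicted index against the planted truth, three-state accuracy
#' of the classifier against the truth states, and (optionally) the same
#' accuracy for models restricted to each single decomposition layer.
#'
#' @param cohort List of `synth_recording`s (see [make_cohort()]).
#' @param train_idx,test_idx Subject indices of the split.
#' @param config A [pipeline_config()].
#' @param layers Integer vector of layers for single-layer comparison
#'   models (`NULL` skips it).
#' @param stride_s Prediction grid on test subjects.
#' @param verbose Print progress.
#' @return List with `model`, `predictions` (per test subject),
#'   `report` (pooled [evaluate_index()] vs truth), `state_accuracy`,
#'   `layer_accuracy` (named by layer), `confusion`.
#' @export
doa_benchmark <- function(cohort, train_idx, test_idx,
                          config = pipeline_config(), layers = 0:3,
                          stride_s = 5, verbose = FALSE) {
  stopifnot(length(intersect(train_idx, test_idx)) == 0L)
  say <- function(...) if (verbose) message(sprintf(...))
  say("extracting features from %d training recordings", length(train_idx))
  train_ft <- bind_feature_tables(
    lapply(cohort[train_idx], config_features, config = config,
           stride_s = config$model$train_stride_s))
  model <- fit_doa_from_features(train_ft, config, say)
  # test features are extracted once per subject and reused across the
  # per-layer comparison models
  test_fts <- lapply(cohort[test_idx], config_features, config = config,
                     stride_s = stride_s)
  pred_from <- function(mdl, ft) {
    X <- as.data.frame(ft)[, mdl$feature_labels, drop = FALSE]
    idx <- pmin(pmax(predict(mdl$regression, X), 0), 100)
    data.frame(time_s = attr(ft, "end_times"), index = idx,
               state = predict(mdl$classifier, X),
               truth = attr(ft, "truth"),
               reference = attr(ft, "reference"))
  }
  preds <- lapply(test_fts, pred_from, mdl = model)
  pooled <- do.call(rbind, preds)
  report <- evaluate_index(pooled$index, pooled$truth)
  truth_state <- classify_state(pooled$truth)
  cls <- classification_report(truth_state, pooled$state)
  layer_acc <- NULL
  if (!is.null(layers)) {
    layer_acc <- vapply(layers, function(l) {
      cfg_l <- config
      cfg_l$model$feature_set <- sprintf("layer%d", l)
      mdl_l <- fit_doa_from_features(train_ft, cfg_l)
      pl <- do.call(rbind, lapply(test_fts, pred_from, mdl = mdl_l))
      classification_report(classify_state(pl$truth), pl$state)$accuracy
    }, numeric(1))
    names(layer_acc) <- sprintf("layer%d", layers)
  }
  list(model = model, predictions = preds, report = report,
       state_accuracy = cls$accuracy, confusion = cls$confusion,
       layer_accuracy = layer_acc)
}

#' Run the pipeline and write artifacts to disk
#'
#' One-call driver mirroring the CLI: simulates (or loads) recordings,
#' fits the model, predicts the held-out subjects and writes feature
#' tables (CSV), the selection audit (JSON), the feature graph (edge-list
#' CSV + GraphML), the model (JSON) and the evaluation report (JSON)
#' into `out_dir`. Every artifact embeds the configuration hash.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param recordings Optional list of recordings; defaults to a
#'   simulated cohort per `config$simulate`.
#' @param train_frac Fraction of subjects used for training (default
#'   2/3, subject-wise).
#' @param verbose Print progress.
#' @return Invisibly, the [doa_benchmark()] result with an
#'   `artifacts` element listing the files written.
#' @export
run_pipeline <- function(out_dir, config = pipeline_config(),
                         recordings = NULL, train_frac = 2 / 3,
                         verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.null(recordings)) {
    s <- config$simulate
    say("simulating %d subjects of %g s", s$n_subjects, s$duration_s)
    recordings <- make_cohort(s$n_subjects, seed = config$seed,
                              duration_s = s$duration_s,
                              artifact_rate = s$artifact_rate)
  }
  n <- length(recordings)
  n_train <- max(1L, round(train_frac * n))
  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_len(n), train_idx)
  if (length(test_idx) == 0L) stop("no held-out subjects; lower train_frac")
  say("training on subjects %s; testing on %s",
      paste(train_idx, collapse = ","), paste(test_idx, collapse = ","))
  bench <- doa_benchmark(recordings, train_idx, test_idx, config,
                         layers = NULL,
                         stride_s = config$model$predict_stride_s,
                         verbose = verbose)
  h <- config_hash(config)
  paths <- list()
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(unclass(config), list(hash = h)), cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  paths$config <- cfg_path
  paths$model <- file.path(out_dir, "model.json")
  save_lssvm(bench$model$regression, paths$model)
  if (!is.null(bench$model$selection)) {
    paths$audit <- file.path(out_dir, "selection_audit.json")
    jsonlite::write_json(list(config_hash = h, phi = bench$model$selection$phi,
                              selected = bench$model$selection$selected,
                              audit = bench$model$selection$audit),
                         paths$audit, auto_unbox = TRUE, digits = NA)
    paths$graph_edges <- file.path(out_dir, "feature_graph_edges.csv")
    write_edgelist_csv(bench$model$selection$graph, paths$graph_edges)
    paths$graphml <- file.path(out_dir, "feature_graph.graphml")
    write_graphml(bench$model$selection$graph, paths$graphml)
  }
  for (i in seq_along(test_idx)) {
    p <- file.path(out_dir, sprintf("predictions_subject%02d.csv", test_idx[i]))
    utils::write.csv(bench$predictions[[i]], p, row.names = FALSE)
    paths[[sprintf("predictions_%d", test_idx[i])]] <- p
  }
  paths$report <- file.path(out_dir, "report.json")
  rep <- bench$report
  attr(rep, "config_hash") <- h
  write_report_json(rep, paths$report)
  say("pooled test Pearson r = %.3f, state accuracy = %.3f",
      bench$report$pearson_r, bench$state_accuracy)
  bench$artifacts <- paths
  invisible(bench)
}
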