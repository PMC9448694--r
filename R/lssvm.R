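# Least-squares SVM with RBF kernel. Training reduces to one bordered
# linear system; regression and one-vs-rest classification share it.

#' Gaussian (RBF) kernel
#'
#' `k(a, b) = exp(-||a - b||^2 / (2 sigma^2))`.
#'
#' @param a,b Numeric feature rows of equal length.
#' @param sigma Kernel width, > 0 (default 1).
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(a, b, sigma = 1) {
  if (length(a) != length(b)) stop("feature rows differ in dimension")
  if (sigma <= 0) stop("`sigma` must be positive")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

# full kernel matrix between row sets (matrices, rows = observations)
rbf_kernel_matrix <- function(x, y = x, sigma = 1) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (sigma <= 0) stop("`sigma` must be positive")
  d2 <- outer(rowSums(x^2), rowSums(y^2), `+`) - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

#' Train a least-squares SVM
#'
#' Solves the LS-SVM dual system
#' \deqn{\begin{bmatrix} 0 & 1^T \\ 1 & K + I/\gamma \end{bmatrix}
#'       \begin{bmatrix} b \\ \alpha \end{bmatrix} =
#'       \begin{bmatrix} 0 \\ y \end{bmatrix}}
#' with RBF kernel matrix `K`. Prediction is
#' `f(x) = sum_i alpha_i k(x_i, x) + b`. For `mode = "classification"` a
#' one-vs-rest machine is trained per class on +/-1 targets and
#' prediction takes the argmax of the class scores.
#'
#' Features are z-scored with training-set statistics before the kernel
#' (the RBF width presumes comparable scales); the scaling is stored in
#' the model and reapplied at prediction.
#'
#' @param x Feature rows (matrix or data.frame, >= 2 rows).
#' @param y Targets: numeric (regression) or factor/character labels
#'   (classification).
#' @param gamma Regularization (default 1); larger fits closer.
#' @param sigma Kernel width (default 1).
#' @param mode `"regression"` or `"classification"` (default chosen from
#'   the type of `y`).
#' @param standardize Z-score features with training statistics
#'   (default `TRUE`).
#' @return Object of class `lssvm` with the support data, dual
#'   coefficients, bias(es) and scaling.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), 20, 2)
#' y <- x[, 1] + rnorm(20, sd = 0.1)
#' fit <- lssvm_train(x, y)
#' predict(fit, x)[1:3]
#' @export
lssvm_train <- function(x, y, gamma = 1, sigma = 1, mode = NULL,
                        standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  if (nrow(x) != length(y)) stop("rows of `x` and length of `y` differ")
  if (gamma <= 0) stop("`gamma` must be positive")
  if (is.null(mode))
    mode <- if (is.numeric(y)) "regression" else "classification"
  mode <- match.arg(mode, c("regression", "classification"))
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  n <- nrow(xs)
  K <- rbf_kernel_matrix(xs, sigma = sigma)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / gamma))
  solve_one <- function(t) {
    sol <- tryCatch(solve(A, c(0, t)),
                    error = function(e)
                      stop("singular LS-SVM system; add jitter to the features or lower gamma"))
    list(b = sol[1], alpha = sol[-1])
  }
  if (mode == "regression") {
    if (!is.numeric(y)) stop("regression targets must be numeric")
    fit <- solve_one(as.numeric(y))
    machines <- list(fit)
    classes <- NULL
  } else {
    yf <- factor(y)
    classes <- levels(yf)
    if (length(classes) < 2L) stop("classification needs >= 2 classes")
    machines <- lapply(classes, function(cl)
      solve_one(ifelse(yf == cl, 1, -1)))
    names(machines) <- classes
  }
  structure(list(x = xs, machines = machines, classes = classes,
                 gamma = gamma, sigma = sigma, mode = mode,
                 center = ctr, scale = scl,
                 feature_labels = colnames(x)),
            class = "lssvm")
}

#' @export
print.lssvm <- function(x, ...) {
  cat(sprintf("LS-SVM (%s): %d support rows, %d features, gamma = %g, sigma = %g\n",
              x$mode, nrow(x$x), ncol(x$x), x$gamma, x$sigma))
  if (!is.null(x$classes))
    cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' Predict from a trained LS-SVM
#'
#' @param object An [lssvm_train()] model.
#' @param newdata Feature rows; columns are matched by name when both
#'   sides are labeled.
#' @param type `"response"` (default: numeric prediction or class label)
#'   or `"score"` (classification: matrix of per-class scores).
#' @param ... Unused.
#' @return Numeric vector (regression), character vector of labels, or a
#'   score matrix.
#' @export
predict.lssvm <- function(object, newdata, type = c("response", "score"), ...) {
  type <- match.arg(type)
  nd <- as.matrix(newdata)
  if (!is.null(object$feature_labels) && !is.null(colnames(nd))) {
    if (!all(object$feature_labels %in% colnames(nd)))
      stop("newdata lacks the features the model was trained on")
    nd <- nd[, object$feature_labels, drop = FALSE]
  }
  if (ncol(nd) != ncol(object$x)) stop("feature dimension mismatch")
  nds <- sweep(sweep(nd, 2, object$center), 2, object$scale, "/")
  Kt <- rbf_kernel_matrix(nds, object$x, sigma = object$sigma)
  scores <- vapply(object$machines, function(mach)
    as.numeric(Kt %*% mach$alpha + mach$b), numeric(nrow(nds)))
  scores <- matrix(scores, nrow = nrow(nds))
  if (object$mode == "regression") return(scores[, 1])
  colnames(scores) <- object$classes
  if (type == "score") return(scores)
  object$classes[max.col(scores, ties.method = "first")]
}

#' Map a 0-100 depth index to an anesthetic state
#'
#' Clinical BIS convention: `awake` at 80 and above, `moderate` in
#' `[40, 80)`, `deep` below 40.
#'
#' @param index Numeric index values in `[0, 100]`.
#' @return Character vector over `c("awake", "moderate", "deep")`.
#' @examples
#' classify_state(c(97.7, 50, 39.99))
#' @export
classify_state <- function(index) {
  if (any(!is.na(index) & (index < 0 | index > 100)))
    stop("index values must lie in [0, 100]")
  out <- rep(NA_character_, length(index))
  out[!is.na(index) & index >= 80] <- "awake"
  out[!is.na(index) & index >= 40 & index < 80] <- "moderate"
  out[!is.na(index) & index < 40] <- "deep"
  out
}

#' State labels in display order
#' @return `c("awake", "moderate", "deep")`.
#' @export
state_levels <- function() c("awake", "moderate", "deep")

#' Save / load an LS-SVM model as JSON
#'
#' The JSON carries the support rows, dual coefficients, biases, kernel
#' parameters, scaling, feature labels and (when attached by the
#' pipeline) the configuration hash.
#'
#' @param model An [lssvm_train()] model.
#' @param path JSON file path.
#' @return `path` invisibly (save); an `lssvm` (load).
#' @export
save_lssvm <- function(model, path) {
  stopifnot(inherits(model, "lssvm"))
  obj <- list(
    mode = model$mode, gamma = model$gamma, sigma = model$sigma,
    classes = model$classes, feature_labels = model$feature_labels,
    center = model$center, scale = model$scale,
    x = model$x,
    machines = lapply(model$machines, function(m) list(b = m$b, alpha = m$alpha)),
    config_hash = attr(model, "config_hash")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lssvm
#' @export
load_lssvm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  machines <- if (is.data.frame(obj$machines)) {
    lapply(seq_len(nrow(obj$machines)), function(i)
      list(b = obj$machines$b[i], alpha = unlist(obj$machines$alpha[i])))
  } else {
    lapply(obj$machines, function(m) list(b = m$b, alpha = unlist(m$alpha)))
  }
  if (!is.null(obj$classes)) names(machines) <- obj$classes
  model <- structure(list(
    x = as.matrix(obj$x), machines = machines,
    classes = obj$classes, gamma = obj$gamma, sigma = obj$sigma,
    mode = obj$mode, center = obj$center, scale = obj$scale,
    feature_labels = obj$feature_labels), class = "lssvm")
  attr(model, "config_hash") <- obj$config_hash
  model
}
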