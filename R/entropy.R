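#' Dispersion-entropy parameters
#'
#' Bundles the three parameters of dispersion entropy: the embedding
#' dimension `m`, the number of quantization classes `c`, and the time
#' delay `tau` (in samples). Defaults follow the values commonly used for
#' anesthetic EEG (`m = 3`, `c = 5`, `tau = 1`), giving `c^m = 125`
#' possible dispersion patterns.
#'
#' @param m Embedding dimension (integer >= 2).
#' @param c Number of classes (integer >= 2).
#' @param tau Time delay in samples (integer >= 1).
#' @param ddof Degrees-of-freedom convention for the standard deviation in
#'   the normal-CDF mapping: 0 (population, the default) or 1 (sample).
#' @param normalize If `TRUE`, dispersion entropy is divided by its maximum
#'   `log(c^m)` so results lie in `[0, 1]`. Off by default (nats).
#' @return An object of class `de_params`.
#' @examples
#' de_params()
#' de_params(m = 2, c = 6, tau = 2)
#' @export
de_params <- function(m = 3, c = 5, tau = 1, ddof = 0, normalize = FALSE) {
  m <- as.integer(m); c <- as.integer(c); tau <- as.integer(tau)
  if (is.na(m) || m < 2L) stop("embedding dimension `m` must be an integer >= 2")
  if (is.na(c) || c < 2L) stop("class count `c` must be an integer >= 2")
  if (is.na(tau) || tau < 1L) stop("time delay `tau` must be an integer >= 1")
  if (!ddof %in% c(0, 1)) stop("`ddof` must be 0 (population) or 1 (sample)")
  if (c^m > 2^52) stop("c^m too large to enumerate dispersion patterns exactly")
  structure(list(m = m, c = c, tau = tau, ddof = ddof,
                 normalize = isTRUE(normalize)),
            class = "de_params")
}

#' @export
print.de_params <- function(x, ...) {
  cat(sprintf("Dispersion entropy parameters: m = %d, c = %d, tau = %d (%s sd%s)\n",
              x$m, x$c, x$tau, if (x$ddof == 0) "population" else "sample",
              if (x$normalize) ", normalized" else ""))
  invisible(x)
}

sd_pop <- function(x, ddof = 0) {
  n <- length(x)
  if (n < 2L) return(0)
  sqrt(sum((x - mean(x))^2) / (n - ifelse(ddof == 1, 1L, 0L)))
}

#' Normal-CDF mapping of a signal into (0, 1)
#'
#' Maps each sample through the cumulative normal distribution
#' `y_i = pnorm((x_i - mu) / sigma)` where `mu` and `sigma` are the mean
#' and standard deviation of the segment itself. The map is
#' order-preserving and invariant to positive affine transforms of the
#' input. A constant segment (zero sd) has no meaningful standardization;
#' all samples map to 0.5 and the result carries a `constant` attribute as
#' a flag.
#'
#' @param x Numeric vector, length >= 2.
#' @param ddof Standard-deviation convention (0 population, 1 sample).
#' @return Numeric vector strictly inside (0, 1), same length as `x`.
#' @examples
#' ncdf_map(c(-1, 0, 1))
#' @export
ncdf_map <- function(x, ddof = 0) {
  if (length(x) == 0L) stop("empty signal")
  if (length(x) < 2L) stop("need at least 2 samples to standardize")
  if (anyNA(x)) stop("signal contains NA")
  s <- sd_pop(x, ddof)
  if (s == 0) {
    y <- rep(0.5, length(x))
    attr(y, "constant") <- TRUE
    return(y)
  }
  y <- stats::pnorm(x, mean = mean(x), sd = s)
  # guard against exact 0/1 from extreme outliers in double precision
  eps <- .Machine$double.xmin
  pmin(pmax(y, eps), 1 - .Machine$double.eps)
}

#' Quantize CDF-mapped values into integer classes
#'
#' Linear transform `z_i = int(c * y_i + 0.5)` with `int` meaning
#' round-half-up, clamped to `[1, c]`.
#'
#' @param y Numeric vector with values in (0, 1).
#' @param c Number of classes.
#' @return Integer vector with values in `1..c`.
#' @examples
#' quantize_classes(c(0.001, 0.5, 0.999), c = 5)  # 1 3 5
#' @export
quantize_classes <- function(y, c = 5) {
  if (length(y) == 0L) stop("empty input")
  if (any(y <= 0 | y >= 1)) stop("values must lie strictly in (0, 1)")
  z <- floor(c * y + 1)          # round-half-up of (c*y + 0.5)
  as.integer(pmin(pmax(z, 1), c))
}

#' Delay-embed an integer class sequence
#'
#' Forms the `N - (m-1)*tau` embedding vectors
#' `(z_i, z_{i+tau}, ..., z_{i+(m-1)tau})` as rows of a matrix.
#'
#' @param z Integer class sequence.
#' @param params A [de_params()] object.
#' @return Integer matrix with `m` columns, one embedding vector per row.
#' @examples
#' de_embed(c(1, 2, 3, 4), de_params(m = 3, c = 5, tau = 1))
#' @export
de_embed <- function(z, params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  m <- params$m; tau <- params$tau
  need <- (m - 1L) * tau + 1L
  n <- length(z)
  if (n < need)
    stop(sprintf("signal too short to embed: length %d < minimum %d (m = %d, tau = %d)",
                 n, need, m, tau))
  nvec <- n - (m - 1L) * tau
  idx <- outer(seq_len(nvec), (seq_len(m) - 1L) * tau, `+`)
  matrix(z[idx], nrow = nvec, ncol = m)
}

# 1-based linear code of each pattern row: sum_j (z_j - 1) c^(j-1) + 1
pattern_codes <- function(emb, c) {
  nvec <- nrow(emb)
  code <- numeric(nvec)
  mult <- 1
  for (j in seq_len(ncol(emb))) {
    code <- code + (emb[, j] - 1) * mult
    mult <- mult * c
  }
  code + 1
}

#' Relative frequencies of dispersion patterns
#'
#' Counts each observed dispersion pattern among the embedding vectors and
#' divides by the number of vectors.
#'
#' @param emb Embedding matrix from [de_embed()], or an integer class
#'   sequence (then embedded first with `params`).
#' @param params A [de_params()] object.
#' @return An object of class `pattern_distribution`: a data.frame with
#'   columns `pattern` (dash-separated class labels) and `freq`, plus
#'   attributes `n_vectors` and `params`.
#' @export
pattern_distribution <- function(emb, params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  if (!is.matrix(emb)) emb <- de_embed(emb, params)
  if (nrow(emb) == 0L) stop("no embedding vectors")
  c <- params$c
  codes <- pattern_codes(emb, c)
  counts <- table(codes)
  code_vals <- as.numeric(names(counts))
  # decode linear code back into class labels
  lab <- vapply(code_vals, function(v) {
    v <- v - 1
    digits <- integer(params$m)
    for (j in seq_len(params$m)) {
      digits[j] <- v %% c + 1
      v <- v %/% c
    }
    paste(digits, collapse = "-")
  }, character(1))
  out <- data.frame(pattern = lab, freq = as.numeric(counts) / nrow(emb),
                    stringsAsFactors = FALSE)
  structure(out, n_vectors = nrow(emb), params = params,
            class = c("pattern_distribution", "data.frame"))
}

#' Dispersion entropy of a signal
#'
#' Shannon entropy (in nats) of the dispersion-pattern distribution: the
#' signal is mapped through the normal CDF of its own mean and standard
#' deviation, quantized into `c` classes, delay-embedded into `m`-tuples,
#' and the entropy `-sum L(pi) log L(pi)` of the pattern frequencies is
#' returned. Values lie in `[0, log(c^m)]`; a constant signal yields 0.
#'
#' @param x Numeric signal.
#' @param params A [de_params()] object.
#' @return Dispersion entropy in nats (or normalized to `[0,1]` when
#'   `params$normalize` is `TRUE`).
#' @examples
#' set.seed(1)
#' dispersion_entropy(rnorm(500))
#' dispersion_entropy(sin(2 * pi * (1:500) / 50))
#' @export
dispersion_entropy <- function(x, params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  y <- ncdf_map(x, params$ddof)
  if (isTRUE(attr(y, "constant"))) {
    # single pattern with frequency 1; still require embeddability
    need <- (params$m - 1L) * params$tau + 1L
    if (length(x) < need)
      stop(sprintf("signal too short to embed: length %d < minimum %d",
                   length(x), need))
    return(0)
  }
  z <- quantize_classes(y, params$c)
  emb <- de_embed(z, params)
  codes <- pattern_codes(emb, params$c)
  counts <- tabulate(codes, nbins = params$c^params$m)
  p <- counts[counts > 0L] / nrow(emb)
  h <- -sum(p * log(p))
  if (params$normalize) h <- h / (params$m * log(params$c))
  h
}

#' Binary hierarchical decomposition of a signal
#'
#' Recursively splits a signal into a low-frequency component (pairwise
#' averages `(x_{2j-1} + x_{2j}) / 2`) and a high-frequency component
#' (pairwise half-differences `(x_{2j-1} - x_{2j}) / 2`) over
#' non-overlapping sample pairs, down to `k` layers. Layer `l` holds
#' `2^l` components; the node index `v` in `[0, 2^l)` is the binary
#' encoding of the low/high operator choices from the root (0 = low,
#' 1 = high), so low children come first. On an odd-length component the
#' trailing sample is dropped (flagged via the `truncated` field).
#'
#' @param x Numeric signal, length >= `2^k`.
#' @param k Number of decomposition layers (integer >= 0).
#' @return An object of class `hier_tree`: a list of components, each a
#'   list with `layer`, `node`, `series`, `truncated`.
#' @examples
#' hier_decompose(c(2, 4, 6, 8), k = 1)
#' @export
hier_decompose <- function(x, k = 3) {
  k <- as.integer(k)
  if (is.na(k) || k < 0L) stop("`k` must be a non-negative integer")
  if (length(x) < 2^k)
    stop(sprintf("signal length %d < 2^k = %d", length(x), 2^k))
  comps <- vector("list", 2^(k + 1L) - 1L)
  comps[[1L]] <- list(layer = 0L, node = 0L, series = as.numeric(x),
                      truncated = FALSE)
  if (k > 0L) {
    pos <- 1L
    for (l in seq_len(k)) {
      for (v in seq_len(2^(l - 1L)) - 1L) {
        parent <- comps[[2^(l - 1L) - 1L + v + 1L]]
        s <- parent$series
        n <- length(s)
        trunc <- n %% 2L == 1L
        if (trunc) s <- s[-n]
        a <- s[seq(1L, length(s), by = 2L)]
        b <- s[seq(2L, length(s), by = 2L)]
        low  <- (a + b) / 2
        high <- (a - b) / 2
        comps[[2^l - 1L + 2L * v + 1L]] <-
          list(layer = l, node = 2L * v, series = low, truncated = trunc)
        comps[[2^l - 1L + 2L * v + 2L]] <-
          list(layer = l, node = 2L * v + 1L, series = high, truncated = trunc)
      }
    }
  }
  structure(list(k = k, components = comps), class = "hier_tree")
}

#' @export
print.hier_tree <- function(x, ...) {
  cat(sprintf("Hierarchical decomposition: %d layers, %d components, root length %d\n",
              x$k, length(x$components), length(x$components[[1]]$series)))
  invisible(x)
}

#' Hierarchical dispersion entropy
#'
#' Dispersion entropy of every node of the binary average/difference
#' decomposition tree, layers `0..k` (15 node entropies for `k = 3`),
#' together with the per-layer mean entropies ("level" features; 4 values
#' for `k = 3`).
#'
#' @param x Numeric signal.
#' @param k Number of decomposition layers.
#' @param params A [de_params()] object.
#' @return An object of class `hde`: list with `node_entropy` (named
#'   numeric vector, names `"L<layer>.N<node>"`), `level_mean` (named
#'   numeric vector `"L<layer>.mean"`), `k`, `params`.
#' @examples
#' set.seed(1)
#' h <- hde(rnorm(1024), k = 3)
#' length(h$node_entropy)  # 15
#' h$level_mean
#' @export
hde <- function(x, k = 3, params = de_params()) {
  tree <- hier_decompose(x, k)
  need <- (params$m - 1L) * params$tau + 1L
  vals <- vapply(tree$components, function(cmp) {
    if (length(cmp$series) < need)
      stop(sprintf("component at layer %d, node %d too short to embed (length %d < %d)",
                   cmp$layer, cmp$node, length(cmp$series), need))
    dispersion_entropy(cmp$series, params)
  }, numeric(1))
  layers <- vapply(tree$components, `[[`, integer(1), "layer")
  nodes <- vapply(tree$components, `[[`, integer(1), "node")
  names(vals) <- sprintf("L%d.N%d", layers, nodes)
  lev <- tapply(vals, layers, mean)
  level_mean <- as.numeric(lev)
  names(level_mean) <- sprintf("L%d.mean", as.integer(names(lev)))
  structure(list(node_entropy = vals, level_mean = level_mean,
                 k = k, params = params), class = "hde")
}

#' @export
print.hde <- function(x, ...) {
  cat(sprintf("Hierarchical dispersion entropy (k = %d, m = %d, c = %d, tau = %d)\n",
              x$k, x$params$m, x$params$c, x$params$tau))
  cat("Per-layer means (nats):\n")
  print(round(x$level_mean, 4))
  invisible(x)
}
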