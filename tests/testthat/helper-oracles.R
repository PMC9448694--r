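# Independent oracles used by the test-suite: a literal-enumeration
# dispersion entropy, an exhaustive modularity search, a closed-form
# kernel-ridge predictor, and a de Bruijn sequence generator for the
# uniform-pattern-occupancy construction.

# dispersion entropy recomputed step by step with string-keyed pattern
# counting; independent of the package's vectorized coding path
oracle_de <- function(x, m = 3, c = 5, tau = 1, ddof = 0) {
  mu <- mean(x)
  sigma <- sqrt(sum((x - mu)^2) / (length(x) - ddof))
  if (sigma == 0) return(0)
  y <- pnorm((x - mu) / sigma)
  z <- floor(c * y + 0.5 + 0.5)          # round-half-up of c*y + 0.5
  z <- pmin(pmax(z, 1), c)
  nvec <- length(z) - (m - 1) * tau
  pats <- character(nvec)
  for (i in seq_len(nvec)) {
    pats[i] <- paste(z[i + (0:(m - 1)) * tau], collapse = ",")
  }
  p <- as.numeric(table(pats)) / nvec
  -sum(p * log(p))
}

# all set partitions of n labeled items (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, maxid) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible())
    }
    for (cm in seq_len(maxid + 1L)) rec(c(assign, cm), max(maxid, cm))
  }
  rec(integer(0), 0L)
  out
}

# global modularity optimum by exhaustive search (feasible to n = 8)
oracle_best_modularity <- function(adj) {
  qs <- vapply(all_partitions(nrow(adj)),
               function(p) modularity_weighted(adj, p), numeric(1))
  list(q = max(qs), partition = all_partitions(nrow(adj))[[which.max(qs)]])
}

# kernel ridge regression with unpenalized intercept, two-step closed
# form: b = (1' A^-1 y) / (1' A^-1 1), alpha = A^-1 (y - b), A = K + I/gamma
oracle_krr_predict <- function(x, y, newx, gamma = 1, sigma = 1) {
  x <- as.matrix(x); newx <- as.matrix(newx)
  K <- exp(-as.matrix(dist(x))^2 / (2 * sigma^2))
  A <- K + diag(nrow(x)) / gamma
  Ainv_y <- solve(A, y)
  Ainv_1 <- solve(A, rep(1, nrow(x)))
  b <- sum(Ainv_y) / sum(Ainv_1)
  alpha <- solve(A, y - b)
  d2 <- outer(rowSums(newx^2), rowSums(x^2), `+`) - 2 * tcrossprod(newx, x)
  Kt <- exp(-pmax(d2, 0) / (2 * sigma^2))
  as.numeric(Kt %*% alpha + b)
}

# de Bruijn sequence over k symbols (0..k-1), order n; classic
# Lyndon-word concatenation. Returned 1-based (symbols 1..k).
de_bruijn <- function(k, n) {
  a <- integer(k * n + 1L)
  s <- integer(0)
  db <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) s <<- c(s, a[2:(p + 1L)])
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      db(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j <= k - 1L) {
        a[t + 1L] <<- j
        db(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  db(1L, 1L)
  s + 1L
}

# signal whose quantized class sequence visits every m-pattern equally
# often: a de Bruijn cycle over c classes unrolled once, mapped back
# through the inverse of the CDF/quantization step
uniform_pattern_signal <- function(m = 3, c = 5) {
  z <- de_bruijn(c, m)
  z <- c(z, z[seq_len(m - 1)])       # close the cycle linearly
  qnorm((z - 0.5) / c)
}

# two 4-cliques joined by one weak bridge: planted community structure
two_clique_adj <- function(w_bridge = 0.1) {
  adj <- matrix(0, 8, 8)
  adj[1:4, 1:4] <- 1
  adj[5:8, 5:8] <- 1
  diag(adj) <- 0
  adj[4, 5] <- adj[5, 4] <- w_bridge
  adj
}

# random symmetric weight matrix with sub-threshold edges removed, the
# kind of graph build_graph() produces
random_thresholded_adj <- function(n) {
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  w[w < 0.5] <- 0
  w
}

# deterministic per-test RNG scope
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
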