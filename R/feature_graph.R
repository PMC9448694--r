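# Community-graph feature selection: pairwise |Pearson| similarity,
# SoftMax scaling, thresholded weighted graph, Louvain communities,
# Laplacian-centrality x variance influence scores, iterative pruning.

#' Absolute Pearson similarity between two feature columns
#'
#' Pearson product-moment correlation taken in absolute value, so the
#' similarity lies in `[0, 1]` (1 = collinear, 0 = uncorrelated; strong
#' anti-correlation counts as similarity).
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Similarity in `[0, 1]`.
#' @examples
#' ppmcc(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
ppmcc <- function(a, b) {
  if (length(a) != length(b)) stop("feature columns differ in length")
  if (length(a) < 2L) stop("need at least 2 segments")
  if (sd_pop(a) == 0 || sd_pop(b) == 0)
    stop("constant feature: similarity undefined (zero variance)")
  abs(stats::cor(a, b))
}

#' Pairwise similarity matrix of a feature table
#'
#' @param ft Feature table (data.frame or matrix, segments x features).
#' @return Symmetric matrix of absolute Pearson correlations, unit
#'   diagonal.
#' @export
similarity_matrix <- function(ft) {
  m <- as.matrix(ft)
  if (ncol(m) < 2L) stop("need at least 2 features")
  sds <- apply(m, 2, sd_pop)
  if (any(sds == 0))
    stop(sprintf("constant feature column(s): %s",
                 paste(colnames(m)[sds == 0], collapse = ", ")))
  q <- abs(stats::cor(m))
  diag(q) <- 1
  q
}

#' SoftMax (logistic) scaling of a similarity matrix
#'
#' Rescales similarities through the logistic function
#' `1 / (1 + exp(-(Q - Qbar) / rho))` where `Qbar` and `rho` are the mean
#' and standard deviation of the off-diagonal similarities. Strictly
#' increasing, so it separates near-tied similarities without reordering
#' them. When all off-diagonal similarities are equal (`rho = 0`) every
#' entry maps to 0.5 with a warning.
#'
#' @param q Symmetric similarity matrix.
#' @return Matrix of the same shape with entries in (0, 1); the diagonal
#'   is mapped like any other entry and is ignored downstream.
#' @export
softmax_normalize <- function(q) {
  q <- as.matrix(q)
  if (nrow(q) != ncol(q) || max(abs(q - t(q))) > 1e-8)
    stop("similarity matrix must be symmetric")
  off <- q[row(q) != col(q)]
  qbar <- mean(off)
  rho <- sd_pop(off)
  if (rho == 0) {
    warning("all similarities equal; SoftMax scaling collapses to 0.5")
    out <- matrix(0.5, nrow(q), ncol(q), dimnames = dimnames(q))
    return(out)
  }
  1 / (1 + exp(-(q - qbar) / rho))
}

#' Build the weighted feature graph
#'
#' Undirected graph over features with an edge wherever the scaled
#' similarity reaches `edge_threshold` (default 0.5); edge weight is the
#' scaled similarity. Isolated nodes are allowed.
#'
#' @param qn Scaled similarity matrix from [softmax_normalize()].
#' @param edge_threshold Minimum weight to keep an edge (default 0.5).
#' @return Object of class `feature_graph`: list with `adj` (weighted
#'   adjacency, zero diagonal), `labels`, `edge_threshold`, and slots
#'   `community`/`influence` filled by later stages.
#' @export
build_graph <- function(qn, edge_threshold = 0.5) {
  qn <- as.matrix(qn)
  if (any(qn < 0 | qn > 1)) stop("scaled similarities must lie in [0, 1]")
  adj <- qn
  diag(adj) <- 0
  adj[adj < edge_threshold] <- 0
  labels <- colnames(qn)
  if (is.null(labels)) labels <- sprintf("f%d", seq_len(ncol(qn)))
  dimnames(adj) <- list(labels, labels)
  structure(list(adj = adj, labels = labels,
                 edge_threshold = edge_threshold,
                 community = NULL, influence = NULL),
            class = "feature_graph")
}

#' @export
print.feature_graph <- function(x, ...) {
  ne <- sum(x$adj[upper.tri(x$adj)] > 0)
  cat(sprintf("Feature graph: %d nodes, %d edges (threshold %.2f)\n",
              length(x$labels), ne, x$edge_threshold))
  if (!is.null(x$community))
    cat(sprintf("  communities: %d\n", length(unique(x$community))))
  invisible(x)
}

#' Weighted Newman-Girvan modularity of a partition
#'
#' `Q = sum_i [ e_ii/W - (a_i/W)^2 ]` over communities, with `e_ii` twice
#' the internal weight, `a_i` the community degree sum and `W` the total
#' weighted degree.
#'
#' @param adj Weighted adjacency matrix (zero diagonal).
#' @param membership Integer community id per node.
#' @return Modularity in `[-0.5, 1]`; 0 for an edgeless graph.
#' @export
modularity_weighted <- function(adj, membership) {
  w2 <- sum(adj)              # = 2 * total edge weight
  if (w2 == 0) return(0)
  degs <- rowSums(adj)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    q <- q + sum(adj[idx, idx]) / w2 - (sum(degs[idx]) / w2)^2
  }
  q
}

#' Louvain community detection (seeded, deterministic)
#'
#' Two-phase Louvain: greedy local moves maximizing weighted modularity
#' gain, then aggregation of communities into super-nodes, repeated until
#' no further modularity improvement, then a refinement sweep of original
#' nodes. The greedy moves depend on the visiting order and the starting
#' partition, so the procedure is multi-started: the first restart begins
#' from singletons (the classic start), later restarts from random
#' partitions, all drawn deterministically from the seed, and the
#' best-modularity result is kept (ties: first found; within a sweep,
#' ties break to the lowest community id). Results are fully reproducible
#' for a given seed.
#'
#' @param graph A [build_graph()] object (or bare adjacency matrix).
#' @param seed Integer seed for visiting orders and restart partitions.
#' @param n_restarts Number of seeded restarts (default 100).
#' @return List with `membership` (integer per node, 1-based consecutive),
#'   `modularity`.
#' @export
louvain_partition <- function(graph, seed = 1, n_restarts = 100) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cand <- louvain_single(graph, seed = seed + (r - 1L) * 7919L,
                           random_init = r > 1L)
    if (is.null(best) || cand$modularity > best$modularity + 1e-12)
      best <- cand
  }
  best
}

louvain_single <- function(graph, seed = 1, random_init = FALSE) {
  adj <- if (inherits(graph, "feature_graph")) graph$adj else as.matrix(graph)
  n <- nrow(adj)
  if (sum(adj) == 0) {
    return(list(membership = seq_len(n), modularity = 0))
  }
  # local RNG: the visiting order is seeded without touching the caller's state
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  # membership of original nodes in current super-nodes
  assign0 <- seq_len(n)
  cur <- adj
  init <- if (random_init) sample.int(n, n, replace = TRUE) else NULL
  repeat {
    ord <- sample.int(nrow(cur))
    loc <- louvain_local_with_selfloops(cur, ord, init = init)
    init <- NULL   # only the first level of the first pass uses it
    new_ids <- match(loc, sort(unique(loc)))
    assign0 <- new_ids[assign0]
    nc <- max(new_ids)
    if (nc == nrow(cur)) break
    # aggregate
    agg <- matrix(0, nc, nc)
    for (a in seq_len(nrow(cur))) for (b in seq_len(nrow(cur))) {
      agg[new_ids[a], new_ids[b]] <- agg[new_ids[a], new_ids[b]] + cur[a, b]
    }
    cur <- agg
  }
  membership <- match(assign0, sort(unique(assign0)))
  # refinement: local moves of original nodes from the coarse partition
  repeat {
    ord <- sample.int(n)
    refined <- louvain_local_with_selfloops(adj, ord, init = membership)
    refined <- match(refined, sort(unique(refined)))
    if (modularity_weighted(adj, refined) <=
        modularity_weighted(adj, membership) + 1e-12) break
    membership <- refined
  }
  list(membership = membership,
       modularity = modularity_weighted(adj, membership))
}

# Louvain inner loop where `adj` may carry self-loops (aggregated
# graphs); `init` seeds the starting membership (refinement sweeps).
louvain_local_with_selfloops <- function(adj, order, init = NULL) {
  n <- nrow(adj)
  member <- if (is.null(init)) seq_len(n) else as.integer(init)
  self_w <- diag(adj)
  off <- adj; diag(off) <- 0
  degs <- rowSums(off) + self_w          # weighted degree incl. self-loop
  w2 <- sum(off) + sum(self_w)           # 2 * total weight
  if (w2 == 0) return(member)
  repeat {
    moved <- FALSE
    for (i in order) {
      cm_i <- member[i]
      nb <- which(off[i, ] > 0)
      member[i] <- 0L
      active <- member != 0L
      comm_tot <- if (any(active)) tapply(degs[active], member[active], sum) else numeric(0)
      # candidates: neighbouring communities, the current one, and a fresh
      # singleton community (gain 0 reference)
      fresh <- max(member, cm_i) + 1L
      cand <- unique(c(member[nb], cm_i, fresh))
      cand <- cand[cand != 0L]
      if (length(cand) == 0L) { member[i] <- cm_i; next }
      k_in <- vapply(cand, function(cm) sum(off[i, nb[member[nb] == cm]]), numeric(1))
      tot <- comm_tot[as.character(cand)]
      tot[is.na(tot)] <- 0
      # gain of joining community cm: 2 k_in / w2 - 2 deg_i tot / w2^2
      gain <- 2 * k_in / w2 - 2 * degs[i] * tot / (w2^2)
      best <- max(gain)
      pick <- min(cand[gain > best - 1e-12])
      stay <- gain[match(cm_i, cand)]
      if (is.na(stay)) stay <- -Inf
      if (best > stay + 1e-12) { member[i] <- pick; moved <- TRUE }
      else member[i] <- cm_i
    }
    if (!moved) break
  }
  member
}

# modularity on a graph that may carry self-loops (aggregated level)
modularity_weighted_selfloops <- function(adj, membership) {
  w2 <- sum(adj)
  if (w2 == 0) return(0)
  off <- adj; diag(off) <- 0
  degs <- rowSums(off) + diag(adj)
  q <- 0
  for (cm in unique(membership)) {
    idx <- membership == cm
    q <- q + (sum(off[idx, idx]) + sum(diag(adj)[idx])) / w2 -
      (sum(degs[idx]) / w2)^2
  }
  q
}

#' Laplacian centrality of every node
#'
#' Laplacian energy of a weighted graph is
#' `E(G) = sum_i d_i^2 + 2 sum_{i<j} w_ij^2` with `d_i` the weighted
#' degrees. A node's centrality is the relative energy drop when it is
#' removed: `(E(G) - E(G - v)) / E(G)`. On a single-node or zero-energy
#' graph the centrality is defined as 1.
#'
#' @param graph A [build_graph()] object or adjacency matrix.
#' @return Numeric vector of centralities, named by node label.
#' @export
laplacian_centrality <- function(graph) {
  adj <- if (inherits(graph, "feature_graph")) graph$adj else as.matrix(graph)
  n <- nrow(adj)
  labels <- rownames(adj)
  if (n == 1L) return(stats::setNames(1, labels))
  energy <- function(a) sum(rowSums(a)^2) + 2 * sum(a[upper.tri(a)]^2)
  e_full <- energy(adj)
  if (e_full == 0) return(stats::setNames(rep(1, n), labels))
  cent <- vapply(seq_len(n), function(v) {
    (e_full - energy(adj[-v, -v, drop = FALSE])) / e_full
  }, numeric(1))
  stats::setNames(cent, labels)
}

#' Influence score of each feature node
#'
#' `inf(f) = LaplacianCentrality(f) * NormVar(f)` where `NormVar` is the
#' population variance of the feature across segments. A feature that is
#' either peripheral in the similarity graph or nearly constant across
#' segments scores low.
#'
#' @param graph A [build_graph()] object whose nodes match columns of
#'   `ft`.
#' @param ft Feature table (segments x features).
#' @return Named numeric vector of influence scores.
#' @export
influence_scores <- function(graph, ft) {
  stopifnot(inherits(graph, "feature_graph"))
  m <- as.matrix(ft)[, graph$labels, drop = FALSE]
  cent <- laplacian_centrality(graph)
  nv <- apply(m, 2, function(col) mean((col - mean(col))^2))
  cent * nv
}

#' Community-graph feature selection
#'
#' The full selection loop: build the scaled-similarity graph, detect
#' Louvain communities, score each feature's influence
#' ([influence_scores()]), drop every feature scoring below the threshold
#' `phi` — except each community's top-influence feature, which is
#' protected as the community representative (ties break to the first
#' label) — then rebuild and repeat until no unprotected feature falls
#' below `phi`. The protection is what collapses a group of redundant
#' (duplicated) features to a single survivor instead of deleting the
#' whole group. By default `phi` is the 25th percentile of the first
#' iteration's influence scores and is then held fixed across
#' iterations.
#'
#' @param ft Feature table (segments x features), >= 2 features.
#' @param edge_threshold Graph edge threshold (default 0.5).
#' @param phi Influence threshold; `NULL` (default) uses the 25th
#'   percentile of the initial scores. `phi = 0` keeps everything.
#' @param seed Seed for the Louvain node order.
#' @param max_iter Safety cap on pruning iterations.
#' @return Object of class `feature_selection`: list with `selected`
#'   (surviving labels), `phi`, `graph` (final annotated
#'   [build_graph()] object), `audit` (per-iteration data.frames of
#'   labels, community, influence, dropped).
#' @examples
#' set.seed(2)
#' ft <- as.data.frame(matrix(rnorm(200), 20, 10))
#' sel <- select_features(ft, phi = 0)
#' sel$selected
#' @export
select_features <- function(ft, edge_threshold = 0.5, phi = NULL,
                            seed = 1, max_iter = NULL) {
  m <- as.data.frame(ft)
  if (ncol(m) < 2L) stop("need at least 2 features to select among")
  if (is.null(max_iter)) max_iter <- ncol(m)
  audit <- list()
  current <- colnames(m)
  phi_fixed <- phi
  final_graph <- NULL
  for (it in seq_len(max_iter)) {
    sub <- m[, current, drop = FALSE]
    if (ncol(sub) < 2L) break
    qn <- softmax_normalize(similarity_matrix(sub))
    g <- build_graph(qn, edge_threshold = edge_threshold)
    part <- louvain_partition(g, seed = seed)
    g$community <- stats::setNames(part$membership, g$labels)
    inf <- influence_scores(g, sub)
    g$influence <- inf
    if (is.null(phi_fixed)) phi_fixed <- unname(stats::quantile(inf, 0.25))
    # community representatives (top influence, first label on ties) are kept
    protected <- unlist(lapply(split(names(inf), g$community[names(inf)]),
                               function(nm) nm[which.max(inf[nm])]))
    drop <- setdiff(names(inf)[inf < phi_fixed], protected)
    audit[[it]] <- data.frame(iteration = it, feature = names(inf),
                              community = as.integer(g$community),
                              influence = unname(inf),
                              dropped = names(inf) %in% drop,
                              row.names = NULL)
    final_graph <- g
    if (length(drop) == 0L) break
    if (length(drop) == length(current))
      stop("all features fall below phi; lower the influence threshold")
    current <- setdiff(current, drop)
  }
  structure(list(selected = current, phi = phi_fixed, graph = final_graph,
                 audit = do.call(rbind, audit), seed = seed,
                 edge_threshold = edge_threshold),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("Feature selection: %d features kept (phi = %.4g, %d iteration%s)\n",
              length(x$selected), x$phi, max(x$audit$iteration),
              if (max(x$audit$iteration) > 1) "s" else ""))
  cat("  ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Export a feature graph
#'
#' `write_edgelist_csv()` writes `from,to,weight`; `write_graphml()`
#' writes a minimal GraphML document with community and influence node
#' attributes when present.
#'
#' @param graph A [build_graph()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(graph, path) {
  stopifnot(inherits(graph, "feature_graph"))
  idx <- which(upper.tri(graph$adj) & graph$adj > 0, arr.ind = TRUE)
  df <- data.frame(from = graph$labels[idx[, 1]],
                   to = graph$labels[idx[, 2]],
                   weight = graph$adj[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist_csv
#' @export
write_graphml <- function(graph, path) {
  stopifnot(inherits(graph, "feature_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    '  <key id="c" for="node" attr.name="community" attr.type="int"/>',
    '  <key id="inf" for="node" attr.name="influence" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (i in seq_along(graph$labels)) {
    lab <- graph$labels[i]
    extra <- ""
    if (!is.null(graph$community))
      extra <- paste0(extra, sprintf('<data key="c">%d</data>', graph$community[[lab]]))
    if (!is.null(graph$influence))
      extra <- paste0(extra, sprintf('<data key="inf">%.10g</data>', graph$influence[[lab]]))
    writeLines(sprintf('    <node id="%s">%s</node>', lab, extra), con)
  }
  idx <- which(upper.tri(graph$adj) & graph$adj > 0, arr.ind = TRUE)
  if (nrow(idx))
    writeLines(sprintf('    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
                       graph$labels[idx[, 1]], graph$labels[idx[, 2]],
                       graph$adj[idx]), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
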