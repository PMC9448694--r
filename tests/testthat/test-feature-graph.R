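test_that("absolute-correlation similarity behaves as a similarity", {
  a <- c(1, 2, 3, 4)
  expect_equal(ppmcc(a, a), 1)
  expect_equal(ppmcc(a, -a), 1)           # anti-correlation counts as similar
  expect_equal(ppmcc(a, c(1, 3, 2, 4)), 0.8)
  expect_error(ppmcc(a, rep(2, 4)), "constant")
  expect_error(ppmcc(a, 1:5), "length")
  m <- with_seed(1, matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c"))))
  q <- similarity_matrix(m)
  expect_true(isSymmetric(q))
  expect_equal(unname(diag(q)), rep(1, 3))
  expect_equal(q["a", "b"], ppmcc(m[, "a"], m[, "b"]))
})

test_that("SoftMax scaling is a centred logistic, hence order-preserving", {
  q <- with_seed(2, {
    m <- matrix(runif(25), 5, 5)
    q <- (m + t(m)) / 2; diag(q) <- 1; q
  })
  qn <- softmax_normalize(q)
  off <- q[row(q) != col(q)]
  qbar <- mean(off)
  rho <- sqrt(mean((off - mean(off))^2))
  # every entry follows the centred logistic of the off-diagonal moments
  expect_equal(qn, 1 / (1 + exp(-(q - qbar) / rho)), tolerance = 1e-12)
  # analytic points: off-diagonals symmetric around 0.5 give mean 0.5 and
  # population sd sqrt(4 * 0.15^2 / 12) = sqrt(0.0075)
  qa <- matrix(0.5, 4, 4)
  qa[1, 2] <- qa[2, 1] <- 0.35
  qa[3, 4] <- qa[4, 3] <- 0.65
  diag(qa) <- 1
  qna <- softmax_normalize(qa)
  expect_equal(qna[1, 3], 0.5)                        # entry at the mean
  expect_equal(qna[3, 4], 1 / (1 + exp(-0.15 / sqrt(0.0075))))
  # a unit standardized deviation maps to the logistic of 1
  expect_equal(1 / (1 + exp(-(qbar + rho - qbar) / rho)), 1 / (1 + exp(-1)))
  # monotonicity: sorting is preserved
  expect_equal(order(qn[row(qn) != col(qn)]), order(off))
  # degenerate: all similarities equal
  q4 <- matrix(0.7, 3, 3); diag(q4) <- 1
  expect_warning(qn4 <- softmax_normalize(q4), "equal")
  expect_true(all(qn4 == 0.5))
})

test_that("graph construction applies the edge threshold", {
  qn <- matrix(c(1, .9, .1, .2,
                 .9, 1, .2, .1,
                 .1, .2, 1, .8,
                 .2, .1, .8, 1), 4, 4,
               dimnames = rep(list(c("a", "b", "c", "d")), 2))
  g <- build_graph(qn, edge_threshold = 0.5)
  expect_equal(sum(g$adj > 0) / 2, 2)               # two 2-cliques
  expect_equal(g$adj["a", "b"], 0.9)
  expect_equal(g$adj["a", "c"], 0)
  expect_equal(sum(build_graph(qn, 0)$adj > 0) / 2, 6)    # complete
  expect_equal(sum(build_graph(qn, 1 + 1e-9)$adj > 0), 0) # empty
})

test_that("Louvain recovers planted cliques and beats singleton partitions", {
  adj <- two_clique_adj()
  part <- louvain_partition(adj, seed = 3)
  expect_length(unique(part$membership), 2L)
  expect_length(unique(part$membership[1:4]), 1L)
  expect_length(unique(part$membership[5:8]), 1L)
  # exhaustive search confirms this optimum on 8 nodes
  best <- oracle_best_modularity(adj)
  expect_equal(part$modularity, best$q, tolerance = 1e-12)
  # single clique collapses to one community
  clique <- matrix(1, 5, 5); diag(clique) <- 0
  expect_length(unique(louvain_partition(clique, seed = 1)$membership), 1L)
  # optimization contract: better than all-singletons whenever edges exist
  with_seed(4, {
    for (rep in 1:10) {
      adj <- random_thresholded_adj(sample(4:8, 1))
      if (sum(adj) == 0) next
      part <- louvain_partition(adj, seed = rep)
      expect_gt(part$modularity,
                modularity_weighted(adj, seq_len(nrow(adj))) - 1e-12)
    }
  })
  # edgeless graph: all singletons, modularity 0
  p0 <- louvain_partition(matrix(0, 4, 4), seed = 1)
  expect_equal(p0$membership, 1:4)
  expect_equal(p0$modularity, 0)
})

test_that("modularity agrees with igraph on shared partitions", {
  skip_if_not_installed("igraph")
  with_seed(5, {
    for (rep in 1:5) {
      adj <- random_thresholded_adj(7)
      if (sum(adj) == 0) next
      part <- louvain_partition(adj, seed = rep)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                               weighted = TRUE)
      expect_equal(part$modularity,
                   igraph::modularity(g, part$membership,
                                      weights = igraph::E(g)$weight),
                   tolerance = 1e-12)
    }
  })
})

test_that("Laplacian centrality matches hand-computed energy drops", {
  # path graph 1-2-3, unit weights: E = 1^2+2^2+1^2 + 2*(1+1) = 10;
  # removing an end leaves E = 4 (drop 6), removing the middle leaves 0
  path <- matrix(0, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1
  expect_equal(unname(laplacian_centrality(path)), c(0.6, 1.0, 0.6))
  # star: hub more central than leaves
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  cent <- laplacian_centrality(star)
  expect_true(all(cent[1] > cent[2:5]))
  expect_equal(unname(laplacian_centrality(matrix(0, 1, 1))), 1)
})

test_that("influence couples centrality with cross-segment variance", {
  ft <- with_seed(6, data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30)))
  ft$d <- ft$a + rnorm(30, sd = 0.01)      # near-duplicate of a
  qn <- softmax_normalize(similarity_matrix(ft))
  g <- build_graph(qn, 0.5)
  inf <- influence_scores(g, ft)
  expect_named(inf, colnames(ft))
  # a constant feature would carry zero influence: variance factor is 0
  ftc <- ft; ftc$c <- ftc$c * 0 + 5
  g0 <- g; g0$labels <- colnames(ftc)
  expect_equal(unname((laplacian_centrality(g0) *
                        apply(ftc, 2, function(v) mean((v - mean(v))^2)))["c"]), 0)
})

test_that("selection collapses duplicates, keeps all at phi 0, is deterministic", {
  ft <- with_seed(7, {
    base <- matrix(rnorm(200), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
    df <- as.data.frame(base)
    df$f1dup <- df$f1 + rnorm(40, sd = 1e-7)
    df
  })
  # phi above every influence score: each community keeps exactly its
  # representative, so the duplicate pair collapses to one survivor
  sel_hi <- select_features(ft, phi = 10, seed = 3)
  expect_lte(sum(c("f1", "f1dup") %in% sel_hi$selected), 1L)
  # phi = 0 keeps everything in a single iteration
  sel0 <- select_features(ft, phi = 0, seed = 3)
  expect_setequal(sel0$selected, colnames(ft))
  expect_equal(max(sel0$audit$iteration), 1L)
  # deterministic under a fixed seed
  sel_a <- select_features(ft, seed = 9)
  sel_b <- select_features(ft, seed = 9)
  expect_identical(sel_a$selected, sel_b$selected)
  expect_identical(sel_a$audit, sel_b$audit)
  # termination bound: no more iterations than features
  expect_lte(max(sel_a$audit$iteration), ncol(ft))
  expect_error(select_features(ft[, 1, drop = FALSE]), "at least 2")
})

test_that("selection favours planted-signal features over noise", {
  # layer-2-labeled features load on a strong latent signal; the rest
  # carry only a weak shared nuisance (as real feature tables do, through
  # segment-level effects) plus noise
  ft <- with_seed(8, {
    n <- 60
    latent <- cumsum(rnorm(n))
    nuis <- cumsum(rnorm(n, sd = 0.4))
    sig <- sapply(1:4, function(i)
      latent * (0.8 + 0.1 * i) + nuis + rnorm(n, sd = 0.3))
    colnames(sig) <- sprintf("L2.N%d", 0:3)
    noise <- sapply(1:6, function(i)
      nuis * (0.6 + 0.1 * i) + rnorm(n, sd = 0.8))
    colnames(noise) <- sprintf("L3.N%d", 0:5)
    as.data.frame(cbind(sig, noise))
  })
  sel <- select_features(ft, seed = 4)
  expect_gt(mean(grepl("^L2", sel$selected)), 0.5)
  expect_true(all(sprintf("L2.N%d", 0:3) %in% sel$selected))
})

test_that("graph exports carry edges and annotations", {
  ft <- with_seed(9, as.data.frame(matrix(rnorm(120), 30, 4)))
  qn <- softmax_normalize(similarity_matrix(ft))
  g <- build_graph(qn, 0.4)
  part <- louvain_partition(g, seed = 1)
  g$community <- stats::setNames(part$membership, g$labels)
  g$influence <- influence_scores(g, ft)
  edge_path <- withr::local_tempfile(fileext = ".csv")
  write_edgelist_csv(g, edge_path)
  edges <- read.csv(edge_path)
  expect_equal(nrow(edges), sum(g$adj[upper.tri(g$adj)] > 0))
  gml_path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, gml_path)
  doc <- xml2::read_xml(gml_path)
  expect_equal(length(xml2::xml_find_all(doc, ".//*[local-name()='node']")), 4L)
  expect_equal(length(xml2::xml_find_all(doc, ".//*[local-name()='edge']")),
               nrow(edges))
})
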