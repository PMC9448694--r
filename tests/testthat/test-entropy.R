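test_that("normal-CDF mapping standardizes with the segment's own moments", {
  # sample-sd convention: x = (-1, 0, 1) has sd 1, so y = Phi(x)
  y1 <- ncdf_map(c(-1, 0, 1), ddof = 1)
  expect_equal(y1, pnorm(c(-1, 0, 1)), tolerance = 1e-12)
  # population convention (default): sd = sqrt(2/3)
  y0 <- ncdf_map(c(-1, 0, 1))
  expect_equal(y0, pnorm(c(-1, 0, 1) / sqrt(2 / 3)), tolerance = 1e-12)
  # the mean maps to the CDF median
  expect_equal(unname(y0[2]), 0.5)
  # positive affine transforms leave the mapping unchanged
  x <- with_seed(4, rnorm(50))
  expect_equal(ncdf_map(3.2 * x + 11), ncdf_map(x), tolerance = 1e-12)
  # constant segment: flagged fallback at 0.5
  yc <- ncdf_map(rep(2, 10))
  expect_true(all(yc == 0.5))
  expect_true(attr(yc, "constant"))
  expect_error(ncdf_map(numeric(0)), "empty")
})

test_that("quantizer rounds half-up and clamps to the class range", {
  expect_identical(quantize_classes(0.5, 5), 3L)
  expect_identical(quantize_classes(0.999, 5), 5L)   # 5.495 rounds to 5
  expect_identical(quantize_classes(0.001, 5), 1L)
  # half-up boundary: c*y + 0.5 = 2.5 exactly at y = 0.4
  expect_identical(quantize_classes(0.4, 5), 3L)
  expect_error(quantize_classes(c(0.2, 1), 5), "strictly")
})

test_that("delay embedding unrolls the definition", {
  expect_equal(de_embed(c(1, 2, 3, 4), de_params(m = 3, c = 5, tau = 1)),
               rbind(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(de_embed(c(1, 2, 3, 4, 5), de_params(m = 2, c = 5, tau = 2)),
               rbind(c(1, 3), c(2, 4), c(3, 5)))
  # boundary: minimum length gives exactly one vector
  p <- de_params(m = 3, c = 5, tau = 2)
  expect_equal(nrow(de_embed(c(1, 1, 1, 1, 1), p)), 1L)
  expect_error(de_embed(c(1, 1, 1, 1), p), "minimum 5")
})

test_that("pattern distribution counts match a brute-force recount", {
  p2 <- de_params(m = 2, c = 3)
  pd <- pattern_distribution(rbind(c(1, 2), c(1, 2), c(2, 1)), p2)
  expect_equal(sort(pd$freq), c(1 / 3, 2 / 3))
  expect_equal(sum(pd$freq), 1)
  # identical tuples collapse to a single pattern
  pd1 <- pattern_distribution(rbind(c(2, 2), c(2, 2)), p2)
  expect_equal(pd1$freq, 1)
  # random signal: recount every pattern independently
  z <- with_seed(11, sample.int(5, 200, replace = TRUE))
  p <- de_params(m = 3, c = 5)
  pd <- pattern_distribution(z, p)
  emb <- de_embed(z, p)
  for (i in seq_len(nrow(pd))) {
    lab <- as.integer(strsplit(pd$pattern[i], "-")[[1]])
    hits <- sum(apply(emb, 1, function(r) all(r == lab)))
    expect_equal(pd$freq[i], hits / nrow(emb))
  }
})

test_that("dispersion entropy matches the literal-enumeration oracle", {
  with_seed(21, {
    for (rep in 1:25) {
      n <- sample(50:1000, 1)
      m <- sample(2:3, 1); c <- sample(3:6, 1); tau <- sample(1:2, 1)
      x <- rnorm(n)
      expect_equal(dispersion_entropy(x, de_params(m = m, c = c, tau = tau)),
                   oracle_de(x, m, c, tau), tolerance = 1e-10)
    }
  })
})

test_that("dispersion entropy hits its analytic bounds", {
  p <- de_params()
  expect_equal(dispersion_entropy(rep(7, 100), p), 0)
  expect_equal(dispersion_entropy(uniform_pattern_signal(3, 5), p), log(125))
  # bounds and affine invariance on random signals
  with_seed(31, {
    for (rep in 1:10) {
      x <- rnorm(sample(100:500, 1))
      h <- dispersion_entropy(x, p)
      expect_gte(h, 0)
      expect_lte(h, log(5^3))
      expect_equal(dispersion_entropy(0.3 * x + 40, p), h, tolerance = 1e-12)
    }
  })
  # normalized variant rescales by the maximum
  pn <- de_params(normalize = TRUE)
  x <- with_seed(32, rnorm(300))
  expect_equal(dispersion_entropy(x, pn),
               dispersion_entropy(x, de_params()) / log(125))
})

test_that("hierarchical decomposition averages/differences and inverts", {
  t0 <- hier_decompose(c(1, 5, 2), k = 0)
  expect_equal(t0$components[[1]]$series, c(1, 5, 2))
  t1 <- hier_decompose(c(2, 4, 6, 8), k = 1)
  expect_equal(t1$components[[2]]$series, c(3, 7))     # low
  expect_equal(t1$components[[3]]$series, c(-1, -1))   # high
  # algebraic inversion on even-length random input
  with_seed(41, {
    for (rep in 1:10) {
      x <- rnorm(2 * sample(10:200, 1))
      tr <- hier_decompose(x, 1)
      lo <- tr$components[[2]]$series; hi <- tr$components[[3]]$series
      expect_equal(lo + hi, x[seq(1, length(x), 2)])
      expect_equal(lo - hi, x[seq(2, length(x), 2)])
    }
  })
  # tree cardinality and node lengths
  tr <- hier_decompose(rnorm(64), 3)
  layers <- vapply(tr$components, `[[`, integer(1), "layer")
  expect_equal(as.integer(table(layers)), c(1L, 2L, 4L, 8L))
  expect_equal(length(tr$components), 15L)
  expect_equal(length(tr$components[[15]]$series), 8L)
  # odd-length components drop the trailing sample, flagged
  tro <- hier_decompose(rnorm(9), 1)
  expect_true(tro$components[[2]]$truncated)
  expect_equal(length(tro$components[[2]]$series), 4L)
  expect_error(hier_decompose(rnorm(7), 3), "2\\^k")
})

test_that("hde returns one entropy per node plus per-layer means", {
  x <- with_seed(51, rnorm(4096))
  h0 <- hde(x, k = 0)
  expect_equal(unname(h0$node_entropy), dispersion_entropy(x))
  h <- hde(x, k = 3)
  expect_length(h$node_entropy, 15L)
  expect_length(h$level_mean, 4L)
  expect_named(h$node_entropy[1], "L0.N0")
  # level means really are the means over their layer's nodes
  expect_equal(unname(h$level_mean["L2.mean"]),
               mean(h$node_entropy[grepl("^L2\\.", names(h$node_entropy))]))
  # broadband noise is more complex than a pure tone at every level
  s <- sin(2 * pi * 5 * (0:4095) / 128)
  hs <- hde(s, k = 3)
  expect_true(all(h$level_mean > hs$level_mean))
  # a 16-sample signal leaves 2 samples per layer-3 node: too short for
  # m = 3 embedding, and the error names the offending node
  expect_error(hde(rnorm(16), k = 3), "layer 3")
})
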