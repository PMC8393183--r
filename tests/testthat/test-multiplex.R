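test_that("layer_divergence builds region profiles from community genes", {
  m <- rbind(
    g1 = c(1, 0, 2),
    g2 = c(0, 1, 2),
    g3 = c(5, 5, 5)
  )
  colnames(m) <- paste0("R", 1:3)
  expr <- mesoconn:::expr_tibble(m)
  d <- layer_divergence(expr, c("g1", "g2"))
  # R1 profile (1,0), R2 profile (0,1): disjoint supports
  expect_equal(d["R1", "R2"], 1)
  # oracle check for every pair
  sub <- t(m[c("g1", "g2"), ])
  for (i in 1:3) for (j in 1:3) {
    if (i == j) next
    expect_equal(d[i, j],
                 jensen_shannon_divergence(normalize_profile(sub[i, ]),
                                           normalize_profile(sub[j, ])),
                 tolerance = 1e-12)
  }
  # identical community profiles -> zero divergence
  d3 <- layer_divergence(expr, c("g3", "g1"))
  expect_true(all(d3 >= 0))
  expect_error(layer_divergence(expr, "g1"), "at least 2")
  zero <- mesoconn:::expr_tibble(rbind(a = c(0, 1), b = c(0, 2)) |>
                                   `colnames<-`(c("R1", "R2")))
  expect_error(layer_divergence(zero, c("a", "b")), "R1")
})

test_that("mode_threshold finds a left-concentrated mode below the median", {
  withr::with_seed(41, {
    vals <- c(rnorm(800, 0.2, 0.01), runif(200, 0.3, 0.9))
  })
  d <- matrix(0, 45, 45)
  d[upper.tri(d)] <- vals[1:990]
  d <- d + t(d)
  mt <- mode_threshold(d)
  expect_lt(abs(mt$value - 0.2), 0.02)
  expect_lt(mt$percentile, 50)
})

test_that("mode_threshold sits near the median of a symmetric sample", {
  withr::with_seed(42, {
    vals <- rnorm(4950, 0.5, 0.05)
  })
  d <- matrix(0, 100, 100)
  d[upper.tri(d)] <- vals
  d <- d + t(d)
  mt <- mode_threshold(d)
  expect_lt(abs(mt$percentile - 50), 12)
})

test_that("mode_threshold handles degenerate and tiny samples", {
  d <- matrix(0.3, 6, 6)
  diag(d) <- 0
  mt <- mode_threshold(d)
  expect_equal(mt$value, 0.3)
  expect_equal(mt$percentile, 100)
  expect_error(mode_threshold(matrix(0, 3, 3)), "Fewer than 10")
})

test_that("build_multiplex binarizes layers at the cutoff", {
  reg <- paste0("R", 1:3)
  l1 <- matrix(c(0, .1, .8, .1, 0, .3, .8, .3, 0), 3, dimnames = list(reg, reg))
  l2 <- matrix(c(0, .6, .2, .6, 0, .9, .2, .9, 0), 3, dimnames = list(reg, reg))
  net <- build_multiplex(list(A = l1, B = l2), cutoff = 0.35)
  expect_equal(net$adjacency$A[cbind(c("R1", "R2"), c("R2", "R3"))], c(1, 1))
  expect_equal(sum(net$adjacency$A) / 2, 2)
  expect_equal(sum(net$adjacency$B) / 2, 1)  # only R1-R3
  expect_equal(net$adjacency$B["R1", "R3"], 1)

  all_net <- build_multiplex(list(A = l1, B = l2), cutoff = 1)
  expect_true(all(vapply(all_net$adjacency, function(a) sum(a) / 2, numeric(1)) == 3))
  none <- build_multiplex(list(A = l1, B = l2), cutoff = 0.05)
  expect_true(all(vapply(none$adjacency, sum, numeric(1)) == 0))

  bad <- l2
  rownames(bad) <- colnames(bad) <- paste0("X", 1:3)
  expect_error(build_multiplex(list(l1, bad), cutoff = 0.5), "identical region labels")
})

test_that("multiplex degree sums intra-layer degrees and ignores couplings", {
  reg <- paste0("R", 1:5)
  net <- mk_multiplex(list(clique = clique_adj(reg), ring = cycle_adj(reg)))
  deg <- multiplex_degree(net)
  expect_equal(deg$degree, rep(6L, 5))  # 4 + 2
  single <- mk_multiplex(list(ring = cycle_adj(reg)))
  expect_equal(multiplex_degree(single)$degree, rep(2L, 5))
  empty <- mk_multiplex(list(a = clique_adj(reg) * 0, b = clique_adj(reg) * 0))
  expect_equal(multiplex_degree(empty)$degree, rep(0L, 5))
})

test_that("multiplex PageRank is a distribution and reduces to single-layer PageRank", {
  reg <- paste0("R", 1:4)
  sym <- mk_multiplex(list(a = clique_adj(reg), b = clique_adj(reg)))
  pr <- multiplex_pagerank(sym)
  nl <- attr(pr, "node_layer")
  expect_equal(nl$pagerank, rep(1 / 8, 8), tolerance = 1e-9)

  withr::with_seed(55, {
    A <- matrix(0, 6, 6, dimnames = list(paste0("R", 1:6), paste0("R", 1:6)))
    A[upper.tri(A)] <- (runif(15) < 0.5) * 1
    A <- A + t(A)
  })
  single <- mk_multiplex(list(g = A))
  pr1 <- multiplex_pagerank(single)
  expect_equal(pr1$pagerank, unname(oracle_pagerank(A)), tolerance = 1e-8)

  rnd <- random_multiplex(10, 3, p = 0.3, seed = 77)
  expect_equal(sum(attr(multiplex_pagerank(rnd), "node_layer")$pagerank), 1,
               tolerance = 1e-9)
})

test_that("multiplex eigenvector centrality matches a dense eigen-solve", {
  reg <- paste0("R", 1:6)
  star <- matrix(0, 6, 6, dimnames = list(reg, reg))
  star[1, 2:6] <- star[2:6, 1] <- 1
  ev <- multiplex_eigenvector(mk_multiplex(list(s = star)))
  expect_equal(which.max(ev$eigenvector), 1)

  for (seed in c(101, 102, 103)) {
    rnd <- random_multiplex(8, 3, p = 0.4, seed = seed)
    S <- mesoconn:::supra_adjacency(rnd)
    dense <- eigen(S, symmetric = TRUE)
    v <- abs(dense$vectors[, which.max(dense$values)])
    per_region <- rowSums(matrix(v, nrow = 8))
    per_region <- per_region / max(per_region)
    got <- multiplex_eigenvector(rnd)
    expect_equal(got$eigenvector, unname(per_region), tolerance = 1e-8)
    expect_equal(attr(got, "leading_eigenvalue"), max(dense$values), tolerance = 1e-8)
  }
})

test_that("uncoupled duplicate layers trigger the disconnected warning", {
  reg <- paste0("R", 1:4)
  net <- mk_multiplex(list(a = clique_adj(reg), b = clique_adj(reg)), omega = 0)
  expect_warning(multiplex_eigenvector(net), "disconnected")
})

test_that("multiplex k-core matches hand fixtures and the pruning oracle", {
  reg <- paste0("R", 1:5)
  k5 <- mk_multiplex(list(clique = clique_adj(reg)))
  expect_equal(multiplex_kcore(k5)$coreness, rep(4L, 5))

  both <- mk_multiplex(list(clique = clique_adj(reg), ring = cycle_adj(reg)))
  kc <- multiplex_kcore(both)
  expect_equal(kc$coreness, rep(6L, 5))
  dist <- attr(kc, "kcore_distribution")
  expect_equal(dist$p[dist$k == 6], 1)

  sizes <- withr::with_seed(77, cbind(sample(5:20, 10, replace = TRUE),
                                      sample(1:4, 10, replace = TRUE)))
  for (seed in 1:10) {
    rnd <- random_multiplex(sizes[seed, 1], sizes[seed, 2], p = 0.35,
                            seed = 300 + seed)
    expect_equal(multiplex_kcore(rnd)$coreness,
                 unname(oracle_multiplex_coreness(rnd)))
  }
})

test_that("coreness is invariant to layer order and region relabeling", {
  rnd <- random_multiplex(12, 3, p = 0.3, seed = 500)
  base <- multiplex_kcore(rnd)$coreness
  flipped <- mk_multiplex(rev(rnd$adjacency), omega = rnd$omega)
  expect_equal(multiplex_kcore(flipped)$coreness, base)

  perm <- withr::with_seed(9, sample(12))
  relabeled <- mk_multiplex(lapply(rnd$adjacency, function(a) a[perm, perm]),
                            omega = rnd$omega)
  expect_equal(multiplex_kcore(relabeled)$coreness, base[perm])
})

test_that("single-layer multiplex metrics reduce to their graph counterparts", {
  withr::with_seed(61, {
    A <- matrix(0, 9, 9, dimnames = list(paste0("R", 1:9), paste0("R", 1:9)))
    A[upper.tri(A)] <- (runif(36) < 0.45) * 1
    A <- A + t(A)
  })
  net <- mk_multiplex(list(g = A))
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  expect_equal(multiplex_degree(net)$degree, unname(igraph::degree(g)))
  expect_equal(multiplex_kcore(net)$coreness, unname(igraph::coreness(g)))
  pr <- multiplex_pagerank(net)
  expect_equal(pr$pagerank,
               unname(igraph::page_rank(g, damping = 0.85)$vector),
               tolerance = 1e-6)
})
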