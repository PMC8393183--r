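test_that("modularity_q agrees with igraph's evaluation on random partitions", {
  withr::with_seed(17, {
    for (rep in 1:10) {
      g <- igraph::sample_gnp(12, 0.4)
      if (igraph::ecount(g) == 0) next
      memb <- sample(1:3, 12, replace = TRUE)
      expect_equal(modularity_q(g, memb), igraph::modularity(g, memb),
                   tolerance = 1e-12)
    }
  })
})

test_that("two disjoint cliques yield two communities with Q = 0.5", {
  p <- leading_eigenvector_communities(two_cliques(5), seed = 1)
  expect_equal(length(unique(p$community)), 2)
  expect_equal(attr(p, "modularity"), 0.5, tolerance = 1e-10)
  # the split matches the cliques
  expect_equal(length(unique(p$community[1:5])), 1)
  expect_equal(length(unique(p$community[6:10])), 1)
  # independent cross-check against igraph's ARPACK implementation
  ig <- igraph::cluster_leading_eigen(two_cliques(5))
  expect_equal(igraph::modularity(ig), attr(p, "modularity"), tolerance = 1e-10)
})

test_that("a single clique is indivisible with Q = 0", {
  p <- leading_eigenvector_communities(named_graph(igraph::make_full_graph(6)),
                                       seed = 2)
  expect_equal(length(unique(p$community)), 1)
  expect_equal(attr(p, "modularity"), 0, tolerance = 1e-12)
})

test_that("planted two-block graphs are recovered exactly", {
  withr::with_seed(5, {
    g <- igraph::sample_sbm(60, pref.matrix = matrix(c(0.5, 0.02, 0.02, 0.5), 2),
                            block.sizes = c(30, 30))
  })
  g <- named_graph(g)
  p <- leading_eigenvector_communities(g, seed = 3)
  truth <- setNames(rep(c("A", "B"), each = 30), igraph::V(g)$name)
  rec <- evaluate_recovery(setNames(p$community, p$node), truth)
  expect_equal(rec$nmi, 1)
  expect_equal(rec$ari, 1)
})

test_that("detected Q is near the exhaustive bipartition optimum on small graphs", {
  withr::with_seed(23, {
    for (rep in 1:15) {
      repeat {
        g <- igraph::sample_gnp(sample(5:10, 1), 0.45)
        if (igraph::ecount(g) >= 2) break
      }
      g <- named_graph(g)
      p <- leading_eigenvector_communities(g, seed = rep)
      expect_gte(attr(p, "modularity"), oracle_best_bipartition_q(g) - 0.05)
    }
  })
})

test_that("empty graphs are rejected", {
  expect_error(leading_eigenvector_communities(igraph::make_empty_graph(0, directed = FALSE)),
               "Empty graph")
})

test_that("refine_communities applies the size rules", {
  # 5-clique + 12-clique: the small community becomes unassigned
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(12))
  g <- named_graph(g)
  p <- leading_eigenvector_communities(g, seed = 1)
  r <- suppressMessages(refine_communities(p, g, min_size = 10, max_size = 150))
  expect_equal(sum(r$community == "unassigned"), 5)
  expect_equal(length(setdiff(unique(r$community), "unassigned")), 1)
})

test_that("oversized communities with internal block structure are split, indivisible ones kept", {
  withr::with_seed(9, {
    blocky <- igraph::sample_sbm(200, pref.matrix = matrix(c(0.3, 0.01, 0.01, 0.3), 2),
                                 block.sizes = c(100, 100))
  })
  blocky <- named_graph(blocky, "b")
  solid <- named_graph(igraph::make_full_graph(180), "k")

  one_comm <- function(g) {
    p <- tibble::tibble(node = igraph::V(g)$name, community = "C1")
    structure(p, class = c("gene_partition", class(p)),
              modularity = modularity_q(g, p$community))
  }
  r_blocky <- suppressMessages(refine_communities(one_comm(blocky), blocky,
                                                  min_size = 10, max_size = 150))
  expect_gte(length(setdiff(unique(r_blocky$community), "unassigned")), 2)

  # an oversized clique admits no positive-modularity split and stays intact
  r_solid <- suppressMessages(refine_communities(one_comm(solid), solid,
                                                 min_size = 10, max_size = 150))
  expect_equal(unique(r_solid$community), "C1")
})

test_that("refine_communities is idempotent", {
  g <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(15),
                              igraph::make_full_graph(12))
  g <- named_graph(g)
  p <- leading_eigenvector_communities(g, seed = 1)
  once <- suppressMessages(refine_communities(p, g))
  twice <- suppressMessages(refine_communities(once, g))
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("stability runs are deterministic on a rigid fixture", {
  stab <- community_stability(two_cliques(5), runs = 10, base_seed = 1)
  expect_length(stab$modularity_samples, 10)
  expect_true(all(abs(stab$modularity_samples - 0.5) < 1e-12))
  expect_equal(stab$mean_agreement, 1)
  expect_error(community_stability(two_cliques(5), runs = 1), "at least 2")
})

test_that("planted three-block graphs give high label agreement across runs", {
  withr::with_seed(13, {
    g <- igraph::sample_sbm(90, pref.matrix = diag(3) * 0.45 + 0.02,
                            block.sizes = rep(30, 3))
  })
  g <- named_graph(g)
  stab <- community_stability(g, runs = 8, base_seed = 5)
  expect_gte(stab$mean_agreement, 0.95)
})

test_that("ER null comparison separates planted structure from chance", {
  withr::with_seed(29, {
    g <- igraph::sample_sbm(80, pref.matrix = diag(4) * 0.6 + 0.03,
                            block.sizes = rep(20, 4))
  })
  g <- named_graph(g)
  stab <- community_stability(g, runs = 5, base_seed = 2)
  cmp <- er_null_comparison(g, stab$modularity_samples, n_null = 10, seed = 3)
  expect_length(cmp$null_modularity, 10)
  expect_gt(mean(stab$modularity_samples), quantile(cmp$null_modularity, 0.95))
  expect_lt(cmp$p_value, 1e-6)
  expect_error(er_null_comparison(g, numeric(0)), "nonempty")
})
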