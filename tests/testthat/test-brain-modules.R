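test_that("supra-modularity of hand partitions matches direct bookkeeping", {
  # two disjoint 5-cliques in one layer: same arithmetic as the single-layer case
  reg <- paste0("R", 1:10)
  a <- matrix(0, 10, 10, dimnames = list(reg, reg))
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  net <- mk_multiplex(list(g = a), omega = 0)
  memb <- rep(c("x", "y"), each = 5)
  expect_equal(supra_modularity(net, memb, gamma = 1, omega = 0), 0.5,
               tolerance = 1e-12)
  expect_equal(supra_modularity(net, rep("x", 10), gamma = 1, omega = 0), 0,
               tolerance = 1e-12)
})

test_that("multilayer Louvain recovers planted region blocks spanning all layers", {
  withr::with_seed(71, {
    reg <- paste0("R", 1:20)
    adj <- lapply(1:3, function(s) {
      a <- matrix(0, 20, 20, dimnames = list(reg, reg))
      block <- rep(1:2, each = 10)
      prob <- ifelse(outer(block, block, "=="), 0.8, 0)
      up <- upper.tri(a)
      a[up] <- (runif(190) < prob[up]) * 1
      a + t(a)
    })
  })
  net <- mk_multiplex(adj)
  ma <- multilayer_louvain(net, seed = 4)
  expect_equal(attr(ma, "n_modules"), 2)
  lab <- matrix(ma$module, nrow = 20)
  # each region keeps one module across all layers, and modules match blocks
  expect_true(all(apply(lab, 1, function(r) length(unique(r)) == 1)))
  expect_equal(length(unique(lab[1:10, 1])), 1)
  expect_equal(length(unique(lab[11:20, 1])), 1)
  expect_false(lab[1, 1] == lab[11, 1])
})

test_that("reported supra-modularity equals direct evaluation and beats baselines", {
  for (seed in c(81, 82)) {
    rnd <- random_multiplex(12, 3, p = 0.3, seed = seed)
    ma <- multilayer_louvain(rnd, seed = seed)
    q <- attr(ma, "supra_modularity")
    expect_equal(q, supra_modularity(rnd, ma$module), tolerance = 1e-10)
    singletons <- as.character(seq_len(36))
    expect_gte(q, supra_modularity(rnd, singletons) - 1e-10)
    expect_gte(q, supra_modularity(rnd, rep("one", 36)) - 1e-10)
  }
})

test_that("single-layer Louvain is competitive with igraph's implementation", {
  for (seed in c(91, 92, 93)) {
    withr::with_seed(seed, {
      g <- igraph::sample_gnp(30, 0.15)
    })
    if (igraph::ecount(g) == 0) next
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    rownames(A) <- colnames(A) <- paste0("R", 1:30)
    net <- mk_multiplex(list(g = A), omega = 0)
    ma <- multilayer_louvain(net, seed = seed, omega = 0)
    q_ours <- attr(ma, "supra_modularity")
    q_igraph <- withr::with_seed(seed,
      igraph::modularity(igraph::cluster_louvain(g)))
    expect_gte(q_ours, q_igraph - 0.02)
  }
})

test_that("strong coupling forces replicas of a region into one module", {
  rnd <- random_multiplex(10, 3, p = 0.4, seed = 111)
  ma <- multilayer_louvain(rnd, omega = 50, seed = 2)
  lab <- matrix(ma$module, nrow = 10)
  expect_true(all(apply(lab, 1, function(r) length(unique(r)) == 1)))
})

test_that("per-layer projected modularity evaluates each layer under module labels", {
  reg <- paste0("R", 1:10)
  a <- matrix(0, 10, 10, dimnames = list(reg, reg))
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  empty <- a * 0
  net <- mk_multiplex(list(cliques = a, bare = empty))
  assign <- tibble::tibble(
    region = rep(reg, 2),
    layer = rep(c("cliques", "bare"), each = 10),
    module = rep(rep(c("x", "y"), each = 5), 2)
  )
  expect_warning(plm <- project_layer_modularity(assign, net), "no edges")
  expect_equal(plm$modularity[plm$layer == "cliques"], 0.5, tolerance = 1e-12)
  expect_equal(plm$modularity[plm$layer == "bare"], 0)

  one <- assign
  one$module <- "all"
  expect_warning(plm1 <- project_layer_modularity(one, net), "no edges")
  expect_equal(plm1$modularity[plm1$layer == "cliques"], 0, tolerance = 1e-12)
})

test_that("random labels on an ER layer give near-zero modularity", {
  withr::with_seed(121, {
    g <- igraph::sample_gnp(50, 0.2)
    labs <- sample(1:4, 50, replace = TRUE)
  })
  expect_lt(abs(modularity_q(g, labs)), 0.1)
})

test_that("region_module_summary counts shared contexts and underlying genes", {
  assign <- tibble::tibble(
    region = rep(c("R1", "R2", "R3"), 2),
    layer = rep(c("C1", "C2"), each = 3),
    module = c("m1", "m1", "m2", "m1", "m2", "m2")
  )
  partition <- tibble::tibble(
    node = paste0("g", 1:5),
    community = c("C1", "C1", "C1", "C2", "C2")
  )
  expr <- tibble::tibble(gene = paste0("g", 1:5), R1 = 1:5, R2 = 5:1, R3 = rep(1, 5))
  summ <- region_module_summary(assign, partition, expr)
  get <- function(a, b, col) summ[[col]][summ$region_a == a & summ$region_b == b]
  expect_equal(get("R1", "R2", "shared_layers"), 1)  # C1 only
  expect_equal(get("R1", "R2", "shared_genes"), 3)
  expect_equal(get("R2", "R3", "shared_layers"), 1)  # C2 only
  expect_equal(get("R2", "R3", "shared_genes"), 2)
  expect_equal(get("R1", "R3", "shared_layers"), 0)
  rs <- attr(summ, "region_summary")
  expect_equal(rs$total_shared[rs$region == "R2"], 2)
  expect_equal(rs$rank[rs$region == "R2"], 1)
})

test_that("co-assignment extremes give layer-count and zero shared contexts", {
  assign <- tibble::tibble(
    region = rep(c("A", "B"), 3),
    layer = rep(paste0("L", 1:3), each = 2),
    module = rep("m", 6)
  )
  partition <- tibble::tibble(node = character(0), community = character(0))
  expr <- tibble::tibble(gene = character(0), R1 = numeric(0))
  summ <- region_module_summary(assign, partition, expr)
  expect_equal(summ$shared_layers, 3)

  assign$module <- c("a", "b", "a", "b", "a", "b")
  summ2 <- region_module_summary(assign, partition, expr)
  expect_equal(summ2$shared_layers, 0)
})

test_that("planted region modules are recovered from multiplex structure", {
  nmis <- vapply(1:3, function(s) {
    sim <- simulate_multiplex(n_regions = 45, n_layers = 4, n_modules = 3,
                              p_in = 0.6, p_out = 0.05, seed = s)
    ma <- multilayer_louvain(sim$net, seed = s)
    rs <- attr(region_module_summary(
      ma,
      tibble::tibble(node = character(0), community = character(0)),
      tibble::tibble(gene = character(0), R1 = numeric(0))
    ), "region_summary")
    evaluate_recovery(setNames(rs$module, rs$region), sim$truth)$nmi
  }, numeric(1))
  expect_gte(mean(nmis), 0.9)
})
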