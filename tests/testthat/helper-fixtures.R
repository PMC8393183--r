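# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive re-derivations (BFS / dense eigen / exhaustive
# enumeration), kept separate from the package's implementation paths.

two_cliques <- function(k = 5) {
  g <- igraph::disjoint_union(igraph::make_full_graph(k), igraph::make_full_graph(k))
  igraph::V(g)$name <- paste0("n", seq_len(2 * k))
  g
}

named_graph <- function(g, prefix = "v") {
  igraph::V(g)$name <- paste0(prefix, seq_len(igraph::vcount(g)))
  g
}

# Build a multiplex object directly from 0/1 adjacency matrices.
mk_multiplex <- function(adj, omega = 1) {
  regions <- rownames(adj[[1]])
  if (is.null(names(adj))) names(adj) <- paste0("L", seq_along(adj))
  structure(
    list(region_labels = regions, layer_labels = names(adj),
         adjacency = adj, omega = omega),
    class = "multiplex"
  )
}

# Ring (cycle) adjacency on the given labels.
cycle_adj <- function(labels) {
  n <- length(labels)
  a <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    a[i, j] <- a[j, i] <- 1
  }
  a
}

clique_adj <- function(labels) {
  n <- length(labels)
  a <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(a) <- 0
  a
}

# --- shortest-path oracles (Floyd-Warshall + geodesic counting) -----------

oracle_dist <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) {
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  }
  d
}

# number of geodesics between every pair
oracle_nsp <- function(A, d) {
  n <- nrow(A)
  nsp <- matrix(0, n, n)
  diag(nsp) <- 1
  for (s in seq_len(n)) {
    for (dist in sort(unique(d[s, is.finite(d[s, ]) & d[s, ] > 0]))) {
      for (t in which(d[s, ] == dist)) {
        preds <- which(A[, t] > 0 & d[s, ] == dist - 1)
        nsp[s, t] <- sum(nsp[s, preds])
      }
    }
  }
  nsp
}

oracle_betweenness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- nrow(A)
  d <- oracle_dist(A)
  nsp <- oracle_nsp(A, d)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t]) || nsp[s, t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        b[v] <- b[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
      }
    }
  }
  b
}

oracle_closeness <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  d <- oracle_dist(A)
  1 / rowSums(d)
}

oracle_eigenvector <- function(A, iter = 100000, tol = 1e-13) {
  x <- rep(1, nrow(A))
  for (i in seq_len(iter)) {
    y <- as.numeric(A %*% x)
    y <- y / sqrt(sum(y^2))
    if (sum(abs(y - x)) < tol) break
    x <- y
  }
  x / max(x)
}

oracle_pagerank <- function(A, damping = 0.85, iter = 100000, tol = 1e-13) {
  n <- nrow(A)
  cs <- colSums(A)
  x <- rep(1 / n, n)
  for (i in seq_len(iter)) {
    flow <- numeric(n)
    for (j in seq_len(n)) {
      if (cs[j] > 0) flow <- flow + damping * A[, j] * x[j] / cs[j]
      else flow <- flow + damping * x[j] / n
    }
    xn <- flow + (1 - damping) / n
    if (sum(abs(xn - x)) < tol) break
    x <- xn
  }
  x / sum(x)
}

# multiplex coreness oracle: repeatedly delete a minimum-total-degree region,
# coreness = the running maximum of the minimum degree at deletion time
oracle_multiplex_coreness <- function(net) {
  n <- length(net$region_labels)
  alive <- rep(TRUE, n)
  core <- integer(n)
  current_k <- 0L
  total_deg <- function(alive) {
    deg <- rep(0, n)
    for (a in net$adjacency) deg <- deg + as.numeric(a %*% alive)
    deg
  }
  while (any(alive)) {
    deg <- total_deg(alive)
    deg[!alive] <- Inf
    v <- which.min(deg)
    current_k <- max(current_k, deg[v])
    core[v] <- current_k
    alive[v] <- FALSE
  }
  setNames(core, net$region_labels)
}

# exhaustive maximum modularity over all bipartitions (incl. the trivial one)
oracle_best_bipartition_q <- function(g) {
  n <- igraph::vcount(g)
  best <- modularity_q(g, rep(1, n))
  for (code in seq_len(2^(n - 1) - 1)) {
    side <- as.integer(intToBits(code))[seq_len(n)]
    best <- max(best, modularity_q(g, side))
  }
  best
}

# divergence matrix whose median-percentile graph is the path 1-2-3-4
path4_divergence <- function() {
  d <- matrix(0, 4, 4, dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  d["g1", "g2"] <- d["g2", "g1"] <- 0.10
  d["g2", "g3"] <- d["g3", "g2"] <- 0.12
  d["g3", "g4"] <- d["g4", "g3"] <- 0.14
  d["g1", "g3"] <- d["g3", "g1"] <- 0.50
  d["g2", "g4"] <- d["g4", "g2"] <- 0.60
  d["g1", "g4"] <- d["g4", "g1"] <- 0.70
  d
}

# variance table with a sharp retained-count step between 4.4 and 4.5 so the
# derivative criterion selects 4.5
step_variance_table <- function() {
  lv <- c(rep(4.43, 80), seq(6.05, 8.95, length.out = 20))
  tibble::tibble(gene = sprintf("g%03d", seq_along(lv)),
                 log_variance = lv, finite = TRUE)
}

random_multiplex <- function(n_regions, n_layers, p = 0.3, omega = 1, seed = 1) {
  withr::with_seed(seed, {
    labels <- paste0("R", seq_len(n_regions))
    adj <- lapply(seq_len(n_layers), function(s) {
      a <- matrix(0, n_regions, n_regions, dimnames = list(labels, labels))
      up <- upper.tri(a)
      a[up] <- (runif(sum(up)) < p) * 1
      a + t(a)
    })
    mk_multiplex(adj, omega = omega)
  })
}
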