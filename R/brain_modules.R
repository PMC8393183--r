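# Multilayer (Mucha-style) modularity machinery: intra-layer Newman-Girvan
# terms at resolution gamma, categorical interlayer coupling at weight omega.

#' Multilayer modularity of a node-layer assignment
#'
#' Direct evaluation of the generalized quality function
#' \eqn{Q = \frac{1}{2\mu}\sum_{ijsr}[(A_{ijs} - \gamma
#' \frac{k_{is}k_{js}}{2m_s})\delta_{sr} + \delta_{ij}\omega]
#' \delta(g_{is}, g_{jr})}: per-layer modularity terms plus the coupling
#' reward for co-assigned replicas. Layers without edges contribute no
#' null-model term.
#'
#' @param net A `multiplex`.
#' @param membership Module label per (region, layer), region index moving
#'   fastest (the order of `expand.grid(region, layer)`).
#' @param gamma Intra-layer resolution, default 1.
#' @param omega Interlayer coupling weight; defaults to the multiplex's
#'   construction omega.
#' @return Supra-modularity Q.
#' @export
supra_modularity <- function(net, membership, gamma = 1, omega = net$omega) {
  n <- length(net$region_labels)
  L <- length(net$layer_labels)
  stopifnot(length(membership) == n * L)
  membership <- as.character(membership)
  two_m <- vapply(net$adjacency, sum, numeric(1))  # 2*m_s per layer
  two_mu <- sum(two_m) + omega * n * L * (L - 1)
  if (two_mu <= 0) abort("Degenerate multiplex: no edges and no coupling.")
  total <- 0
  for (s in seq_len(L)) {
    lab <- membership[(s - 1) * n + seq_len(n)]
    A <- net$adjacency[[s]]
    same <- outer(lab, lab, "==")
    total <- total + sum(A * same)
    if (two_m[s] > 0) {
      k <- rowSums(A)
      Kc <- tapply(k, lab, sum)
      total <- total - gamma * sum(Kc^2) / two_m[s]
    }
  }
  if (L > 1 && omega > 0) {
    lab_mat <- matrix(membership, nrow = n, ncol = L)
    for (i in seq_len(n)) {
      tt <- table(lab_mat[i, ])
      total <- total + omega * sum(tt * (tt - 1))
    }
  }
  unname(total / two_mu)
}

#' Multilayer Louvain module detection
#'
#' Greedy optimization of the multilayer modularity (see
#' [supra_modularity()]): seed-shuffled local moving of node-layers between
#' modules followed by aggregation of modules into super-nodes, repeated
#' until no quality gain remains.
#'
#' @param net A `multiplex`.
#' @param gamma Intra-layer resolution, default 1.
#' @param omega Interlayer coupling weight; defaults to the multiplex omega.
#' @param seed Seed controlling the node sweep order.
#' @return An object of class `module_assignment`: tibble with columns
#'   `region`, `layer`, `module`, with attributes `supra_modularity`,
#'   `per_layer_modularity`, `n_modules`, `gamma`, `omega`.
#' @export
multilayer_louvain <- function(net, gamma = 1, omega = net$omega, seed = 1L) {
  n <- length(net$region_labels)
  L <- length(net$layer_labels)
  NL <- n * L
  if (NL == 0) abort("Empty multiplex.")
  W <- supra_adjacency(net, omega = omega)
  two_m <- vapply(net$adjacency, sum, numeric(1))
  # per node-layer intra strength, by layer
  K <- matrix(0, NL, L)
  kv <- numeric(NL)
  for (s in seq_len(L)) {
    ix <- (s - 1) * n + seq_len(n)
    kv[ix] <- rowSums(net$adjacency[[s]])
    K[ix, s] <- kv[ix]
  }
  inv2m <- ifelse(two_m > 0, 1 / two_m, 0)

  membership <- local_seed(seed, louvain_levels(W, K, inv2m, gamma))

  # map back to labels M1.. by decreasing module size
  sizes <- sort(table(membership), decreasing = TRUE)
  relab <- setNames(paste0("M", seq_along(sizes)), names(sizes))
  module <- unname(relab[as.character(membership)])
  out <- tibble::tibble(
    region = rep(net$region_labels, L),
    layer = rep(net$layer_labels, each = n),
    module = module
  )
  q <- supra_modularity(net, module, gamma = gamma, omega = omega)
  out <- structure(out,
    class = c("module_assignment", class(out)),
    supra_modularity = q,
    gamma = gamma,
    omega = omega,
    n_modules = length(sizes)
  )
  attr(out, "per_layer_modularity") <- project_layer_modularity(out, net)
  out
}

# One full Louvain hierarchy: local moving + aggregation until stable.
# W: supra weight matrix (edge term); K: node x layer intra strengths;
# inv2m: 1/(2 m_s) per layer. Returns a membership vector for the original
# node-layers.
louvain_levels <- function(W, K, inv2m, gamma) {
  n0 <- nrow(W)
  assign0 <- seq_len(n0)
  repeat {
    comm <- louvain_local_move(W, K, inv2m, gamma)
    ids <- sort(unique(comm))
    comm <- match(comm, ids)
    moved <- length(ids) < nrow(W)
    assign0 <- comm[assign0]
    if (!moved) break
    # aggregate communities into super-nodes
    f <- factor(comm, levels = seq_along(ids))
    W <- rowsum(t(rowsum(W, f)), f)
    K <- rowsum(K, f)
    if (nrow(W) == 1) break
  }
  assign0
}

louvain_local_move <- function(W, K, inv2m, gamma, tol = 1e-12) {
  nn <- nrow(W)
  comm <- seq_len(nn)
  Kc <- K  # community x layer strengths (starts as singleton copy)
  improved <- TRUE
  sweep_count <- 0
  while (improved && sweep_count < 100) {
    improved <- FALSE
    sweep_count <- sweep_count + 1
    for (v in sample.int(nn)) {
      a <- comm[v]
      wv_row <- W[v, ]
      wv_row[v] <- 0
      neigh <- which(wv_row > 0)
      cand <- unique(c(a, comm[neigh]))
      if (length(cand) == 1) next
      wv <- vapply(cand, function(c) sum(wv_row[comm == c]), numeric(1))
      null_v <- vapply(cand, function(c) {
        Kcc <- Kc[c, ]
        if (c == a) Kcc <- Kcc - K[v, ]
        gamma * sum(K[v, ] * Kcc * inv2m)
      }, numeric(1))
      score <- wv - null_v
      cur <- score[cand == a]
      best <- which.max(score)
      if (score[best] > cur + tol && cand[best] != a) {
        b <- cand[best]
        comm[v] <- b
        Kc[a, ] <- Kc[a, ] - K[v, ]
        Kc[b, ] <- Kc[b, ] + K[v, ]
        improved <- TRUE
      }
    }
  }
  comm
}

#' @export
print.module_assignment <- function(x, ...) {
  cat(sprintf("<module_assignment> %d modules over %d node-layers, supra-Q = %.4f\n",
              attr(x, "n_modules"), nrow(x), attr(x, "supra_modularity")))
  NextMethod()
}

#' Per-layer modularity of a module assignment
#'
#' For each layer, the Newman-Girvan modularity of that layer's intra-layer
#' graph under the module labels carried by its node-layer replicas. Layers
#' without edges score 0 with a warning.
#'
#' @param assign A `module_assignment` (or a tibble with `region`, `layer`,
#'   `module`).
#' @param net The `multiplex` the assignment covers.
#' @return Tibble with columns `layer`, `modularity`.
#' @export
project_layer_modularity <- function(assign, net) {
  n <- length(net$region_labels)
  qs <- vapply(seq_along(net$layer_labels), function(s) {
    lay <- net$layer_labels[s]
    lab <- assign$module[assign$layer == lay][match(
      net$region_labels, assign$region[assign$layer == lay]
    )]
    A <- net$adjacency[[s]]
    if (sum(A) == 0) {
      warn(sprintf("Layer '%s' has no edges: modularity set to 0.", lay))
      return(0)
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    modularity_q(g, lab)
  }, numeric(1))
  tibble::tibble(layer = net$layer_labels, modularity = qs)
}

#' Region connectivity through shared brain modules
#'
#' For every pair of regions, counts the layers in which both regions'
#' replicas share a module, and sums the community genes underlying those
#' shared layers. Also ranks each region by its total shared-module
#' connectivity, and reports each region's consensus module (majority label
#' over its layer replicas, ties to the lowest label).
#'
#' @param assign A `module_assignment`.
#' @param partition The `gene_partition` whose communities define the layers
#'   (community labels must match the multiplex layer labels).
#' @param expr Expression tibble (used to count genes present per community).
#' @return Tibble with columns `region_a`, `region_b`, `shared_layers`,
#'   `shared_genes`; attribute `region_summary` is a per-region tibble with
#'   `region`, `module`, `total_shared`, `rank`.
#' @export
region_module_summary <- function(assign, partition, expr) {
  regions <- sort(unique(assign$region))
  layers <- unique(assign$layer)
  lab <- tidyr::pivot_wider(assign, names_from = "layer", values_from = "module")
  lab <- lab[match(regions, lab$region), , drop = FALSE]
  lab_mat <- as.matrix(lab[, layers, drop = FALSE])
  genes_per_layer <- vapply(layers, function(cl) {
    sum(partition$community == cl & partition$node %in% expr[[1]])
  }, numeric(1))
  n <- length(regions)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  shared_layers <- integer(nrow(pr))
  shared_genes <- numeric(nrow(pr))
  for (p in seq_len(nrow(pr))) {
    same <- lab_mat[pr[p, 1], ] == lab_mat[pr[p, 2], ]
    shared_layers[p] <- sum(same)
    shared_genes[p] <- sum(genes_per_layer[same])
  }
  out <- tibble::tibble(
    region_a = regions[pr[, 1]],
    region_b = regions[pr[, 2]],
    shared_layers = shared_layers,
    shared_genes = shared_genes
  )
  tot <- setNames(rep(0, n), regions)
  for (p in seq_len(nrow(pr))) {
    tot[pr[p, 1]] <- tot[pr[p, 1]] + shared_layers[p]
    tot[pr[p, 2]] <- tot[pr[p, 2]] + shared_layers[p]
  }
  consensus <- apply(lab_mat, 1, function(r) {
    tt <- table(r)
    names(tt)[which.max(tt)]  # ties -> lowest label (table is name-sorted)
  })
  attr(out, "region_summary") <- tibble::tibble(
    region = regions,
    module = consensus,
    total_shared = as.numeric(tot),
    rank = as.integer(rank(-tot, ties.method = "min"))
  )
  out
}
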