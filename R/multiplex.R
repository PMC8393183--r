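#' Region-by-region divergence for one gene community
#'
#' Each region's profile is the expression vector of the community's genes in
#' that region, normalized to a distribution; the layer is the matrix of
#' pairwise Jensen-Shannon divergences among regions.
#'
#' @param expr Expression tibble.
#' @param community_genes Character vector of gene IDs (subset of the matrix,
#'   at least 2).
#' @param community Optional community label for error messages.
#' @return Symmetric regions-by-regions divergence matrix.
#' @export
layer_divergence <- function(expr, community_genes, community = NULL) {
  m <- assert_expression(expr)
  community_genes <- as.character(community_genes)
  if (!all(community_genes %in% rownames(m))) {
    abort("`community_genes` must be a subset of the expression matrix genes.")
  }
  if (length(community_genes) < 2) abort("A community layer needs at least 2 genes.")
  sub <- t(m[community_genes, , drop = FALSE])  # regions x genes
  s <- rowSums(sub)
  if (any(s <= 0)) {
    abort(sprintf(
      "Region '%s' has all-zero expression for community%s.",
      rownames(sub)[which(s <= 0)[1]],
      if (is.null(community)) "" else sprintf(" '%s'", community)
    ))
  }
  jsd_all_pairs(sub / s)
}

#' Divergence layers for every gene community
#'
#' @param expr Expression tibble.
#' @param partition A `gene_partition` (labels `"unassigned"` are skipped, as
#'   are communities with fewer than 2 genes present in `expr`).
#' @return Named list of regions-by-regions divergence matrices, one per
#'   community.
#' @export
community_layers <- function(expr, partition) {
  labs <- setdiff(unique(partition$community), "unassigned")
  genes_present <- expr[[1]]
  layers <- list()
  for (cl in sort(labs)) {
    gg <- intersect(partition$node[partition$community == cl], genes_present)
    if (length(gg) < 2) next
    layers[[cl]] <- layer_divergence(expr, gg, community = cl)
  }
  if (length(layers) == 0) abort("No community with at least 2 genes present.")
  layers
}

#' Mode of the pooled layer-divergence distribution
#'
#' Pools all off-diagonal divergences across layers, histograms them with the
#' Freedman-Diaconis bin width, and returns the midpoint of the most
#' populated bin (ties to the lowest bin) together with its percentile rank
#' in the pooled sample (`100 * mean(pooled <= mode)`). This mode is the
#' multiplex edge cutoff: it keeps the least divergent region pairs while
#' discarding the sparse high-divergence tail. If all pooled values are
#' identical the mode is that value with percentile 100.
#'
#' @param layers List of divergence matrices (or a single matrix).
#' @return List with `value` (mode divergence) and `percentile`.
#' @export
mode_threshold <- function(layers) {
  if (is.matrix(layers)) layers <- list(layers)
  pooled <- unlist(lapply(layers, function(d) d[upper.tri(d)]), use.names = FALSE)
  if (length(pooled) < 10) abort("Fewer than 10 pooled divergences: histogram unstable.")
  if (diff(range(pooled)) == 0) {
    return(list(value = pooled[1], percentile = 100))
  }
  bw <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
  if (bw <= 0) bw <- diff(range(pooled)) / ceiling(sqrt(length(pooled)))
  breaks <- seq(min(pooled), max(pooled) + bw, by = bw)
  h <- hist(pooled, breaks = breaks, plot = FALSE, right = FALSE)
  top <- which.max(h$counts)  # first maximum = lowest bin
  mode_value <- h$mids[top]
  list(value = mode_value, percentile = 100 * mean(pooled <= mode_value))
}

#' Assemble the community-layered multiplex network
#'
#' One layer per gene community over a shared set of brain-region nodes:
#' an intra-layer edge links two regions when their divergence in that layer
#' is at most `cutoff`; every region is coupled to its own replica in every
#' other layer with categorical coupling weight `coupling_weight`.
#'
#' @param layers Named list of regions-by-regions divergence matrices with
#'   identical region labels.
#' @param cutoff Divergence cutoff (e.g. `mode_threshold(layers)$value`).
#' @param coupling_weight Interlayer coupling weight omega (>= 0), default 1.
#' @return An object of class `multiplex`: list with `region_labels`,
#'   `layer_labels`, `adjacency` (list of binary matrices) and `omega`.
#' @export
build_multiplex <- function(layers, cutoff, coupling_weight = 1.0) {
  stopifnot(length(layers) >= 1, coupling_weight >= 0)
  regions <- rownames(layers[[1]])
  for (d in layers) {
    if (!identical(rownames(d), regions) || !identical(colnames(d), regions)) {
      abort("All layers must share identical region labels.")
    }
  }
  if (is.null(names(layers))) names(layers) <- paste0("L", seq_along(layers))
  adj <- lapply(layers, function(d) {
    a <- (d <= cutoff) * 1
    diag(a) <- 0
    a
  })
  structure(
    list(
      region_labels = regions,
      layer_labels = names(layers),
      adjacency = adj,
      omega = coupling_weight
    ),
    class = "multiplex"
  )
}

#' @export
print.multiplex <- function(x, ...) {
  ne <- vapply(x$adjacency, function(a) sum(a) / 2, numeric(1))
  cat(sprintf("<multiplex> %d regions x %d layers, omega = %g\n",
              length(x$region_labels), length(x$layer_labels), x$omega))
  cat("  intra-layer edges:", paste(sprintf("%s=%d", x$layer_labels, ne), collapse = ", "), "\n")
  invisible(x)
}

# Supra-adjacency matrix: intra-layer blocks on the diagonal, omega * I
# between every pair of layers. Node-layer order: region fastest, layer slowest.
supra_adjacency <- function(net, omega = net$omega) {
  n <- length(net$region_labels)
  L <- length(net$layer_labels)
  S <- matrix(0, n * L, n * L)
  for (s in seq_len(L)) {
    ix <- (s - 1) * n + seq_len(n)
    S[ix, ix] <- net$adjacency[[s]]
  }
  if (L > 1 && omega > 0) {
    for (s in seq_len(L - 1)) for (r in (s + 1):L) {
      is <- (s - 1) * n + seq_len(n)
      ir <- (r - 1) * n + seq_len(n)
      S[cbind(is, ir)] <- omega
      S[cbind(ir, is)] <- omega
    }
  }
  rownames(S) <- colnames(S) <- paste(rep(net$region_labels, L),
                                      rep(net$layer_labels, each = n), sep = "|")
  S
}

#' Multiplex degree
#'
#' For each region, the total number of intra-layer links over all layers;
#' interlayer couplings to its own replicas are ignored.
#'
#' @param net A `multiplex`.
#' @return Tibble with columns `region`, `degree` and per-layer degree
#'   columns.
#' @export
multiplex_degree <- function(net) {
  per <- vapply(net$adjacency, rowSums, numeric(length(net$region_labels)))
  if (is.null(dim(per))) per <- matrix(per, nrow = length(net$region_labels))
  colnames(per) <- net$layer_labels
  dplyr::bind_cols(
    tibble::tibble(region = net$region_labels, degree = as.integer(rowSums(per))),
    tibble::as_tibble(per)
  )
}

#' Multiplex PageRank
#'
#' Power iteration on the supra-transition matrix: intra-layer edges plus
#' interlayer couplings are column-normalized; dangling node-layers teleport
#' uniformly; with damping `r` the walker follows the supra-structure and
#' teleports uniformly over all N x L node-layers with probability `1 - r`.
#' The stationary distribution over node-layers sums to 1; a region's score
#' is the sum over its layer replicas.
#'
#' @param net A `multiplex`.
#' @param damping Damping factor r, default 0.85.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter Iteration cap.
#' @return Tibble with columns `region`, `pagerank`; attribute `node_layer`
#'   holds the per-(region, layer) stationary probabilities.
#' @export
multiplex_pagerank <- function(net, damping = 0.85, tol = 1e-10, max_iter = 10000) {
  S <- supra_adjacency(net)
  NL <- nrow(S)
  if (sum(S) == 0) abort("Multiplex has no edges or couplings: PageRank undefined.")
  colsum <- colSums(S)
  dangling <- colsum == 0
  Tm <- S
  if (any(!dangling)) {
    Tm[, !dangling] <- sweep(S[, !dangling, drop = FALSE], 2, colsum[!dangling], "/")
  }
  x <- rep(1 / NL, NL)
  res <- Inf
  for (it in seq_len(max_iter)) {
    xn <- damping * as.numeric(Tm %*% x) +
      damping * sum(x[dangling]) / NL +
      (1 - damping) / NL
    res <- sum(abs(xn - x))
    x <- xn
    if (res < tol) break
  }
  if (res >= tol) {
    abort(sprintf("PageRank did not converge: residual %.3g after %d iterations.",
                  res, max_iter))
  }
  x <- x / sum(x)
  n <- length(net$region_labels)
  L <- length(net$layer_labels)
  per_region <- rowSums(matrix(x, nrow = n, ncol = L))
  out <- tibble::tibble(region = net$region_labels, pagerank = per_region)
  attr(out, "node_layer") <- tibble::tibble(
    region = rep(net$region_labels, L),
    layer = rep(net$layer_labels, each = n),
    pagerank = x
  )
  out
}

#' Multiplex eigenvector centrality
#'
#' Leading eigentensor of the supra-adjacency matrix (intra-layer edges plus
#' interlayer couplings) by power iteration; a region's score is the sum of
#' its node-layer entries, rescaled to unit maximum.
#'
#' @param net A `multiplex`.
#' @param tol Convergence tolerance on the iterate, default 1e-10.
#' @param max_iter Iteration cap.
#' @return Tibble with columns `region`, `eigenvector`; attributes
#'   `leading_eigenvalue` and `node_layer`.
#' @export
multiplex_eigenvector <- function(net, tol = 1e-10, max_iter = 100000) {
  S <- supra_adjacency(net)
  if (sum(S) == 0) abort("Supra-adjacency is all zero: eigenvector centrality undefined.")
  gs <- igraph::graph_from_adjacency_matrix((S > 0) * 1, mode = "undirected")
  if (igraph::components(gs)$no > 1) {
    warn("Supra-graph is disconnected: scores reflect the dominant component.")
  }
  NL <- nrow(S)
  # shift by +1 so the algebraically largest eigenvalue strictly dominates in
  # magnitude (the supra-adjacency of a bipartite structure has a matching
  # negative eigenvalue that would make plain power iteration oscillate)
  Ssh <- S
  diag(Ssh) <- diag(Ssh) + 1
  x <- rep(1 / sqrt(NL), NL)
  lambda <- 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    y <- as.numeric(Ssh %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) abort("Power iteration collapsed to zero: no leading eigenvalue.")
    y <- y / ny
    if (sum(abs(y - x)) < tol) {
      x <- y
      lambda <- ny - 1
      converged <- TRUE
      break
    }
    x <- y
    lambda <- ny - 1
  }
  if (!converged) abort("Eigenvector centrality did not converge.")
  x <- abs(x)
  n <- length(net$region_labels)
  L <- length(net$layer_labels)
  per_region <- rowSums(matrix(x, nrow = n, ncol = L))
  per_region <- per_region / max(per_region)
  out <- tibble::tibble(region = net$region_labels, eigenvector = per_region)
  attr(out, "leading_eigenvalue") <- lambda
  attr(out, "node_layer") <- tibble::tibble(
    region = rep(net$region_labels, L),
    layer = rep(net$layer_labels, each = n),
    eigenvector = x
  )
  out
}

#' Multiplex k-core decomposition
#'
#' Iterative pruning on the multiplex degree: while targeting level k, any
#' region whose total intra-layer degree (summed over layers) falls below k
#' is removed from all layers simultaneously; regions removed at level k have
#' coreness k - 1. Also reports the coreness distribution
#' \eqn{P_k(q) = n_k(q) / n_{k\mathrm{-core}}}: the fraction of regions with
#' coreness exactly k among regions with coreness at least 1.
#'
#' @param net A `multiplex`.
#' @return Tibble with columns `region`, `coreness`; attribute
#'   `kcore_distribution` (tibble `k`, `p`).
#' @export
multiplex_kcore <- function(net) {
  n <- length(net$region_labels)
  adj <- net$adjacency
  alive <- rep(TRUE, n)
  core <- rep(0L, n)
  k <- 1L
  while (any(alive)) {
    repeat {
      deg <- rep(0, n)
      for (a in adj) {
        deg <- deg + as.numeric(a %*% alive)
      }
      drop <- alive & deg < k
      if (!any(drop)) break
      core[drop] <- k - 1L
      alive[drop] <- FALSE
    }
    k <- k + 1L
    if (k > 1L + sum(vapply(adj, sum, numeric(1)))) break
  }
  tab <- table(core[core >= 1])
  dist <- if (length(tab) > 0) {
    tibble::tibble(k = as.integer(names(tab)), p = as.numeric(tab) / sum(tab))
  } else {
    tibble::tibble(k = integer(0), p = numeric(0))
  }
  out <- tibble::tibble(region = net$region_labels, coreness = core)
  attr(out, "kcore_distribution") <- dist
  out
}
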