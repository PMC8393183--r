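#' Betweenness-entropy sweep over divergence percentiles
#'
#' For each percentile in `percentiles`, keeps the edges whose divergence is
#' at most that percentile of the off-diagonal (upper-triangle) divergences,
#' computes unweighted node betweenness on the resulting graph, and takes the
#' Shannon entropy (natural log) of the betweenness distribution, estimated
#' by a histogram with `bins` equal-width bins spanning the betweenness
#' range; when all betweenness values are equal (in particular all zero, as
#' on a complete graph) the entropy is 0. The selected percentile maximizes
#' this entropy (ties go to the smallest percentile) — the maximum-entropy
#' sparsification criterion used to binarize the gene divergence matrix.
#' The entropy is low both for over-sparse graphs (betweenness concentrated
#' on a few bridges) and for over-dense ones (betweenness collapsed near a
#' single value), and peaks where the mesoscale structure is richest.
#'
#' @param d Symmetric divergence matrix (see [pairwise_divergence()]).
#' @param percentiles Integer percentile grid, default `1:99`.
#' @param bins Number of equal-width histogram bins, default 100.
#' @return An object of class `entropy_sweep`: tibble with columns
#'   `percentile`, `cutoff`, `entropy`, `n_edges`, with attributes
#'   `selected_percentile` and `selected_value`.
#' @export
betweenness_entropy_sweep <- function(d, percentiles = 1:99, bins = 100) {
  if (length(percentiles) == 0) abort("Empty percentile grid.")
  if (nrow(d) < 3) abort("Need at least 3 nodes for the betweenness sweep.")
  vals <- d[upper.tri(d)]
  cuts <- quantile(vals, percentiles / 100, type = 7, names = FALSE)
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  pd <- d[upper.tri(d)]
  labels <- rownames(d)
  res <- lapply(seq_along(percentiles), function(k) {
    keep <- pd <= cuts[k]
    g <- graph_from_pairs(labels, pairs[keep, , drop = FALSE], all_nodes = TRUE)
    b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
    c(entropy = betweenness_hist_entropy(b, bins = bins), n_edges = sum(keep))
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(
    percentile = as.integer(percentiles),
    cutoff = cuts,
    entropy = res[, "entropy"],
    n_edges = as.integer(res[, "n_edges"])
  )
  sel <- which.max(out$entropy)  # first index on ties = smallest percentile
  structure(out,
    class = c("entropy_sweep", class(out)),
    selected_percentile = out$percentile[sel],
    selected_value = out$cutoff[sel]
  )
}

#' @export
print.entropy_sweep <- function(x, ...) {
  cat(sprintf("<entropy_sweep> selected percentile %d (divergence <= %.6g)\n",
              attr(x, "selected_percentile"), attr(x, "selected_value")))
  NextMethod()
}

#' Build the unweighted gene regulatory network
#'
#' Links every pair with divergence at or below `cutoff_value` (lowest
#' divergence = strongest co-expression), drops self-pairs, and removes
#' zero-degree nodes. The result is an unweighted, undirected igraph graph.
#'
#' @param d Symmetric divergence matrix.
#' @param cutoff_value Divergence cutoff in \[0, 1\] (e.g.
#'   `attr(sweep, "selected_value")`).
#' @return An igraph graph whose vertex names are the retained labels.
#' @export
build_grn <- function(d, cutoff_value) {
  stopifnot(cutoff_value >= 0, cutoff_value <= 1)
  labels <- rownames(d)
  pairs <- which(upper.tri(d) & d <= cutoff_value, arr.ind = TRUE)
  g <- graph_from_pairs(labels, pairs, all_nodes = FALSE)
  inform(sprintf("build_grn: %d nodes, %d edges (of %d labels) at cutoff %.6g.",
                 igraph::vcount(g), igraph::ecount(g), length(labels), cutoff_value))
  g
}

#' Single-layer GRN metric panel
#'
#' Per-node degree, betweenness, closeness and eigenvector centrality, plus
#' the degree-assortativity coefficient and the mean-neighbor-degree curve
#' (whose rise/plateau phases diagnose assortative mixing). On a disconnected
#' graph, eigenvector centrality is reported for the largest component (NA
#' elsewhere) with a warning; assortativity is NaN when all degrees are equal.
#'
#' @param g An igraph graph (nonempty).
#' @return An object of class `grn_panel`: list with `nodes` (tibble: `node`,
#'   `degree`, `betweenness`, `closeness`, `eigenvector`), `assortativity`
#'   (scalar), and `knn` (tibble: `degree`, `mean_neighbor_degree`).
#' @export
grn_metric_panel <- function(g) {
  if (igraph::vcount(g) == 0) abort("Empty graph.")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  cls <- suppressWarnings(igraph::closeness(g, normalized = FALSE))
  ev <- rep(NA_real_, igraph::vcount(g))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warn("Graph is disconnected: eigenvector centrality reported for the largest component only.")
    giant <- which(comp$membership == which.max(comp$csize))
    sub <- igraph::induced_subgraph(g, giant)
    ev[giant] <- igraph::eigen_centrality(sub)$vector
  } else {
    ev <- igraph::eigen_centrality(g)$vector
  }
  if (length(unique(deg)) < 2) {
    warn("All degrees equal: assortativity is undefined (NaN).")
    assort <- NaN
  } else {
    assort <- igraph::assortativity_degree(g, directed = FALSE)
  }
  knnk <- suppressWarnings(igraph::knn(g)$knnk)
  knn_tb <- tibble::tibble(
    degree = seq_along(knnk),
    mean_neighbor_degree = as.numeric(knnk)
  ) %>% dplyr::filter(!is.nan(.data$mean_neighbor_degree))
  structure(
    list(
      nodes = tibble::tibble(
        node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
        degree = as.numeric(deg),
        betweenness = as.numeric(btw),
        closeness = as.numeric(cls),
        eigenvector = as.numeric(ev)
      ),
      assortativity = assort,
      knn = knn_tb
    ),
    class = "grn_panel"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple graph from an index-pair matrix over `labels`; with all_nodes = TRUE
# isolated labels are kept as vertices, otherwise only edge endpoints appear.
graph_from_pairs <- function(labels, pairs, all_nodes = FALSE) {
  el <- cbind(labels[pairs[, 1]], labels[pairs[, 2]])
  if (nrow(el) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
  }
  if (all_nodes) {
    missing <- setdiff(labels, igraph::V(g)$name)
    if (length(missing) > 0) g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g
}

#' @export
print.grn_panel <- function(x, ...) {
  cat(sprintf("<grn_panel> %d nodes, assortativity %.4g\n",
              nrow(x$nodes), x$assortativity))
  print(head(x$nodes))
  invisible(x)
}
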