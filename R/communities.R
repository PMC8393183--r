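#' Newman-Girvan modularity of a partition
#'
#' Direct evaluation of
#' \eqn{Q = \frac{1}{2m}\sum_{ij}(A_{ij} - \frac{k_i k_j}{2m})\,
#' \delta(g_i, g_j)}, equivalently
#' \eqn{\sum_c [m_c/m - (K_c/2m)^2]}.
#'
#' @param g igraph graph.
#' @param membership Vector of community labels, one per vertex (in vertex
#'   order).
#' @return Modularity Q in \[-1, 1\].
#' @export
modularity_q <- function(g, membership) {
  m <- igraph::ecount(g)
  if (m == 0) abort("Modularity undefined for an edgeless graph.")
  if (length(membership) != igraph::vcount(g)) {
    abort("`membership` must have one label per vertex.")
  }
  membership <- as.character(membership)
  el <- igraph::ends(g, igraph::E(g), names = FALSE)
  within <- membership[el[, 1]] == membership[el[, 2]]
  k <- igraph::degree(g)
  Kc <- tapply(k, membership, sum)
  ec_full <- setNames(rep(0, length(Kc)), names(Kc))
  # count within-community edges per community (label of either endpoint)
  w_lab <- membership[el[within, 1]]
  if (length(w_lab) > 0) {
    tt <- table(w_lab)
    ec_full[names(tt)] <- as.numeric(tt)
  }
  sum(ec_full / m - (Kc / (2 * m))^2)
}

# Leading (most positive) eigenpair of a symmetric matrix by shifted power
# iteration with a seeded random start. Returns list(value, vector).
leading_eigen_power <- function(B, tol = 1e-10, max_iter = 10000) {
  n <- nrow(B)
  if (n == 1) return(list(value = B[1, 1], vector = 1))
  shift <- max(rowSums(abs(B))) + 1
  M <- B
  diag(M) <- diag(M) + shift
  x <- rnorm(n)
  x <- x / sqrt(sum(x^2))
  for (it in seq_len(max_iter)) {
    y <- M %*% x
    ny <- sqrt(sum(y^2))
    if (ny == 0) break
    y <- as.numeric(y / ny)
    if (sum(abs(y - x)) < tol || sum(abs(y + x)) < tol) {
      x <- y
      break
    }
    x <- y
  }
  list(value = as.numeric(t(x) %*% B %*% x), vector = as.numeric(x))
}

# Fine-tuning pass of the spectral bisection (Newman-style): greedily flip
# single nodes between the two sides while s' B s increases, never emptying a
# side. `s` is a +/-1 vector.
refine_split <- function(B, s, tol = 1e-12) {
  n <- length(s)
  bs <- as.numeric(B %*% s)
  dB <- diag(B)
  max_flips <- 50L * n
  for (it in seq_len(max_flips)) {
    gains <- -4 * s * bs + 4 * dB
    # forbid flips that would empty a side
    if (sum(s > 0) == 1) gains[s > 0] <- -Inf
    if (sum(s < 0) == 1) gains[s < 0] <- -Inf
    best <- which.max(gains)
    if (gains[best] <= tol) break
    s[best] <- -s[best]
    bs <- bs + 2 * s[best] * B[, best]
  }
  s
}

#' Leading-eigenvector community detection
#'
#' Newman's recursive spectral bisection on the modularity matrix
#' \eqn{B = A - P} with \eqn{P_{ij} = k_i k_j / 2m}: each group is split by
#' the sign structure of the leading eigenvector of its generalized
#' modularity matrix, followed by a greedy single-node fine-tuning pass of
#' each bisection, and a branch stops when the leading eigenvalue is not
#' positive (within `eps`) or the split does not increase Q. Disconnected
#' graphs are analyzed per connected component. The eigensolver starts from a
#' seeded random vector, which is the source of run-to-run variability.
#'
#' @param g igraph graph with at least one edge.
#' @param seed Integer seed for the eigensolver start vectors.
#' @param eps Eigenvalue positivity tolerance.
#' @return An object of class `gene_partition`: tibble with columns `node`,
#'   `community`, with attribute `modularity` (Q of the partition, evaluated
#'   directly).
#' @export
leading_eigenvector_communities <- function(g, seed = 1L, eps = 1e-8) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0 || m == 0) abort("Empty graph: no communities to detect.")
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
  k <- rowSums(A)
  B <- A - outer(k, k) / (2 * m)
  membership <- integer(n)
  next_label <- 0L
  local_seed(seed, {
    comp <- igraph::components(g)
    groups <- split(seq_len(n), comp$membership)
    while (length(groups) > 0) {
      idx <- groups[[1]]
      groups <- groups[-1]
      split_done <- FALSE
      if (length(idx) > 1) {
        Bg <- B[idx, idx, drop = FALSE]
        diag(Bg) <- diag(Bg) - rowSums(Bg)
        le <- leading_eigen_power(Bg)
        if (le$value > eps) {
          s <- refine_split(Bg, ifelse(le$vector >= 0, 1, -1))
          dq <- as.numeric(t(s) %*% Bg %*% s) / (4 * m)
          if (dq > eps && length(unique(s)) == 2) {
            groups <- c(groups, list(idx[s > 0]), list(idx[s < 0]))
            split_done <- TRUE
          }
        }
      }
      if (!split_done) {
        next_label <- next_label + 1L
        membership[idx] <- next_label
      }
    }
  })
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  # relabel communities by decreasing size, C1 largest
  sizes <- sort(table(membership), decreasing = TRUE)
  relab <- setNames(paste0("C", seq_along(sizes)), names(sizes))
  out <- tibble::tibble(node = nodes, community = unname(relab[as.character(membership)]))
  structure(out,
    class = c("gene_partition", class(out)),
    modularity = modularity_q(g, out$community)
  )
}

partition_modularity <- function(p) attr(p, "modularity")

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d nodes, %d communities, Q = %.4f\n",
              nrow(x), length(unique(x$community)), attr(x, "modularity")))
  NextMethod()
}

#' Apply community size rules and re-split oversized communities
#'
#' Communities smaller than `min_size` are dissolved (their genes labeled
#' `"unassigned"` and excluded downstream). Communities larger than
#' `max_size` are re-submitted to [leading_eigenvector_communities()] on
#' their induced subgraph; a split is kept only when it yields at least two
#' sub-communities of size `>= min_size` with positive subgraph modularity,
#' recursively until stable.
#'
#' @param p A `gene_partition`.
#' @param g The graph the partition was detected on.
#' @param min_size,max_size Size rules (defaults 10 and 150).
#' @param seed Seed for the re-splitting eigensolver.
#' @return A refined `gene_partition` (Q recomputed over all labels,
#'   `"unassigned"` treated as one group for the evaluation).
#' @export
refine_communities <- function(p, g, min_size = 10, max_size = 150, seed = 1L) {
  stopifnot(inherits(p, "gene_partition"))
  lab <- setNames(p$community, p$node)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (!setequal(names(lab), nodes)) abort("Partition does not cover the graph.")

  # re-split oversized communities until every remaining one is either small
  # enough or confirmed indivisible
  indivisible <- character(0)
  repeat {
    sizes <- table(lab[lab != "unassigned"])
    big <- setdiff(names(sizes)[sizes > max_size], indivisible)
    if (length(big) == 0) break
    for (cl in big) {
      members <- names(lab)[lab == cl]
      sub <- igraph::induced_subgraph(g, members)
      kept <- FALSE
      if (igraph::ecount(sub) > 0) {
        sp <- leading_eigenvector_communities(sub, seed = seed)
        kept <- length(unique(sp$community)) >= 2 &&
          sum(table(sp$community) >= min_size) >= 2 &&
          partition_modularity(sp) > 0
        if (kept) lab[sp$node] <- paste0(cl, ".", sp$community)
      }
      if (!kept) indivisible <- c(indivisible, cl)
    }
  }
  sizes <- table(lab[lab != "unassigned"])
  small <- names(sizes)[sizes < min_size]
  lab[lab %in% small] <- "unassigned"
  inform(sprintf("refine_communities: %d communities kept, %d genes unassigned.",
                 length(setdiff(unique(lab), "unassigned")), sum(lab == "unassigned")))
  out <- tibble::tibble(node = p$node, community = unname(lab[p$node]))
  structure(out,
    class = c("gene_partition", class(out)),
    modularity = modularity_q(g, out$community)
  )
}

#' Repeat community detection and summarize stability
#'
#' Runs the detection `runs` times with seeds `base_seed .. base_seed+runs-1`,
#' records each partition and its modularity, and reports per-gene label
#' agreement: each run's labels are matched (greedy best-Jaccard) to the
#' highest-modularity run, and agreement is the fraction of runs assigning
#' each gene its across-run majority label.
#'
#' @param g igraph graph.
#' @param runs Number of repetitions (>= 2), default 30.
#' @param base_seed First seed.
#' @return An object of class `stability_report`: list with `runs`,
#'   `partitions` (list of `gene_partition`), `modularity_samples`,
#'   `agreement` (per-gene tibble) and `mean_agreement`.
#' @export
community_stability <- function(g, runs = 30, base_seed = 1L) {
  if (runs < 2) abort("`runs` must be at least 2.")
  seeds <- base_seed + seq_len(runs) - 1L
  parts <- lapply(seeds, function(s) leading_eigenvector_communities(g, seed = s))
  qs <- vapply(parts, partition_modularity, numeric(1))
  ref <- parts[[which.max(qs)]]
  matched <- lapply(parts, function(p) match_labels(p, ref))
  lab_mat <- do.call(cbind, matched)
  majority <- apply(lab_mat, 1, function(r) names(which.max(table(r))))
  agree <- rowMeans(lab_mat == majority)
  structure(
    list(
      runs = runs,
      seeds = seeds,
      partitions = parts,
      modularity_samples = qs,
      agreement = tibble::tibble(node = ref$node, majority = majority, agreement = agree),
      mean_agreement = mean(agree)
    ),
    class = "stability_report"
  )
}

# Relabel partition `p`'s communities with the labels of `ref` by greedy
# best-Jaccard matching; unmatched communities keep a fresh label.
match_labels <- function(p, ref) {
  stopifnot(identical(p$node, ref$node))
  pl <- p$community
  rl <- ref$community
  pc <- unique(pl)
  rc <- unique(rl)
  jac <- outer(pc, rc, Vectorize(function(a, b) {
    ia <- pl == a
    ib <- rl == b
    sum(ia & ib) / sum(ia | ib)
  }))
  out <- setNames(rep(NA_character_, length(pc)), pc)
  jw <- jac
  while (any(jw > 0, na.rm = TRUE)) {
    ij <- which(jw == max(jw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out[pc[ij[1]]] <- rc[ij[2]]
    jw[ij[1], ] <- -1
    jw[, ij[2]] <- -1
  }
  miss <- is.na(out)
  out[miss] <- paste0("extra", seq_len(sum(miss)))
  unname(out[pl])
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %d runs, Q mean %.4f (sd %.2g), mean agreement %.3f\n",
              x$runs, mean(x$modularity_samples), stats::sd(x$modularity_samples),
              x$mean_agreement))
  invisible(x)
}

#' Modularity comparison against Erdos-Renyi null models
#'
#' Generates `n_null` G(n, m) random graphs with the node and edge counts of
#' `g`, runs the same leading-eigenvector community stage on each, and
#' compares the observed modularity sample against the null sample with a
#' one-way ANOVA.
#'
#' @param g igraph graph the observed partitions came from.
#' @param observed Numeric vector of observed modularity values.
#' @param n_null Number of null graphs, default 30.
#' @param seed Base seed for null generation and detection.
#' @return List with `f_statistic`, `p_value`, `null_modularity` (vector) and
#'   `observed` (echo).
#' @export
er_null_comparison <- function(g, observed, n_null = 30, seed = 1L) {
  if (length(observed) == 0) abort("`observed` must be nonempty.")
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  nulls <- vapply(seq_len(n_null), function(b) {
    gb <- local_seed(seed + b - 1L, igraph::sample_gnm(n, m))
    partition_modularity(leading_eigenvector_communities(gb, seed = seed + b - 1L))
  }, numeric(1))
  vals <- c(observed, nulls)
  grp <- factor(rep(c("observed", "null"), c(length(observed), n_null)))
  if (stats::sd(vals) == 0) {
    f <- 0
    pv <- 1
  } else {
    tst <- oneway.test(vals ~ grp, var.equal = TRUE)
    f <- unname(tst$statistic)
    pv <- unname(tst$p.value)
  }
  list(f_statistic = f, p_value = pv, null_modularity = nulls, observed = observed)
}
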