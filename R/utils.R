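# Internal helpers shared across stages.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so pipeline stages compose
# deterministically without clobbering user randomness.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce an expression table (tibble with a `gene` id column followed by one
# numeric column per region) to a labelled numeric matrix.
expr_values <- function(expr) {
  stopifnot(is.data.frame(expr), ncol(expr) >= 2)
  genes <- as.character(expr[[1]])
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

# Rebuild the canonical expression tibble from a labelled matrix.
expr_tibble <- function(values) {
  tb <- tibble::as_tibble(values, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene = rownames(values)), tb)
}

assert_expression <- function(expr, arg = "expr") {
  m <- expr_values(expr)
  if (anyNA(m)) {
    abort(sprintf("`%s` contains missing values.", arg))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "`%s` contains a negative value at gene '%s', region '%s'.",
      arg, rownames(m)[bad[1]], colnames(m)[bad[2]]
    ))
  }
  if (anyDuplicated(rownames(m))) {
    abort(sprintf(
      "`%s` contains duplicated gene IDs: %s.",
      arg, paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", ")
    ))
  }
  if (anyDuplicated(colnames(m))) {
    abort(sprintf("`%s` contains duplicated region labels.", arg))
  }
  invisible(m)
}

# Shannon entropy (natural log) of a nonnegative vector after sum
# normalization; the all-zero vector maps to 0 by convention.
shannon_entropy <- function(x) {
  s <- sum(x)
  if (s <= 0) return(0)
  p <- x / s
  p <- p[p > 0]
  -sum(p * log(p))
}

# Histogram-based Shannon entropy of a betweenness distribution: equal-width
# bins spanning the value range; a degenerate range (all values equal, e.g.
# all zero on a complete graph) has entropy 0.
betweenness_hist_entropy <- function(b, bins = 100) {
  if (length(b) == 0) return(0)
  rng <- range(b)
  if (diff(rng) == 0) return(0)
  h <- hist(b, breaks = seq(rng[1], rng[2], length.out = bins + 1),
            plot = FALSE, include.lowest = TRUE)
  shannon_entropy(h$counts)
}
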