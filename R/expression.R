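#' Load a genes-by-regions expression matrix
#'
#' Reads a tab-separated expression table whose header row holds brain-region
#' labels and whose first column holds gene identifiers. Values must be
#' nonnegative expression levels; rows with missing values are rejected.
#'
#' @param path Path to a TSV file (UTF-8, "." decimal point).
#' @return A tibble with a `gene` character column followed by one numeric
#'   column per region.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tR1\tR2", "g1\t1\t2", "g2\t0\t3"), tf)
#' load_expression(tf)
#' @export
load_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("Expression file '%s' not found.", path))
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(tb) < 3) {
    abort("Malformed header: need a gene ID column and at least two region columns.")
  }
  names(tb)[1] <- "gene"
  vals <- suppressWarnings(
    as.matrix(vapply(tb[-1], as.numeric, numeric(nrow(tb))))
  )
  if (nrow(tb) == 1) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, names(tb)[-1]))
  bad <- which(is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-numeric or missing value at gene '%s', region '%s'.",
      tb$gene[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "Negative expression value at gene '%s', region '%s'.",
      tb$gene[neg[1, 1]], colnames(vals)[neg[1, 2]]
    ))
  }
  if (anyDuplicated(tb$gene)) {
    abort(sprintf(
      "Duplicated gene ID(s): %s.",
      paste(unique(tb$gene[duplicated(tb$gene)]), collapse = ", ")
    ))
  }
  rownames(vals) <- tb$gene
  expr_tibble(vals)
}

#' Read a gene blacklist file
#'
#' One gene identifier per line; blank lines and `#` comments are ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of gene IDs.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) abort(sprintf("Blacklist file '%s' not found.", path))
  x <- readLines(path, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Remove blacklisted transcripts
#'
#' Drops rows whose gene ID appears in `blacklist` (e.g. long non-coding
#' transcripts and transcription/translation/replication machinery that would
#' otherwise dominate baseline co-expression). Row order of the survivors is
#' preserved; entries absent from the matrix are ignored.
#'
#' @param expr Expression tibble (see [load_expression()]).
#' @param blacklist Character vector of gene IDs, or a file path readable by
#'   [read_blacklist()].
#' @return Filtered expression tibble.
#' @export
filter_blacklist <- function(expr, blacklist) {
  assert_expression(expr)
  if (length(blacklist) == 1 && is.character(blacklist) && file.exists(blacklist)) {
    blacklist <- read_blacklist(blacklist)
  }
  blacklist <- unique(as.character(blacklist))
  hit <- expr[[1]] %in% blacklist
  inform(sprintf("filter_blacklist: removed %d of %d genes.", sum(hit), nrow(expr)))
  expr[!hit, , drop = FALSE]
}

#' Per-gene log10 expression variance across brain regions
#'
#' For each gene the sample variance (denominator N - 1) of its expression
#' across the N regions, reported on a log10 scale. Genes with zero variance
#' get `finite = FALSE` and a `-Inf` sentinel.
#'
#' @param expr Expression tibble.
#' @return A tibble with columns `gene`, `log_variance`, `finite`.
#' @examples
#' expr <- tibble::tibble(gene = c("a", "b"), R1 = c(1, 5), R2 = c(3, 5))
#' gene_log_variance(expr)  # gene a: log10(2)
#' @export
gene_log_variance <- function(expr) {
  m <- assert_expression(expr)
  if (ncol(m) < 2) abort("Variance needs at least two regions (N >= 2).")
  v <- unname(apply(m, 1, var))
  tibble::tibble(
    gene = rownames(m),
    log_variance = ifelse(v > 0, log10(v), -Inf),
    finite = v > 0
  )
}

#' Derivative-sweep selection of the variant-gene threshold
#'
#' Sweeps candidate log-variance thresholds on a fixed-step grid and counts
#' the genes retained above each. The threshold is placed where the first
#' derivative of the retained-count curve attains its minimum and,
#' simultaneously, the second derivative is highest: among grid points within
#' `tol` of the global first-derivative minimum, the one maximizing the second
#' derivative is selected (ties broken to the smallest threshold). Derivatives
#' are central finite differences, so the selection is restricted to interior
#' grid points. Zero-variance genes are excluded from the sweep and are always
#' non-variant.
#'
#' @param vt Variance tibble from [gene_log_variance()].
#' @param step Grid increment on the log10-variance axis (default 0.1).
#' @param tol Tolerance for the first-derivative-minimum tie set.
#' @return An object of class `threshold_sweep`: a tibble with columns
#'   `threshold`, `retained`, `d1`, `d2` plus attributes
#'   `selected_threshold` and `step`.
#' @export
sweep_variance_threshold <- function(vt, step = 0.1, tol = 1e-9) {
  lv <- vt$log_variance[vt$finite]
  if (length(lv) == 0) abort("No finite log-variances: sweep impossible.")
  if (diff(range(lv)) == 0) abort("All finite log-variances are equal: sweep impossible.")
  grid <- seq(floor(min(lv)), ceiling(max(lv)), by = step)
  if (length(grid) < 3) abort("Fewer than 3 grid points span the log-variance range.")
  retained <- vapply(grid, function(t) sum(lv > t), integer(1))
  n <- length(grid)
  d1 <- rep(NA_real_, n)
  d2 <- rep(NA_real_, n)
  i <- 2:(n - 1)
  d1[i] <- (retained[i + 1] - retained[i - 1]) / (2 * step)
  d2[i] <- (retained[i + 1] - 2 * retained[i] + retained[i - 1]) / step^2
  cand <- which(!is.na(d1) & d1 <= min(d1, na.rm = TRUE) + tol)
  sel <- cand[which.max(d2[cand])]
  # which.max already takes the first (smallest threshold) among exact ties
  out <- tibble::tibble(threshold = grid, retained = retained, d1 = d1, d2 = d2)
  structure(out,
    class = c("threshold_sweep", class(out)),
    selected_threshold = grid[sel],
    step = step
  )
}

#' Selected variance threshold of a sweep
#' @param sweep A `threshold_sweep` object.
#' @return The selected threshold (log10-variance units).
#' @export
selected_threshold <- function(sweep) {
  attr(sweep, "selected_threshold")
}

#' Subset an expression matrix to its variant genes
#'
#' Variant genes are those with finite log10 variance strictly greater than
#' the selected threshold.
#'
#' @param expr Expression tibble.
#' @param vt Variance tibble from [gene_log_variance()]; computed if `NULL`.
#' @param sweep A `threshold_sweep`, or a bare numeric threshold.
#' @return Expression tibble restricted to variant genes.
#' @export
variant_genes <- function(expr, sweep, vt = NULL) {
  if (is.null(vt)) vt <- gene_log_variance(expr)
  thr <- if (inherits(sweep, "threshold_sweep")) selected_threshold(sweep) else as.numeric(sweep)
  keep <- vt$finite & vt$log_variance > thr
  inform(sprintf("variant_genes: %d of %d genes above log10 variance %.3g.",
                 sum(keep), nrow(vt), thr))
  expr[expr[[1]] %in% vt$gene[keep], , drop = FALSE]
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d grid points, selected threshold %.4g\n",
              nrow(x), selected_threshold(x)))
  NextMethod()
}
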