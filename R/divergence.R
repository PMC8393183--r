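#' Normalize a nonnegative profile to a probability distribution
#'
#' @param row Nonnegative numeric vector with at least one positive entry.
#' @param label Optional label used in error messages.
#' @return Vector summing to one, proportional to the input.
#' @export
normalize_profile <- function(row, label = NULL) {
  if (any(row < 0)) abort("Profile has negative entries.")
  s <- sum(row)
  if (s <= 0) {
    abort(sprintf("All-zero profile%s cannot be normalized.",
                  if (is.null(label)) "" else sprintf(" for '%s'", label)))
  }
  row / s
}

#' Jensen-Shannon divergence between two distributions
#'
#' \eqn{JSD(p, q) = \frac12 KL(p \| m) + \frac12 KL(q \| m)} with
#' \eqn{m = (p + q)/2}, using base-2 logarithms so the value lies in
#' \eqn{[0, 1]}: 0 for identical distributions, 1 for disjoint supports.
#' \eqn{0 \log 0} is taken as 0.
#'
#' @param p,q Probability vectors of equal length (each summing to 1 within
#'   1e-9).
#' @return JSD in bits, a scalar in \[0, 1\].
#' @examples
#' jensen_shannon_divergence(c(0.5, 0.5), c(1, 0))  # ~0.311278
#' @export
jensen_shannon_divergence <- function(p, q) {
  if (length(p) != length(q)) abort("Distributions differ in length.")
  if (any(p < 0) || any(q < 0)) abort("Distributions must be nonnegative.")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("Inputs must sum to 1 (within 1e-9); see normalize_profile().")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log2(a[i]) - log2(m[i])))
  }
  d <- 0.5 * kl(p) + 0.5 * kl(q)
  min(max(d, 0), 1)
}

# Entropy in bits of each row of a rowwise-stochastic matrix.
row_entropy_bits <- function(P) {
  L <- ifelse(P > 0, log2(pmax(P, .Machine$double.xmin)), 0)
  -rowSums(P * L * (P > 0))
}

# All-pairs JSD between the rows of a rowwise-stochastic matrix, via
# JSD(p, q) = H((p+q)/2) - (H(p) + H(q))/2 in bits.
jsd_all_pairs <- function(P) {
  n <- nrow(P)
  h <- row_entropy_bits(P)
  D <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    M <- (P[js, , drop = FALSE] + rep(P[i, ], each = length(js))) / 2
    d <- row_entropy_bits(M) - (h[js] + h[i]) / 2
    d <- pmin(pmax(d, 0), 1)
    D[i, js] <- d
    D[js, i] <- d
  }
  D
}

#' Pairwise Jensen-Shannon divergence matrix
#'
#' Normalizes each profile to a distribution and computes all pairwise JSDs,
#' yielding the symmetric zero-diagonal similarity structure from which the
#' gene network (axis `"genes"`: gene rows compared across regions) or the
#' region connectivity layers (axis `"regions"`: region columns compared
#' across the given gene subset) are built.
#'
#' @param expr Expression tibble.
#' @param axis `"genes"` or `"regions"`.
#' @return A symmetric numeric matrix with labels on both dimnames, values in
#'   \[0, 1\], zero diagonal.
#' @export
pairwise_divergence <- function(expr, axis = c("genes", "regions")) {
  axis <- match.arg(axis)
  m <- assert_expression(expr)
  if (axis == "regions") m <- t(m)
  s <- rowSums(m)
  if (any(s <= 0)) {
    abort(sprintf("All-zero profile for '%s'.", rownames(m)[which(s <= 0)[1]]))
  }
  jsd_all_pairs(m / s)
}
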