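#' Canonical edge enumeration for undirected networks
#'
#' Unique node pairs of an n-node network are enumerated 1-based in
#' row-major upper-triangle order: (1,2), (1,3), ..., (1,n), (2,3), ...,
#' (n-1,n). For n = 26 this yields 325 edges, with e.g. pair (2,13) at
#' index 36, (7,8) at 136 and (11,20) at 214.
#'
#' @param i,j node indices with `1 <= i < j <= n` (vectorized).
#' @param n node count.
#' @return `edgeIndex`: integer edge index/indices. `indexToPair`: a
#'   two-column integer matrix with columns `node_i`, `node_j`.
#' @examples
#' edgeIndex(2, 13, 26)   # 36
#' indexToPair(214, 26)   # nodes 11 and 20
#' @export
edgeIndex <- function(i, j, n) {
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (any(i < 1L) || any(j <= i) || any(j > n))
    stop("edge indices must satisfy 1 <= i < j <= n")
  as.integer((i - 1L) * n - (i * (i + 1L)) %/% 2L + j)
}

#' @rdname edgeIndex
#' @param k edge index/indices in 1..n(n-1)/2 (vectorized).
#' @export
indexToPair <- function(k, n) {
  k <- as.integer(k); n <- as.integer(n)
  m <- (n * (n - 1L)) %/% 2L
  if (any(k < 1L) || any(k > m))
    stop(sprintf("edge index out of range 1..%d", m))
  ## first node: largest i with cumulative count below k
  ## edges with first node < i: (i-1)*n - i*(i+1)/2 + ... closed form via
  ## inversion of the triangular numbering
  kk <- m - k                      # count from the end: 0-based
  i2 <- floor((sqrt(8 * kk + 1) - 1) / 2)   # rows counted from the bottom
  i <- n - 1L - as.integer(i2)
  offset <- (i - 1L) * n - (i * (i + 1L)) %/% 2L
  j <- as.integer(k - offset)
  cbind(node_i = i, node_j = j)
}

#' @rdname edgeIndex
#' @export
edgePairs <- function(n) {
  n <- as.integer(n)
  indexToPair(seq_len((n * (n - 1L)) %/% 2L), n)
}

#' @rdname edgeIndex
#' @export
nEdges <- function(n) (as.integer(n) * (as.integer(n) - 1L)) %/% 2L

## Fold a symmetric matrix into the canonical edge vector and back.
symToEdge <- function(m) {
  n <- nrow(m)
  t(m)[lower.tri(t(m))]   # row-major upper triangle
}

edgeToSym <- function(v, n, diag = 1) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- NA   # placeholder
  idx <- edgePairs(n)
  m[cbind(idx[, 1], idx[, 2])] <- v
  m[cbind(idx[, 2], idx[, 1])] <- v
  diag(m) <- diag
  m
}
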