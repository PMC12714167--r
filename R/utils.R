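# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a stage-specific seed from the pipeline master seed. Stages are
# numbered; the scheme is a plain counter so any stage can be re-run in
# isolation from its cached upstream outputs. Kept < 2^31 (R integers).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((as.numeric(seed) * 1009 + 97 * stage) %% .Machine$integer.max)
}

# Benjamini-Hochberg wrapper kept as a single choke point so every module
# adjusts p-values the same way.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

is_square_matrix <- function(x) is.matrix(x) && nrow(x) == ncol(x)

# Upper-triangle edge index (i < j) for an N-node network, as a 2-column
# matrix in column-major upper.tri order. All edge vectors in the NBS module
# are laid out in this order.
edge_index <- function(n) {
  ut <- upper.tri(matrix(0, n, n))
  cbind(row(ut)[ut], col(ut)[ut])
}

# Rebuild a symmetric zero-diagonal matrix from an upper-triangle vector.
edges_to_matrix <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m + t(m)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two labelings of the same items; 1 for
#' identical partitions (up to label names), about 0 for independent ones.
#' Used to score recovery of planted module memberships.
#'
#' @param a,b label vectors of equal length.
#' @return scalar adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(length(a), 2)
  max_index <- (si + sj) / 2
  if (max_index == expected) return(1)
  (sij - expected) / (max_index - expected)
}

#' Jaccard similarity of two edge sets
#'
#' Edges are unordered node pairs given as 2-column matrices; orientation
#' is ignored.
#'
#' @param edges_a,edges_b 2-column matrices of node indices.
#' @return |intersection| / |union|, with 1 for two empty sets.
#' @export
edge_set_jaccard <- function(edges_a, edges_b) {
  key <- function(e) {
    if (is.null(e) || nrow(e) == 0L) return(character(0))
    e <- t(apply(as.matrix(e), 1, sort))
    unique(paste(e[, 1], e[, 2], sep = "-"))
  }
  ka <- key(edges_a); kb <- key(edges_b)
  if (!length(ka) && !length(kb)) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}
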