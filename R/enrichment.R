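# Pathway over-representation (hypergeometric upper tail with the standard
# reporting filters) and expression-weighted cell-type enrichment via a
# uniform bootstrap over background gene lists.

#' Hypergeometric over-representation analysis
#'
#' For each gene set: upper-tail hypergeometric p-value for an overlap at
#' least as large as observed, the enrichment factor
#' `(overlap / list size) / (term size / universe size)`, and pass flags
#' for the reporting filters (p below `p_cutoff`, overlap at least
#' `min_overlap`, enrichment factor above `min_enrichment`). Results are
#' sorted by p-value; `top_n` optionally restricts the report to the top
#' terms that pass all filters.
#'
#' @param gene_list character vector of query genes (subset of universe).
#' @param gene_sets named list of character vectors (e.g. [read_gmt()]);
#'   members outside the universe are ignored.
#' @param universe background gene ids.
#' @param p_cutoff,min_overlap,min_enrichment reporting filters
#'   (defaults 0.01, 3, 1.0).
#' @param top_n optional cap on reported passing terms (e.g. 5).
#' @return data.frame of class `ora_result`: `term`, `overlap`,
#'   `term_size`, `list_size`, `universe_size`, `p`, `enrichment_factor`,
#'   `pass`.
#' @export
ora <- function(gene_list, gene_sets, universe, p_cutoff = 0.01,
                min_overlap = 3, min_enrichment = 1.0, top_n = NULL) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(gene_list, universe)
  if (length(outside)) {
    stop("gene_list contains genes outside the universe: ", outside[1L])
  }
  gene_list <- unique(gene_list)
  N <- length(universe)
  n <- length(gene_list)
  rows <- lapply(names(gene_sets), function(nm) {
    term <- intersect(gene_sets[[nm]], universe)
    K <- length(term)
    k <- length(intersect(term, gene_list))
    # P(X >= k) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    ef <- if (n == 0 || K == 0) 0 else (k / n) / (K / N)
    data.frame(term = nm, overlap = k, term_size = K, list_size = n,
               universe_size = N, p = p, enrichment_factor = ef)
  })
  out <- do.call(rbind, rows)
  out$pass <- out$p < p_cutoff & out$overlap >= min_overlap &
    out$enrichment_factor > min_enrichment
  out <- out[order(out$p), , drop = FALSE]
  if (!is.null(top_n)) {
    keep_top <- which(out$pass)[seq_len(min(top_n, sum(out$pass)))]
    out <- out[sort(keep_top), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Cell-type specificity matrix
#'
#' Row-normalizes a genes x cell-types mean-expression matrix to
#' proportions: `s_gc = mean expression of g in c / sum_c mean
#' expression`. All-zero genes are dropped with a warning; negative
#' values are an error.
#'
#' @param celltype_expression nonnegative genes x cell-types matrix.
#' @return specificity matrix whose rows sum to 1.
#' @export
specificity <- function(celltype_expression) {
  m <- as.matrix(celltype_expression)
  if (any(m < 0)) stop("expression values must be nonnegative")
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s) dropped from the specificity matrix")
    m <- m[!zero, , drop = FALSE]
    totals <- totals[!zero]
  }
  m / totals
}

#' Expression-weighted cell-type enrichment by bootstrap
#'
#' The observed statistic per cell type is the mean specificity of the
#' target genes. Bootstrap lists of the same length are sampled uniformly
#' without replacement from the background; the enrichment p-value is
#' `(1 + #\{bootstrap mean >= observed\}) / (n_boot + 1)`, the
#' sd-from-mean z is `(observed - mean_boot) / sd_boot`, and p-values are
#' BH-adjusted across cell types.
#'
#' @param target_genes character vector (subset of the specificity rows).
#' @param spec_matrix specificity matrix from [specificity()].
#' @param n_boot bootstrap count (>= 100).
#' @param seed RNG seed.
#' @return data.frame of class `ewce_result`: `cell_type`, `observed`,
#'   `boot_mean`, `boot_sd`, `z`, `p`, `p_adj`.
#' @export
ewce_bootstrap <- function(target_genes, spec_matrix, n_boot = 1000,
                           seed = 1) {
  if (n_boot < 100L) stop("n_boot must be at least 100")
  genes <- rownames(spec_matrix)
  missing <- setdiff(target_genes, genes)
  if (length(missing)) {
    stop("target genes absent from the specificity matrix: ", missing[1L])
  }
  L <- length(unique(target_genes))
  if (L > length(genes)) stop("target list longer than the background")
  set.seed(as.integer(seed))
  observed <- colMeans(spec_matrix[unique(target_genes), , drop = FALSE])
  # one bootstrap list per row: L uniform draws without replacement
  boot_means <- matrix(0, n_boot, ncol(spec_matrix))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(genes), L)
    boot_means[b, ] <- colMeans(spec_matrix[idx, , drop = FALSE])
  }
  p <- vapply(seq_along(observed), function(cc) {
    (1 + sum(boot_means[, cc] >= observed[cc])) / (n_boot + 1)
  }, numeric(1))
  bm <- colMeans(boot_means)
  bs <- apply(boot_means, 2, stats::sd)
  z <- ifelse(bs > 0, (observed - bm) / bs, 0)
  out <- data.frame(cell_type = colnames(spec_matrix), observed = observed,
                    boot_mean = bm, boot_sd = bs, z = z, p = p,
                    p_adj = bh_adjust(p), row.names = NULL)
  class(out) <- c("ewce_result", "data.frame")
  out
}

#' @export
print.ewce_result <- function(x, ...) {
  cat("Expression-weighted cell-type enrichment\n")
  df <- as.data.frame(x)
  df$sig <- ifelse(df$p_adj < 0.05, "*", "")
  print(format(df, digits = 3), row.names = FALSE)
  invisible(x)
}
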