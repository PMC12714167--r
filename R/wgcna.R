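# Weighted gene coexpression network construction over brain regions:
# soft-threshold selection by scale-free topology fit, topological overlap,
# average-linkage module detection with a simplified tree cut, module
# eigengenes, module-trait association with BH-FDR, and GS/MM hub-gene
# screening. Samples are regions; genes are variables.

# Standard module color order of the coexpression literature; background
# genes are "grey".
MODULE_COLORS <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                   "black", "pink", "magenta", "purple", "greenyellow",
                   "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                   "grey60", "lightgreen", "lightyellow", "royalblue")

#' Unsigned coexpression adjacency
#'
#' `a_ij = |cor(g_i, g_j)|^power` across regions, with unit diagonal.
#'
#' @param expr genes x regions matrix.
#' @param power soft-threshold exponent (positive).
#' @return genes x genes adjacency in [0, 1].
#' @export
adjacency_matrix <- function(expr, power) {
  stopifnot(power > 0)
  a <- abs(stats::cor(t(expr)))^power
  diag(a) <- 1
  a
}

# Scale-free topology fit index for one connectivity vector: bin k, regress
# log10(frequency) on log10(mean k per bin), return R^2 signed by the
# slope (scale-free networks have negative slope). Degenerate all-equal k
# yields 0.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 2L) return(0)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3L) return(0)
  x <- log10(mean_k[ok]); y <- log10(freq[ok])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2L]) * r2
}

#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power, computes node connectivity `k_i = sum_j a_ij`
#' (diagonal excluded) and the signed R-squared of the log-log regression
#' of the binned degree distribution. Returns the smallest power whose fit
#' reaches `target_r2`; if none does, the power with the maximum fit, with
#' a warning.
#'
#' @param expr genes x regions matrix (>= 20 genes).
#' @param powers candidate powers (default 1..20).
#' @param target_r2 required scale-free fit (default 0.85).
#' @return selected power (integer); the per-power fit table is attached
#'   as attribute `fit_table`.
#' @export
select_soft_power <- function(expr, powers = 1:20, target_r2 = 0.85) {
  if (!length(powers)) stop("candidate_powers must be nonempty")
  if (nrow(expr) < 20L) stop("need at least 20 genes")
  cor_abs <- abs(stats::cor(t(expr)))
  diag(cor_abs) <- 0
  fits <- vapply(powers, function(p) scale_free_fit(rowSums(cor_abs^p)),
                 numeric(1))
  tab <- data.frame(power = powers, sft_r2 = fits)
  hit <- which(fits >= target_r2)
  if (length(hit)) {
    beta <- powers[hit[1L]]
  } else {
    beta <- powers[which.max(fits)]
    warning("no candidate power reaches scale-free fit ", target_r2,
            "; using power ", beta, " (max fit ", round(max(fits), 3), ")")
  }
  attr(beta, "fit_table") <- tab
  beta
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for i != j with `k_i = sum_{j != i} a_ij`, and `TOM_ii = 1`. The
#' clustering dissimilarity is `1 - TOM`.
#'
#' @param adjacency genes x genes adjacency in [0, 1] with unit diagonal.
#' @return TOM matrix in [0, 1].
#' @export
tom_matrix <- function(adjacency) {
  if (any(adjacency < 0 | adjacency > 1)) {
    stop("adjacency entries must lie in [0, 1]")
  }
  a <- adjacency
  diag(a) <- 1
  k <- rowSums(a) - 1
  # (A^2)_ij counts u = i and u = j once each as a_ij (unit diagonal), so
  # sum_{u != i,j} a_iu a_uj + a_ij = (A^2)_ij - a_ij
  num <- a %*% a - a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  # clamp float noise
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect modules by average-linkage clustering of the TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut by a
#' simplified static rule (all branches merging below `cut_height`,
#' default 0.99, deep split off); clusters smaller than
#' `min_module_size` fall into the "grey" background. Surviving modules
#' are labelled by descending size using the standard color order.
#'
#' @param dissimilarity genes x genes dissimilarity (1 - TOM).
#' @param min_module_size smallest gene count for a proper module
#'   (default 100).
#' @param cut_height static tree-cut height.
#' @return named character vector gene -> module color ("grey" =
#'   background); the dendrogram is attached as attribute `dendro`.
#' @export
detect_modules <- function(dissimilarity, min_module_size = 100,
                           cut_height = 0.99) {
  stopifnot(is_square_matrix(dissimilarity))
  genes <- rownames(dissimilarity) %||% paste0("g", seq_len(nrow(dissimilarity)))
  if (nrow(dissimilarity) < min_module_size) {
    warning("fewer genes than min_module_size; all genes are background")
    labels <- stats::setNames(rep("grey", length(genes)), genes)
    return(labels)
  }
  dendro <- stats::hclust(stats::as.dist(dissimilarity), method = "average")
  raw <- stats::cutree(dendro, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- rep("grey", length(genes))
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    colors <- c(MODULE_COLORS,
                paste0("module", seq_len(max(0, length(keep) -
                                               length(MODULE_COLORS)))))
    for (i in seq_along(keep)) {
      labels[raw == as.integer(keep[i])] <- colors[i]
    }
  }
  labels <- stats::setNames(labels, genes)
  attr(labels, "dendro") <- dendro
  labels
}

#' Module eigengene
#'
#' First principal component of the module genes' per-gene standardized
#' region profiles, computed by SVD, with the sign oriented so the mean
#' correlation with the member genes is positive. Constant gene rows are
#' dropped with a warning.
#'
#' @param expr genes x regions matrix.
#' @param module_genes character vector of member genes (>= 2).
#' @return numeric eigengene vector over regions; proportion of variance
#'   explained is attached as attribute `var_explained`.
#' @export
module_eigengene <- function(expr, module_genes) {
  if (length(module_genes) < 2L) stop("a module needs at least 2 genes")
  x <- expr[module_genes, , drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene row(s) dropped from the eigengene")
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2L) stop("fewer than 2 non-constant genes in module")
  }
  z <- t(scale(t(x)))
  sv <- svd(z, nu = 0, nv = 1)
  me <- sv$v[, 1L]
  if (mean(stats::cor(me, t(z))) < 0) me <- -me
  attr(me, "var_explained") <- sv$d[1L]^2 / sum(sv$d^2)
  me
}

#' Eigengenes of every proper module
#'
#' @param expr genes x regions matrix.
#' @param labels gene -> module vector from [detect_modules()].
#' @return regions x modules matrix of eigengenes (background excluded).
#' @export
module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) return(matrix(numeric(0), ncol(expr), 0))
  out <- vapply(mods, function(m) {
    module_eigengene(expr, names(labels)[labels == m])
  }, numeric(ncol(expr)))
  rownames(out) <- colnames(expr)
  out
}

#' Merge modules with near-identical eigengenes
#'
#' Average-linkage clustering of eigengene correlation dissimilarity
#' (1 - cor); module groups merging below `merge_height` are fused and the
#' merged modules relabelled by descending size.
#'
#' @param expr genes x regions matrix.
#' @param labels gene -> module vector.
#' @param merge_height eigengene dissimilarity below which modules fuse
#'   (default 0.25).
#' @return updated gene -> module vector.
#' @export
merge_similar_modules <- function(expr, labels, merge_height = 0.25) {
  mods <- setdiff(unique(labels), "grey")
  if (length(mods) < 2L) return(labels)
  me <- module_eigengenes(expr, labels)
  diss <- 1 - stats::cor(me)
  cl <- stats::cutree(stats::hclust(stats::as.dist(diss), method = "average"),
                      h = merge_height)
  if (max(cl) == length(mods)) return(labels) # nothing merges
  merged <- labels
  for (grp in unique(cl)) {
    members <- mods[cl == grp]
    merged[labels %in% members] <- members[1L]
  }
  # relabel by descending size with the canonical color order
  sizes <- sort(table(merged[merged != "grey"]), decreasing = TRUE)
  colors <- c(MODULE_COLORS,
              paste0("module", seq_len(max(0, length(sizes) -
                                             length(MODULE_COLORS)))))
  out <- merged
  for (i in seq_along(sizes)) {
    out[merged == names(sizes)[i]] <- colors[i]
  }
  stats::setNames(out, names(labels))
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait, with
#' Benjamini-Hochberg adjustment across all module x trait cells. Regions
#' missing in the trait are excluded pairwise.
#'
#' @param eigengenes regions x modules matrix.
#' @param traits per-region trait vector, or regions x traits matrix.
#' @return data.frame `module`, `trait`, `r`, `p`, `p_adj`.
#' @export
module_trait <- function(eigengenes, traits) {
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1,
                                             dimnames = list(NULL, "trait"))
  rows <- list()
  for (m in colnames(eigengenes)) {
    for (tr in colnames(traits)) {
      ok <- is.finite(eigengenes[, m]) & is.finite(traits[, tr])
      if (sum(ok) < 4L) stop("fewer than 4 overlapping regions for module ",
                             m, " and trait ", tr)
      ct <- correlate(eigengenes[ok, m], traits[ok, tr])
      rows[[paste(m, tr)]] <- data.frame(module = m, trait = tr,
                                         r = ct$r, p = ct$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Hub-gene screen by module membership and gene significance
#'
#' MM = correlation of a gene with its own module eigengene; GS =
#' correlation of the gene with the regional trait. A gene is a hub of its
#' module iff |MM| > `mm_threshold` and |GS| > `gs_threshold`. Background
#' genes are excluded (not an error).
#'
#' @param expr genes x regions matrix.
#' @param labels gene -> module vector.
#' @param trait per-region trait vector.
#' @param mm_threshold module-membership cutoff (default 0.8).
#' @param gs_threshold gene-significance cutoff (default 0.5).
#' @return data.frame `gene`, `module`, `MM`, `GS`, `hub`.
#' @export
hub_genes <- function(expr, labels, trait, mm_threshold = 0.8,
                      gs_threshold = 0.5) {
  stopifnot(mm_threshold > 0, mm_threshold < 1,
            gs_threshold > 0, gs_threshold < 1)
  mods <- setdiff(unique(labels), "grey")
  ok <- is.finite(trait)
  rows <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    me <- module_eigengene(expr, genes)
    mm <- as.numeric(stats::cor(me[ok], t(expr[genes, ok, drop = FALSE])))
    gs <- as.numeric(stats::cor(trait[ok], t(expr[genes, ok, drop = FALSE])))
    data.frame(gene = genes, module = m, MM = mm, GS = gs,
               hub = abs(mm) > mm_threshold & abs(gs) > gs_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a weighted coexpression network and its modules end to end
#'
#' Soft-power selection (unless `power` is given), unsigned adjacency,
#' TOM, average-linkage module detection, eigengene-based module merging,
#' eigengenes, module-trait association, and the GS/MM hub screen.
#'
#' @param expr genes x regions matrix.
#' @param trait per-region trait vector (optional; without it the
#'   module-trait and hub stages are skipped).
#' @param power soft threshold (default 12, the conventional choice this
#'   package's demo configuration records). Pass NULL to select it by
#'   scale-free fit — meaningful for transcriptome-scale data whose
#'   connectivity is heavy-tailed, but not for low-rank block fixtures,
#'   whose degree distribution is bimodal and never fits a power law.
#' @param min_module_size,cut_height,merge_height see
#'   [detect_modules()] / [merge_similar_modules()].
#' @param mm_threshold,gs_threshold hub screen cutoffs.
#' @param target_r2 scale-free fit target for power selection.
#' @return object of class `coexpression_modules`: list with `power`,
#'   `labels`, `eigengenes`, `module_trait`, `hubs`, `module_sizes`,
#'   `sft_table`.
#' @export
wgcna_modules <- function(expr, trait = NULL, power = 12,
                          min_module_size = 100, cut_height = 0.99,
                          merge_height = 0.25, mm_threshold = 0.8,
                          gs_threshold = 0.5, target_r2 = 0.85) {
  sft <- NULL
  if (is.null(power)) {
    power <- select_soft_power(expr, target_r2 = target_r2)
    sft <- attr(power, "fit_table")
  }
  adj <- adjacency_matrix(expr, power)
  tom <- tom_matrix(adj)
  labels <- detect_modules(1 - tom, min_module_size = min_module_size,
                           cut_height = cut_height)
  dendro <- attr(labels, "dendro")
  labels <- merge_similar_modules(expr, labels, merge_height = merge_height)
  me <- module_eigengenes(expr, labels)
  mt <- NULL; hubs <- NULL
  if (!is.null(trait) && ncol(me) > 0) {
    mt <- module_trait(me, trait)
    hubs <- hub_genes(expr, labels, trait, mm_threshold, gs_threshold)
  }
  structure(list(power = as.integer(power), labels = labels,
                 eigengenes = me, module_trait = mt, hubs = hubs,
                 module_sizes = sort(table(labels[labels != "grey"]),
                                     decreasing = TRUE),
                 n_background = sum(labels == "grey"),
                 sft_table = sft, dendro = dendro),
            class = "coexpression_modules")
}

#' @export
print.coexpression_modules <- function(x, ...) {
  cat("Coexpression modules (soft power ", x$power, ")\n", sep = "")
  if (length(x$module_sizes)) {
    cat("  modules:",
        paste(sprintf("%s(%d)", names(x$module_sizes), x$module_sizes),
              collapse = " "), "\n")
  } else {
    cat("  no modules detected\n")
  }
  cat("  background (grey):", x$n_background, "genes\n")
  if (!is.null(x$module_trait)) {
    sig <- x$module_trait[x$module_trait$p_adj < 0.05, , drop = FALSE]
    cat("  trait-associated modules (FDR < 0.05):",
        if (nrow(sig)) paste(sprintf("%s (r = %.2f)", sig$module, sig$r),
                             collapse = ", ") else "none", "\n")
  }
  if (!is.null(x$hubs)) cat("  hub genes:", sum(x$hubs$hub), "\n")
  invisible(x)
}

#' @export
summary.coexpression_modules <- function(object, ...) {
  out <- list(power = object$power,
              module_sizes = object$module_sizes,
              n_background = object$n_background,
              module_trait = object$module_trait,
              n_hubs = if (is.null(object$hubs)) NA_integer_
                       else sum(object$hubs$hub))
  class(out) <- "summary.coexpression_modules"
  out
}

#' @export
print.summary.coexpression_modules <- function(x, ...) {
  cat("Soft power:", x$power, "\n")
  cat("Module sizes:\n")
  print(x$module_sizes)
  cat("Background genes:", x$n_background, "\n")
  if (!is.null(x$module_trait)) {
    cat("Module-trait associations:\n")
    print(x$module_trait, digits = 3)
  }
  cat("Hub genes:", x$n_hubs, "\n")
  invisible(x)
}

#' Regional trait from an NBS result
#'
#' The default circuit trait for module-trait analysis: per region, the
#' sum of |t| over the significant components' edges incident to it, and
#' zero elsewhere. When no component is significant the fallback uses all
#' edges' |t| (a continuous involvement map) so downstream calibration
#' still has a well-defined trait.
#'
#' @param nbs an `nbs_result`.
#' @param alpha FWER threshold selecting components.
#' @return named numeric vector over the parcellation's regions.
#' @export
trait_from_nbs <- function(nbs, alpha = 0.05) {
  stopifnot(inherits(nbs, "nbs_result"))
  labels <- nbs$stat_map$region_labels
  n <- length(labels)
  trait <- stats::setNames(numeric(n), labels)
  sig <- significant_components(nbs, alpha)
  if (length(sig)) {
    tmat <- nbs$stat_map$t
    for (comp in sig) {
      for (e in seq_len(nrow(comp$edges))) {
        i <- comp$edges[e, 1L]; j <- comp$edges[e, 2L]
        trait[i] <- trait[i] + abs(tmat[i, j])
        trait[j] <- trait[j] + abs(tmat[i, j])
      }
    }
  } else {
    tmat <- abs(nbs$stat_map$t)
    trait <- rowSums(tmat)
    names(trait) <- labels
  }
  trait
}
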