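# Network-based statistic: mass-univariate two-sample t-tests at every
# edge, a primary component-forming threshold (two-sided p < 0.001 by
# default), connected components of the suprathreshold graph, and
# familywise error control from the permutation null distribution of the
# maximum component size (size = edge count).

# Stack a list of structural networks into a subjects x edges matrix over
# the upper triangle (edge_index order).
stack_edges <- function(networks) {
  n <- length(networks[[1L]]$region_labels)
  ut <- upper.tri(matrix(0, n, n))
  t(vapply(networks, function(net) {
    if (nrow(net$A) != n) {
      stop("network dimension mismatch: ", nrow(net$A), " vs ", n)
    }
    net$A[ut]
  }, numeric(sum(ut))))
}

# Vectorized pooled-variance two-sample t for many edges at once.
# X: subjects x edges; a: logical group-A indicator. Zero pooled variance
# yields t = 0.
pooled_t <- function(X, a) {
  na <- sum(a); nb <- sum(!a)
  ma <- colMeans(X[a, , drop = FALSE])
  mb <- colMeans(X[!a, , drop = FALSE])
  ssa <- colSums(X[a, , drop = FALSE]^2) - na * ma^2
  ssb <- colSums(X[!a, , drop = FALSE]^2) - nb * mb^2
  vp <- (ssa + ssb) / (na + nb - 2)
  se <- sqrt(vp * (1 / na + 1 / nb))
  tt <- (ma - mb) / se
  tt[!is.finite(tt)] <- 0
  tt
}

#' Edgewise two-sample t-statistics between two groups
#'
#' Pooled-variance two-sample t at every upper-triangle edge. Edges with
#' zero pooled variance (e.g. absent in all subjects) get statistic 0 and
#' p-value 1.
#'
#' @param networks_a,networks_b lists of [structural_network()] over the
#'   same parcellation, at least 3 subjects each.
#' @return list with `t` (symmetric N x N matrix of t-statistics), `p`
#'   (matching two-sided p matrix), `df`, `region_labels`.
#' @export
edgewise_tstats <- function(networks_a, networks_b) {
  if (length(networks_a) < 3L || length(networks_b) < 3L) {
    stop("each group needs at least 3 subjects")
  }
  labels <- networks_a[[1L]]$region_labels
  X <- stack_edges(c(networks_a, networks_b))
  a <- rep(c(TRUE, FALSE), c(length(networks_a), length(networks_b)))
  df <- length(a) - 2L
  tt <- pooled_t(X, a)
  pp <- 2 * stats::pt(-abs(tt), df)
  pp[tt == 0] <- 1
  n <- length(labels)
  tm <- edges_to_matrix(tt, n); dimnames(tm) <- list(labels, labels)
  pm <- edges_to_matrix(pp, n); diag(pm) <- 1
  dimnames(pm) <- dimnames(tm)
  list(t = tm, p = pm, df = df, region_labels = labels)
}

# Null distribution of the maximum suprathreshold component size under
# label permutation. All permutations' group sums are computed at once by
# blocked matrix multiplication (indicator matrix %*% data); only the few
# suprathreshold edges per permutation reach the component search.
perm_max_component_sizes <- function(X, na, n_nodes, eidx, tcrit, n_perm,
                                     block = 500L) {
  n_subj <- nrow(X)
  nb <- n_subj - na
  X2 <- X^2
  tot_s <- colSums(X)
  tot_ss <- colSums(X2)
  inv_n <- 1 / na + 1 / nb
  df <- n_subj - 2L
  null_max <- integer(n_perm)
  done <- 0L
  while (done < n_perm) {
    m <- min(block, n_perm - done)
    P <- matrix(0, m, n_subj)
    for (b in seq_len(m)) P[b, sample.int(n_subj, na)] <- 1
    Sa <- P %*% X
    SSa <- P %*% X2
    Sb <- rep(tot_s, each = m) - Sa
    vp <- (SSa - Sa^2 / na + (rep(tot_ss, each = m) - SSa) - Sb^2 / nb) / df
    tt <- (Sa / na - Sb / nb) / sqrt(vp * inv_n)
    sup <- is.finite(tt) & abs(tt) > tcrit
    for (b in seq_len(m)) {
      k <- sum(sup[b, ])
      null_max[done + b] <- if (k <= 1L) k else {
        comps <- edge_components(eidx[sup[b, ], , drop = FALSE], n_nodes)
        max(vapply(comps, `[[`, integer(1), "n_edges"))
      }
    }
    done <- done + m
  }
  null_max
}

# Connected components of a set of suprathreshold edges, as edge-count
# sized components. edges: 2-column matrix of node indices.
edge_components <- function(edges, n_nodes, tvals = NULL) {
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_nodes - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[edges[, 1L]]
  lapply(unique(comp_of_edge), function(cid) {
    sel <- comp_of_edge == cid
    e <- edges[sel, , drop = FALSE]
    list(edges = e,
         nodes = sort(unique(as.vector(e))),
         n_edges = nrow(e),
         mean_t = if (is.null(tvals)) NA_real_ else mean(tvals[sel]))
  })
}

#' Suprathreshold connected components of an edge statistic map
#'
#' Thresholds the two-sided edge p-values at `primary_p` and returns the
#' connected components of the surviving edges (single-edge components
#' allowed). The sign of each component's mean t is retained so the
#' direction of the group difference is recoverable.
#'
#' @param stat_map result of [edgewise_tstats()].
#' @param primary_p primary component-forming threshold (uncorrected
#'   two-sided p).
#' @return list of components, each with `edges` (2-column index matrix),
#'   `nodes`, `n_edges`, `mean_t`.
#' @export
threshold_components <- function(stat_map, primary_p = 0.001) {
  n <- nrow(stat_map$t)
  tcrit <- stats::qt(1 - primary_p / 2, stat_map$df)
  ut <- upper.tri(stat_map$t)
  sel <- which(abs(stat_map$t) > tcrit & ut, arr.ind = TRUE)
  edge_components(sel, n, stat_map$t[sel])
}

#' Network-based statistic with max-component permutation FWER
#'
#' Permutes group labels uniformly (the observed labelling is never
#' counted as a permutation), builds the null distribution of the maximum
#' suprathreshold component size, and assigns each observed component the
#' familywise-corrected p-value
#' (1 + #\{permutation max >= observed size\}) / (n_perm + 1), which is
#' never zero.
#'
#' @param networks list of [structural_network()] for both groups.
#' @param labels logical or two-level vector marking group membership,
#'   aligned with `networks`.
#' @param primary_p primary component-forming threshold.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutations.
#' @param contrast_name optional label carried into the result.
#' @return object of class `nbs_result`: `components` (each with
#'   `fwer_p`), `stat_map`, `null_max_size`, `primary_p`, `n_perm`,
#'   `seed`, `contrast`.
#' @export
nbs_test <- function(networks, labels, primary_p = 0.001, n_perm = 1000,
                     seed = 1, contrast_name = "custom") {
  if (n_perm < 100L) stop("n_perm must be at least 100")
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2L) stop("labels must define two groups")
  a <- labels == levels(droplevels(labels))[1L]
  if (sum(a) < 3L || sum(!a) < 3L) stop("each group needs at least 3 subjects")
  n_subj <- length(networks)
  if (n_subj != length(a)) stop("networks/labels length mismatch")
  n_exch <- choose(n_subj, sum(a))
  if (n_exch < n_perm) {
    warning("only ", n_exch, " distinct label assignments exist; ",
            "permutation p-values are coarse")
  }
  region_labels <- networks[[1L]]$region_labels
  n <- length(region_labels)
  X <- stack_edges(networks)
  df <- n_subj - 2L
  tcrit <- stats::qt(1 - primary_p / 2, df)
  eidx <- edge_index(n)

  observed_t <- pooled_t(X, a)
  sel <- abs(observed_t) > tcrit
  components <- edge_components(eidx[sel, , drop = FALSE], n, observed_t[sel])

  set.seed(as.integer(seed))
  null_max <- perm_max_component_sizes(X, sum(a), n, eidx, tcrit, n_perm)
  for (i in seq_along(components)) {
    obs <- components[[i]]$n_edges
    components[[i]]$fwer_p <- (1 + sum(null_max >= obs)) / (n_perm + 1)
  }
  structure(list(components = components,
                 stat_map = list(t = edges_to_matrix(observed_t, n),
                                 df = df, region_labels = region_labels),
                 null_max_size = null_max, primary_p = primary_p,
                 n_perm = n_perm, seed = seed, contrast = contrast_name),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("Network-based statistic (", x$contrast, " contrast)\n", sep = "")
  cat("  primary threshold p <", format(x$primary_p),
      " | ", x$n_perm, "permutations\n")
  if (!length(x$components)) {
    cat("  no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      comp <- x$components[[i]]
      cat(sprintf("  component %d: %d edges over %d nodes, mean t %+.2f, FWER p = %.4g%s\n",
                  i, comp$n_edges, length(comp$nodes), comp$mean_t,
                  comp$fwer_p, if (comp$fwer_p < 0.05) " *" else ""))
    }
  }
  invisible(x)
}

#' Significant components of an NBS result
#'
#' @param x an `nbs_result`.
#' @param alpha FWER threshold.
#' @return list of components with `fwer_p < alpha`.
#' @export
significant_components <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "nbs_result"))
  Filter(function(comp) comp$fwer_p < alpha, x$components)
}

#' Build the SI / SB circuit contrasts from a phenotype table
#'
#' The SI contrast compares patients with vs without suicidal ideation
#' (MDDSI vs MDDNSI). The SB contrast compares patients with vs without
#' suicidal behavior, where the non-SB group merges MDDNSI and MDDSI.
#' Healthy controls take part in neither circuit contrast.
#'
#' @param phenotypes phenotype data.frame.
#' @param name "SI" or "SB".
#' @return list with `name`, `group_a`, `group_b` (subject-id vectors;
#'   group_a is the affected group).
#' @export
circuit_contrast <- function(phenotypes, name = c("SI", "SB")) {
  name <- match.arg(name)
  phenotypes <- validate_phenotypes(phenotypes)
  ids <- split(phenotypes$subject_id, phenotypes$group)
  if (name == "SI") {
    ga <- ids$MDDSI; gb <- ids$MDDNSI
  } else {
    ga <- ids$MDDSB; gb <- c(ids$MDDNSI, ids$MDDSI)
  }
  if (length(ga) < 3L || length(gb) < 3L) {
    stop("contrast ", name, " has a group with fewer than 3 subjects")
  }
  list(name = name, group_a = ga, group_b = gb)
}

#' Mean edge weight of a component within one subject's network
#'
#' @param network a [structural_network()].
#' @param component a component from [nbs_test()] /
#'   [threshold_components()] (needs an `edges` matrix).
#' @return arithmetic mean of the subject's FA weights over the
#'   component's edges.
#' @export
component_mean_strength <- function(network, component) {
  edges <- component$edges
  if (is.null(edges) || nrow(edges) == 0L) stop("component has no edges")
  n <- nrow(network$A)
  if (any(edges > n)) stop("component edges exceed network dimensions")
  mean(network$A[edges])
}

#' Partial correlation of component strength with behavioral scores
#'
#' Residualizes both the per-subject component strength and each scale
#' score on the nuisance covariates (age, sex coded 0/1, education,
#' medication load) and reports the Pearson correlation of the residuals
#' with Bonferroni correction across the scale battery.
#'
#' @param strengths per-subject component mean strengths (named or aligned
#'   with `scores` rows).
#' @param scores data.frame of scale scores (one column per scale).
#' @param covariates data.frame/matrix of numeric nuisance covariates.
#' @return data.frame `scale`, `r`, `p`, `p_bonf`.
#' @export
behavior_partial_correlation <- function(strengths, scores, covariates) {
  scores <- as.data.frame(scores)
  res <- lapply(names(scores), function(sc) {
    ct <- correlate(strengths, scores[[sc]], covariates = covariates)
    data.frame(scale = sc, r = ct$r, p = ct$p)
  })
  out <- do.call(rbind, res)
  out$p_bonf <- pmin(1, out$p * nrow(out))
  out
}
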