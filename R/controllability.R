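# Average network controllability of structural connectomes.
#
# The network is modelled as discrete, noise-free, linear time-invariant
# dynamics x[t+1] = A x[t] + B_k u_k[t], where A is the (stabilized)
# symmetric FA-weighted connectivity matrix and B_k = (e_k1, ..., e_kp)
# selects the control nodes. Average controllability of a single control
# node k is the trace of the infinite-horizon controllability Gramian
#   W_k = sum_{t >= 0} A^t e_k e_k' (A')^t ,
# the unique solution of the discrete Lyapunov equation
#   W_k = A W_k A' + e_k e_k' .
# trace(W_k) = sum_{t >= 0} ||A^t e_k||^2 >= 1, with equality iff the k-th
# row of A is zero.

#' Stabilize a raw connectivity matrix
#'
#' Divides the matrix by one plus its largest eigenvalue, so the spectral
#' radius becomes lambda_max / (1 + lambda_max) < 1 and the Gramian series
#' converges. This normalization is the standard convention in the network
#' control literature; it changes absolute controllability values, so only
#' contrasts and ranks are comparable across conventions.
#'
#' @param A_raw symmetric nonnegative numeric matrix (e.g. the `A` slot of
#'   a [structural_network()], or the object itself).
#' @return stabilized matrix with spectral radius strictly below 1.
#' @export
stabilize <- function(A_raw) {
  if (inherits(A_raw, "structural_network")) A_raw <- A_raw$A
  if (!is_square_matrix(A_raw)) stop("A_raw must be a square matrix")
  if (!all(is.finite(A_raw))) stop("A_raw contains non-finite entries")
  if (max(abs(A_raw - t(A_raw))) > 1e-9) stop("A_raw must be symmetric")
  if (any(A_raw < 0)) stop("A_raw must be nonnegative")
  lam <- eigen(A_raw, symmetric = TRUE, only.values = TRUE)$values[1L]
  A_raw / (1 + lam)
}

spectral_radius <- function(A) {
  max(abs(eigen(A, symmetric = TRUE, only.values = TRUE)$values))
}

# Solve W = A W A' + Q by the doubling (Smith) iteration:
#   W <- W + M W M',  M <- M^2
# which squares the effective horizon each step; quadratic convergence for
# spectral radius < 1.
solve_dlyap <- function(A, Q, tol = 1e-12, max_iter = 200L) {
  W <- Q
  M <- A
  for (i in seq_len(max_iter)) {
    W_new <- W + M %*% W %*% t(M)
    M <- M %*% M
    if (max(abs(W_new - W)) < tol) return(W_new)
    W <- W_new
  }
  stop("Lyapunov iteration did not converge in ", max_iter, " steps")
}

#' Average controllability of one control node
#'
#' Trace of the infinite-horizon controllability Gramian with B = e_k,
#' obtained by solving the discrete Lyapunov fixed point. Always >= 1
#' (the t = 0 term contributes ||e_k||^2 = 1).
#'
#' @param A stabilized system matrix (spectral radius < 1); see
#'   [stabilize()].
#' @param k control node index in 1..N.
#' @param tol convergence tolerance of the Lyapunov solve.
#' @return scalar average controllability.
#' @export
average_controllability <- function(A, k, tol = 1e-12) {
  if (!is_square_matrix(A)) stop("A must be a square matrix")
  n <- nrow(A)
  if (!(k %in% seq_len(n))) stop("control node k = ", k, " out of range 1..", n)
  if (spectral_radius(A) >= 1) {
    stop("A has spectral radius >= 1; stabilize() it first")
  }
  Q <- matrix(0, n, n)
  Q[k, k] <- 1
  W <- solve_dlyap(A, Q, tol = tol)
  sum(diag(W))
}

#' Average controllability of every node at once
#'
#' For symmetric stabilized A = V diag(lambda) V', the Gramian trace for
#' control node k has the closed form sum_i V[k,i]^2 / (1 - lambda_i^2);
#' one eigendecomposition yields all N node values. Agrees with the
#' per-node Lyapunov solve to solver tolerance.
#'
#' @inheritParams average_controllability
#' @return numeric vector of length N, named by the rownames of `A`.
#' @export
average_controllability_all <- function(A) {
  if (!is_square_matrix(A)) stop("A must be a square matrix")
  if (max(abs(A - t(A))) > 1e-9) stop("A must be symmetric")
  e <- eigen(A, symmetric = TRUE)
  if (max(abs(e$values)) >= 1) {
    stop("A has spectral radius >= 1; stabilize() it first")
  }
  ac <- drop((e$vectors^2) %*% (1 / (1 - e$values^2)))
  names(ac) <- rownames(A)
  ac
}

#' Node-wise average controllability for a cohort
#'
#' Stabilizes each subject's network and computes every region's average
#' controllability, preserving region order.
#'
#' @param networks list of [structural_network()] objects sharing the same
#'   region labels.
#' @return subjects x regions numeric matrix (rownames subject ids).
#' @export
cohort_controllability <- function(networks) {
  stopifnot(length(networks) >= 1L)
  labels <- networks[[1L]]$region_labels
  for (i in seq_along(networks)) {
    li <- networks[[i]]$region_labels
    mism <- which(li != labels)
    if (length(mism)) {
      stop(sprintf(
        "region label mismatch for subject '%s' at position %d: '%s' vs '%s'",
        networks[[i]]$subject_id, mism[1L], li[mism[1L]], labels[mism[1L]]))
    }
  }
  out <- t(vapply(networks, function(net) {
    average_controllability_all(stabilize(net$A))
  }, numeric(length(labels))))
  rownames(out) <- vapply(networks, `[[`, character(1), "subject_id")
  colnames(out) <- labels
  out
}

#' Group comparison of average controllability per region
#'
#' For each region (optionally a circuit subset), gates on per-group
#' Shapiro-Wilk normality, runs one-way ANOVA (all groups normal) or
#' Kruskal-Wallis otherwise, runs pairwise post hocs only where the
#' omnibus is significant, and Benjamini-Hochberg adjusts the omnibus
#' p-values across regions.
#'
#' @param anc_table subjects x regions matrix from
#'   [cohort_controllability()].
#' @param phenotypes phenotype data.frame with `subject_id` and `group`.
#' @param regions optional character vector restricting the comparison to a
#'   circuit's regions (default: all columns).
#' @param alpha significance level for the omnibus gate of the post hocs.
#' @return data.frame with one row per region: `region`, `test`,
#'   `statistic`, `p`, `p_adj`; the per-region post-hoc tables are attached
#'   as the `posthoc` attribute (named list).
#' @export
compare_anc <- function(anc_table, phenotypes, regions = NULL, alpha = 0.05) {
  phenotypes <- validate_phenotypes(phenotypes)
  idx <- match(rownames(anc_table), phenotypes$subject_id)
  if (anyNA(idx)) stop("subjects in anc_table missing from phenotypes")
  groups <- droplevels(phenotypes$group[idx])
  if (any(table(groups) < 3L)) {
    small <- names(which(table(groups) < 3L))[1L]
    stop("group '", small, "' has fewer than 3 subjects")
  }
  regions <- regions %||% colnames(anc_table)
  missing <- setdiff(regions, colnames(anc_table))
  if (length(missing)) stop("unknown region(s): ", paste(missing, collapse = ", "))
  rows <- vector("list", length(regions))
  posthoc <- stats::setNames(vector("list", length(regions)), regions)
  for (i in seq_along(regions)) {
    cmp <- compare_groups(anc_table[, regions[i]], groups, posthoc_gate = alpha)
    rows[[i]] <- data.frame(region = regions[i], test = cmp$test,
                            statistic = cmp$statistic, p = cmp$p)
    posthoc[[i]] <- cmp$posthoc
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  attr(out, "posthoc") <- posthoc
  out
}
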