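# Regional-expression preprocessing in the style of donor microarray
# atlases: distance-thresholded sample-to-region assignment, scaled robust
# sigmoid normalization within gene x donor, cross-donor consistency
# (differential stability) filtering, and aggregation to a genes x regions
# matrix. Probe-level steps (annotation, intensity filtering, probe
# selection) are outside the input boundary: inputs are gene-level.

#' Assign tissue samples to parcellation regions by distance
#'
#' Each sample is assigned to its nearest region centroid (Euclidean) if
#' the distance is at most `max_distance_mm`, otherwise dropped. Exact
#' ties go to the lower region index (deterministic).
#'
#' @param sample_coords samples x 3 coordinate matrix (mm, atlas space).
#' @param centroids regions x 3 centroid matrix in the same space.
#' @param max_distance_mm assignment threshold (default 2 mm).
#' @return integer vector of region indices, NA for dropped samples; the
#'   number dropped is attached as attribute `n_dropped` and reported via
#'   a message.
#' @export
assign_samples <- function(sample_coords, centroids, max_distance_mm = 2) {
  centroids <- as.matrix(centroids)
  sample_coords <- as.matrix(sample_coords)
  if (nrow(centroids) == 0L) stop("empty centroid set")
  if (ncol(sample_coords) != 3L || ncol(centroids) != 3L) {
    stop("coordinates must have 3 columns")
  }
  # squared distances sample x region
  d2 <- outer(rowSums(sample_coords^2), rowSums(centroids^2), `+`) -
    2 * sample_coords %*% t(centroids)
  d2[d2 < 0] <- 0
  nearest <- max.col(-d2, ties.method = "first") # lower index wins ties
  dist_min <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  assigned <- ifelse(dist_min <= max_distance_mm, nearest, NA_integer_)
  n_dropped <- sum(is.na(assigned))
  if (n_dropped > 0) {
    message(n_dropped, " sample(s) beyond ", max_distance_mm,
            " mm of any centroid were dropped")
  }
  attr(assigned, "n_dropped") <- n_dropped
  assigned
}

#' Scaled robust sigmoid normalization
#'
#' For one gene's values within one donor:
#' `s = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, then min-max
#' rescaled to [0, 1]. IQR/1.35 approximates a robust standard deviation.
#' Constant vectors (IQR = 0) map to 0.5 everywhere. The transform is
#' rank-preserving.
#'
#' @param x numeric vector (>= 2 values).
#' @return normalized vector in [0, 1].
#' @export
scaled_robust_sigmoid <- function(x) {
  if (length(x) < 2L) stop("need at least 2 values per gene x donor")
  iqr <- stats::IQR(x)
  if (iqr == 0) return(rep(0.5, length(x)))
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Normalize a donor's sample x gene matrix gene-wise
#'
#' Applies [scaled_robust_sigmoid()] to every gene column within one
#' donor's samples.
#'
#' @param expr samples x genes matrix for a single donor.
#' @return matrix of the same shape with values in [0, 1].
#' @export
normalize_donor <- function(expr) {
  apply(expr, 2, scaled_robust_sigmoid)
}

#' Filter genes inconsistent across donors (differential stability)
#'
#' A gene's differential stability is the mean pairwise Spearman
#' correlation of its per-donor region profiles; genes below
#' `min_consistency` are dropped.
#'
#' @param donor_profiles named list (one element per donor, >= 2 donors)
#'   of genes x regions matrices over the same genes; regions missing in a
#'   donor are NA.
#' @param min_consistency retention threshold (default 0.1).
#' @return character vector of retained genes; the per-gene DS values are
#'   attached as attribute `ds`.
#' @export
filter_inconsistent_genes <- function(donor_profiles, min_consistency = 0.1) {
  if (length(donor_profiles) < 2L) {
    stop("consistency is undefined with a single donor")
  }
  genes <- rownames(donor_profiles[[1L]])
  pairs <- utils::combn(length(donor_profiles), 2)
  ds <- rowMeans(vapply(seq_len(ncol(pairs)), function(k) {
    a <- donor_profiles[[pairs[1, k]]]
    b <- donor_profiles[[pairs[2, k]]]
    vapply(seq_along(genes), function(g) {
      ok <- is.finite(a[g, ]) & is.finite(b[g, ])
      if (sum(ok) < 3L) return(NA_real_)
      suppressWarnings(stats::cor(a[g, ok], b[g, ok], method = "spearman"))
    }, numeric(1))
  }, numeric(length(genes))), na.rm = TRUE)
  ds[is.nan(ds)] <- 0
  retained <- genes[ds >= min_consistency]
  attr(retained, "ds") <- stats::setNames(ds, genes)
  retained
}

#' Aggregate assigned, normalized samples to a genes x regions atlas
#'
#' Region value = mean over all assigned samples pooled across donors.
#' Regions with no assigned sample are kept as NA columns (explicitly
#' missing, never zero-filled) and listed in the `missing_regions`
#' attribute.
#'
#' @param expr samples x genes normalized matrix (all donors stacked).
#' @param assignments region index per sample (NA = dropped), from
#'   [assign_samples()].
#' @param n_regions total region count.
#' @param region_labels optional region names.
#' @return genes x regions matrix with attribute `missing_regions`.
#' @export
aggregate_samples <- function(expr, assignments, n_regions,
                              region_labels = NULL) {
  region_labels <- region_labels %||% sprintf("ROI%03d", seq_len(n_regions))
  keep <- !is.na(assignments)
  expr <- expr[keep, , drop = FALSE]
  assignments <- assignments[keep]
  out <- matrix(NA_real_, ncol(expr), n_regions,
                dimnames = list(colnames(expr), region_labels))
  for (r in unique(assignments)) {
    out[, r] <- colMeans(expr[assignments == r, , drop = FALSE])
  }
  missing <- region_labels[!(seq_len(n_regions) %in% assignments)]
  attr(out, "missing_regions") <- missing
  out
}

#' Full transcriptome preparation from tissue samples to an atlas matrix
#'
#' Runs assignment, per-donor scaled-robust-sigmoid normalization,
#' cross-donor consistency filtering, and aggregation; optionally
#' restricts to a hemisphere's region subset first (the generated
#' parcellations are single-hemisphere, so the default keeps everything).
#'
#' @param samples list with `donor`, `coords`, `expr` (samples x genes),
#'   as from [generate_tissue_samples()] or read from TSV.
#' @param centroids regions x 3 centroid matrix.
#' @param max_distance_mm assignment threshold.
#' @param min_consistency differential-stability threshold.
#' @param region_labels optional region names.
#' @param hemisphere_regions optional character subset of regions to keep
#'   (e.g. left-hemisphere labels).
#' @return list with `expr` (genes x regions, values in [0, 1]),
#'   `provenance` (counts of samples assigned/dropped, genes filtered,
#'   missing regions).
#' @export
prep_expression <- function(samples, centroids, max_distance_mm = 2,
                            min_consistency = 0.1, region_labels = NULL,
                            hemisphere_regions = NULL) {
  n_regions <- nrow(as.matrix(centroids))
  region_labels <- region_labels %||% sprintf("ROI%03d", seq_len(n_regions))
  assigned <- suppressMessages(
    assign_samples(samples$coords, centroids, max_distance_mm))
  donors <- unique(samples$donor)
  norm <- matrix(NA_real_, nrow(samples$expr), ncol(samples$expr),
                 dimnames = dimnames(samples$expr))
  profiles <- list()
  for (dn in donors) {
    sel <- samples$donor == dn
    norm[sel, ] <- normalize_donor(samples$expr[sel, , drop = FALSE])
    profiles[[dn]] <- aggregate_samples(norm[sel, , drop = FALSE],
                                        assigned[sel], n_regions,
                                        region_labels)
  }
  retained <- filter_inconsistent_genes(profiles, min_consistency)
  expr <- aggregate_samples(norm, assigned, n_regions, region_labels)
  expr <- expr[retained, , drop = FALSE]
  if (!is.null(hemisphere_regions)) {
    expr <- expr[, intersect(colnames(expr), hemisphere_regions), drop = FALSE]
  }
  missing <- colnames(expr)[colSums(is.finite(expr)) == 0]
  provenance <- list(
    n_samples = length(assigned),
    n_dropped_samples = attr(assigned, "n_dropped"),
    n_genes_in = ncol(samples$expr),
    n_genes_retained = length(retained),
    min_consistency = min_consistency,
    max_distance_mm = max_distance_mm,
    missing_regions = missing
  )
  list(expr = expr, provenance = provenance)
}
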