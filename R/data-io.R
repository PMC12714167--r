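# Readers and writers for the external formats the pipeline touches:
# tab-delimited connectome matrices, CSV phenotype tables, GMT gene sets,
# BrainNet Viewer .node/.edge exports, TSV expression matrices, and JSON
# ground-truth sidecars. All writers round-trip through their readers.

GROUP_LEVELS <- c("HC", "MDDNSI", "MDDSI", "MDDSB")

SCALE_COLUMNS <- c("HAMD17", "HAMA", "CTQ", "RSES", "MoCA",
                   "ERQ_CR", "ERQ_ES", "RFQ_promote", "RFQ_prevent")

#' Construct a structural brain network
#'
#' A structural network is one subject's symmetric, nonnegative, FA-weighted
#' adjacency matrix over a named parcellation, with a zero diagonal. It is
#' the system matrix of the linear dynamics used for controllability.
#'
#' @param A numeric square matrix of edge weights.
#' @param region_labels character vector of parcel names, one per row of
#'   `A`. Defaults to the dimnames of `A` or `R1..RN`.
#' @param subject_id subject identifier string.
#' @param sym_tol maximum tolerated asymmetry before the matrix is rejected;
#'   asymmetries below it are removed by averaging `A` with its transpose.
#' @return an object of class `structural_network` with elements `A`,
#'   `region_labels`, `subject_id`.
#' @export
structural_network <- function(A, region_labels = NULL, subject_id = "subject",
                               sym_tol = 1e-9) {
  if (!is_square_matrix(A)) {
    stop("adjacency must be a square matrix, got ", nrow(A), " x ", ncol(A))
  }
  if (!all(is.finite(A))) stop("adjacency contains non-finite entries")
  asym <- abs(A - t(A))
  if (max(asym) > sym_tol) {
    worst <- sort(which(asym == max(asym), arr.ind = TRUE)[1L, ])
    stop(sprintf(
      "matrix is asymmetric beyond tolerance at cell (%d,%d): %g vs %g",
      worst[1L], worst[2L], A[worst[1L], worst[2L]], A[worst[2L], worst[1L]]))
  }
  A <- (A + t(A)) / 2
  if (any(A < 0)) {
    bad <- which(A < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative weight at cell (%d,%d)", bad[1L], bad[2L]))
  }
  diag(A) <- 0
  region_labels <- region_labels %||% rownames(A) %||% paste0("R", seq_len(nrow(A)))
  if (length(region_labels) != nrow(A)) {
    stop("region_labels length (", length(region_labels),
         ") does not match matrix dimension (", nrow(A), ")")
  }
  dimnames(A) <- list(region_labels, region_labels)
  structure(list(A = A, region_labels = as.character(region_labels),
                 subject_id = as.character(subject_id)),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  cat("Structural network:", x$subject_id, "\n")
  cat("  regions:", length(x$region_labels),
      " edges (nonzero):", sum(x$A[upper.tri(x$A)] > 0), "\n")
  cat("  weight range: [", format(min(x$A)), ", ", format(max(x$A)), "]\n", sep = "")
  invisible(x)
}

#' Read a connectome matrix from a tab-delimited file
#'
#' Expects a header row of region labels followed by an N x N numeric block.
#' The matrix must be symmetric within `sym_tol`; it is then symmetrized
#' exactly as (A + t(A)) / 2 to absorb text round-trip float noise.
#'
#' @param path file path.
#' @param subject_id subject identifier; defaults to the file name stem.
#' @inheritParams structural_network
#' @return a `structural_network`.
#' @export
read_connectome <- function(path, subject_id = NULL, sym_tol = 1e-9) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE)
  A <- as.matrix(df)
  if (!is.numeric(A)) stop("connectome file is not numeric: ", path)
  if (nrow(A) != ncol(A)) {
    stop("connectome file is not square (", nrow(A), " x ", ncol(A), "): ", path)
  }
  subject_id <- subject_id %||% sub("\\.[^.]*$", "", basename(path))
  structural_network(A, region_labels = colnames(A),
                     subject_id = subject_id, sym_tol = sym_tol)
}

#' Write a connectome matrix as tab-delimited text
#'
#' @param network a `structural_network`.
#' @param path output file path.
#' @export
write_connectome <- function(network, path) {
  stopifnot(inherits(network, "structural_network"))
  df <- as.data.frame(network$A)
  names(df) <- network$region_labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from CSV
#'
#' Validates subject-id uniqueness, the closed group-label set
#' (HC, MDDNSI, MDDSI, MDDSB), and nonnegative ages.
#'
#' @param path CSV file path.
#' @return a data.frame with `group` as a factor over the closed level set.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_phenotypes(df)
}

validate_phenotypes <- function(df) {
  required <- c("subject_id", "group", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("phenotype table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(df$subject_id)) {
    stop("duplicate subject_id: ", df$subject_id[duplicated(df$subject_id)][1L])
  }
  bad <- setdiff(unique(as.character(df$group)), GROUP_LEVELS)
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(df$age < 0)) stop("negative age for subject ",
                            df$subject_id[which(df$age < 0)[1L]])
  df$group <- factor(df$group, levels = GROUP_LEVELS)
  df
}

#' @rdname read_phenotypes
#' @param phenotypes a phenotype data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT dialect: set name, description, then member
#' genes. Duplicate members within a set are deduplicated with a warning;
#' duplicate set names and lines with fewer than three fields are errors.
#'
#' @param path GMT file path.
#' @return a named list of character vectors with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descriptions <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT line ", i, " has fewer than 3 fields: ", lines[[i]])
    }
    name <- fields[[1]]
    if (name %in% names(sets)) stop("duplicate gene-set name: ", name)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", name, "' deduplicated")
      members <- unique(members)
    }
    sets[[name]] <- members
    descriptions[[name]] <- fields[[2]]
  }
  attr(sets, "description") <- descriptions
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional per-set description strings.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(sets, "description") %||%
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a subnetwork for BrainNet Viewer
#'
#' Writes the `.node` (six whitespace-delimited columns: x y z color size
#' label) and `.edge` (N x N symmetric matrix) files BrainNet Viewer reads.
#'
#' @param coords N x 3 matrix of node coordinates (mm).
#' @param edges N x N symmetric weight matrix.
#' @param path_prefix output path without extension.
#' @param size,color per-node numeric columns (recycled).
#' @param labels per-node label strings.
#' @return paths of the two files written, invisibly.
#' @export
write_brainnet <- function(coords, edges, path_prefix, size = 1, color = 1,
                           labels = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  n <- nrow(coords)
  if (!is_square_matrix(edges) || nrow(edges) != n) {
    stop("node/edge dimension mismatch: ", n, " nodes vs ",
         nrow(edges), " x ", ncol(edges), " edge matrix")
  }
  labels <- labels %||% paste0("R", seq_len(n))
  node <- data.frame(coords[, 1], coords[, 2], coords[, 3],
                     rep_len(color, n), rep_len(size, n), labels)
  node_path <- paste0(path_prefix, ".node")
  edge_path <- paste0(path_prefix, ".edge")
  utils::write.table(node, node_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(edges, edge_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

# Parse a .node file back (used by round-trip tests and previews).
read_brainnet_node <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("x", "y", "z", "color", "size", "label"))
  df$label <- as.character(df$label)
  df
}

#' Read / write a genes x regions expression matrix as TSV
#'
#' Genes are rows (first column `gene`), regions are the remaining columns.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene rownames and region colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  genes <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- genes
  m
}

#' @rdname read_expression_matrix
#' @param expr numeric matrix, genes in rows.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a ground-truth sidecar
#'
#' The synthetic-data generators serialize their planted structure (module
#' labels, planted edges, effect sizes, ...) as JSON next to the data so
#' that validation code can consume it without re-deriving it.
#'
#' @param truth a list of planted parameters.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
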