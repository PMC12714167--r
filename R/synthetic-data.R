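# Synthetic-data generators. Every pipeline input is generated with known
# planted structure (differential edge components, coexpression modules,
# trait couplings, cell-type enrichments, per-gene validation effects) so
# each downstream stage has a recoverable ground truth. Generators are
# fully determined by their spec + seed and return the planted parameters
# alongside the data; write_ground_truth() serializes them as a JSON
# sidecar.

#' Specification of a synthetic connectome cohort
#'
#' @param n_per_group named integer vector of subjects per group; names
#'   from HC, MDDNSI, MDDSI, MDDSB. Defaults to the four clinical group
#'   sizes used throughout the package's fixtures.
#' @param n_regions parcel count (>= 10).
#' @param planted_edges 2-column integer matrix of region pairs forming
#'   the differential component; must form a connected subgraph on its
#'   incident nodes. NULL for no planted component.
#' @param edge_effect standardized mean difference (in units of
#'   `noise_sd`) subtracted from planted edges in `affected_group`.
#' @param affected_group group receiving the attenuation.
#' @param base_weight_range interval for FA-like group-mean edge weights.
#' @param noise_sd subject-level edge noise scale.
#' @param density fraction of region pairs connected in the base topology.
#' @param seed integer RNG seed.
#' @return validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = c(HC = 37, MDDNSI = 31, MDDSI = 34,
                                        MDDSB = 22),
                        n_regions = 90, planted_edges = NULL,
                        edge_effect = 0, affected_group = "MDDSI",
                        base_weight_range = c(0.2, 0.8), noise_sd = 0.1,
                        density = 0.15, seed = 1) {
  if (n_regions < 10) stop("n_regions must be at least 10")
  if (edge_effect < 0) stop("edge_effect must be nonnegative")
  if (is.null(names(n_per_group)) ||
      !all(names(n_per_group) %in% GROUP_LEVELS)) {
    stop("n_per_group must be named with labels from: ",
         paste(GROUP_LEVELS, collapse = ", "))
  }
  if (!affected_group %in% names(n_per_group)) {
    stop("affected_group '", affected_group, "' not among the cohort groups")
  }
  stopifnot(length(base_weight_range) == 2L,
            base_weight_range[1] >= 0, base_weight_range[2] <= 1,
            base_weight_range[1] < base_weight_range[2],
            noise_sd > 0, density > 0, density <= 1)
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2L) stop("planted_edges needs 2 columns")
    bad <- which(planted_edges < 1 | planted_edges > n_regions, arr.ind = TRUE)
    if (length(bad)) {
      e <- bad[1L, 1L]
      stop(sprintf("planted edge (%d,%d) is out of range 1..%d",
                   planted_edges[e, 1], planted_edges[e, 2], n_regions))
    }
    if (any(planted_edges[, 1] == planted_edges[, 2])) {
      stop("planted edges may not be self-loops")
    }
    g <- igraph::graph_from_edgelist(planted_edges, directed = FALSE)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
    if (igraph::components(g)$no != 1L) {
      stop("planted_edges must form a connected subgraph on their nodes")
    }
  }
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 planted_edges = planted_edges, edge_effect = edge_effect,
                 affected_group = affected_group,
                 base_weight_range = base_weight_range, noise_sd = noise_sd,
                 density = density, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Group offsets of the synthetic phenotype scales: location per group in
# the order HC, MDDNSI, MDDSI, MDDSB, plus a common sd. Locations follow
# the clinical pattern of the cohort the generator emulates (patients
# elevated on depression/anxiety scales, SI group highest on HAMD, SB
# group intermediate); they are fixtures, not estimates.
SCALE_PARAMS <- list(
  HAMD17      = list(mu = c(1.0, 19.0, 21.0, 14.5), sd = 4.0),
  HAMA        = list(mu = c(1.0, 15.0, 15.0, 14.5), sd = 4.0),
  CTQ         = list(mu = c(33, 38, 43, 36),        sd = 8.0),
  RSES        = list(mu = c(37, 62, 62, 54.5),      sd = 8.0),
  MoCA        = list(mu = c(26, 25, 26, 25),        sd = 2.0),
  ERQ_CR      = list(mu = c(36, 26, 29, 29),        sd = 6.0),
  ERQ_ES      = list(mu = c(15, 18, 16.5, 14.5),    sd = 5.0),
  RFQ_promote = list(mu = c(20.4, 17.2, 17.0, 18.8), sd = 3.7),
  RFQ_prevent = list(mu = c(20.4, 18.8, 18.3, 18.5), sd = 3.0)
)

generate_phenotypes <- function(spec) {
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)
  gi <- match(groups, GROUP_LEVELS)
  age_mu <- c(34.2, 31.1, 30.3, 30.1)[gi]
  df <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    group = groups,
    age = round(pmax(18, stats::rnorm(n, age_mu, 11)), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    education = round(pmax(6, stats::rnorm(n, 11, 3)), 1),
    medication_load = ifelse(groups == "HC", 0,
                             round(stats::rgamma(n, shape = 2, rate = 1), 2))
  )
  for (sc in names(SCALE_PARAMS)) {
    pars <- SCALE_PARAMS[[sc]]
    df[[sc]] <- round(pmax(0, stats::rnorm(n, pars$mu[gi], pars$sd)), 1)
  }
  validate_phenotypes(df)
}

#' Generate a cohort of FA-weighted structural connectomes
#'
#' Base topology is a random geometric graph on parcel centroids (uniform
#' in a 100 mm cube) with distance-decaying group-mean weights inside
#' `base_weight_range`; subject matrices add symmetric Gaussian edge noise
#' and are clipped to [0, 1]. Planted edges are forced into the topology
#' with mid-range mean weight (so clipping cannot bias the planted
#' contrast) and attenuated by `edge_effect * noise_sd` in the affected
#' group.
#'
#' @param spec a [cohort_spec()].
#' @return list with `networks` (list of [structural_network()]),
#'   `phenotypes` (data.frame), `centroids`, and `ground_truth` (planted
#'   edges, affected group, effect, per-edge shift).
#' @export
generate_connectome_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions
  labels <- sprintf("ROI%03d", seq_len(n))
  centroids <- matrix(stats::runif(n * 3, 0, 100), ncol = 3)
  d <- as.matrix(stats::dist(centroids))
  ut <- upper.tri(d)
  radius <- stats::quantile(d[ut], spec$density)
  present <- d <= radius & ut
  pe_ut <- NULL
  if (!is.null(spec$planted_edges)) {
    # orient planted pairs into the upper triangle and force them present
    pe_ut <- t(apply(spec$planted_edges, 1, sort))
    present[pe_ut] <- TRUE
  }
  # distance-decaying mean weight within base_weight_range
  b <- spec$base_weight_range
  mu <- matrix(0, n, n)
  decay <- mean(d[present])
  mu[present] <- b[1] + (b[2] - b[1]) * exp(-d[present] / decay)
  if (!is.null(pe_ut)) {
    # mid-range mean so the planted attenuation cannot be clipped away
    mu[pe_ut] <- mean(b)
  }
  shift <- spec$edge_effect * spec$noise_sd
  phenotypes <- generate_phenotypes(spec)
  networks <- vector("list", nrow(phenotypes))
  for (s in seq_len(nrow(phenotypes))) {
    mu_s <- mu
    if (!is.null(pe_ut) &&
        phenotypes$group[s] == spec$affected_group) {
      mu_s[pe_ut] <- mu_s[pe_ut] - shift
    }
    noise <- matrix(0, n, n)
    noise[present] <- stats::rnorm(sum(present), 0, spec$noise_sd)
    A <- mu_s + noise
    A[!present] <- 0
    A <- pmin(pmax(A, 0), 1)
    A <- A + t(A)
    networks[[s]] <- structural_network(A, labels, phenotypes$subject_id[s])
  }
  truth <- list(
    planted_edges = if (is.null(pe_ut)) NULL else unname(as.matrix(pe_ut)),
    affected_group = spec$affected_group,
    edge_effect = spec$edge_effect,
    noise_sd = spec$noise_sd,
    planted_shift = shift,
    region_labels = labels,
    seed = spec$seed
  )
  list(networks = networks, phenotypes = phenotypes,
       centroids = centroids, ground_truth = truth)
}

#' Specification of a synthetic regional expression atlas
#'
#' @param n_genes total gene count.
#' @param n_regions region count (matching the connectome parcellation or
#'   its left-hemisphere half).
#' @param modules list of planted modules, each
#'   `list(size =, cor =, trait_cor =)`: module size (>= 2), within-module
#'   correlation, and the correlation of the module's latent factor with
#'   the regional trait. Sizes must sum to <= n_genes.
#' @param trait per-region numeric vector, or "generate" for a standard
#'   normal trait.
#' @param seed integer RNG seed.
#' @return validated `expression_spec` list.
#' @export
expression_spec <- function(n_genes = 1000, n_regions = 120,
                            modules = list(list(size = 150, cor = 0.7,
                                                trait_cor = 0.5),
                                           list(size = 150, cor = 0.7,
                                                trait_cor = 0),
                                           list(size = 150, cor = 0.7,
                                                trait_cor = 0),
                                           list(size = 150, cor = 0.7,
                                                trait_cor = 0)),
                            trait = "generate", seed = 1) {
  sizes <- vapply(modules, `[[`, numeric(1), "size")
  cors <- vapply(modules, `[[`, numeric(1), "cor")
  tcors <- vapply(modules, `[[`, numeric(1), "trait_cor")
  if (any(sizes < 2)) stop("each module must have size >= 2")
  if (sum(sizes) > n_genes) stop("module sizes sum to more than n_genes")
  if (any(abs(cors) > 1) || any(abs(tcors) > 1)) {
    stop("correlations must lie in [-1, 1]")
  }
  if (any(cors < 0)) {
    stop("within-module correlation must be nonnegative: a block of ",
         "mutually anti-correlated genes is infeasible for size > 2")
  }
  infeasible <- abs(tcors) == 1 & cors < 1
  if (any(infeasible)) {
    stop("module ", which(infeasible)[1L],
         ": |trait_cor| = 1 is infeasible with within-module noise (cor < 1)")
  }
  if (is.numeric(trait) && length(trait) != n_regions) {
    stop("trait vector length must equal n_regions")
  }
  structure(list(n_genes = n_genes, n_regions = n_regions, modules = modules,
                 trait = trait, seed = as.integer(seed)),
            class = "expression_spec")
}

#' Generate a genes x regions expression atlas with planted modules
#'
#' Each planted module m has a latent region factor f_m built as
#' `trait_cor * z(trait) + sqrt(1 - trait_cor^2) * noise` (so the factor
#' correlates with the trait at the stated value in population); member
#' genes are `sqrt(cor) * f_m + sqrt(1 - cor) * noise`, giving the stated
#' within-module correlation. Background genes are independent noise and
#' labelled "none".
#'
#' @param spec an [expression_spec()].
#' @return object of class `expression_atlas`: list with `expr` (genes x
#'   regions matrix), `gene_ids`, `region_labels`, `trait`, and
#'   `ground_truth` (module labels and planted parameters).
#' @export
generate_expression_atlas <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(spec$seed)
  n_g <- spec$n_genes; n_r <- spec$n_regions
  region_labels <- sprintf("ROI%03d", seq_len(n_r))
  gene_ids <- sprintf("GENE%05d", seq_len(n_g))
  trait <- if (identical(spec$trait, "generate")) stats::rnorm(n_r)
           else as.numeric(spec$trait)
  if (stats::sd(trait) == 0) stop("trait is constant; cannot plant couplings")
  zt <- as.numeric(scale(trait))
  labels <- rep("none", n_g)
  expr <- matrix(stats::rnorm(n_g * n_r), nrow = n_g,
                 dimnames = list(gene_ids, region_labels))
  offset <- 0L
  factors <- list()
  for (m in seq_along(spec$modules)) {
    mod <- spec$modules[[m]]
    rho <- mod$trait_cor; w <- mod$cor
    f <- rho * zt + sqrt(1 - rho^2) * stats::rnorm(n_r)
    f <- as.numeric(scale(f))
    idx <- offset + seq_len(mod$size)
    noise <- matrix(stats::rnorm(mod$size * n_r), nrow = mod$size)
    expr[idx, ] <- sqrt(w) * rep(f, each = mod$size) + sqrt(1 - w) * noise
    labels[idx] <- paste0("M", m)
    factors[[paste0("M", m)]] <- f
    offset <- offset + mod$size
  }
  truth <- list(
    module_labels = stats::setNames(labels, gene_ids),
    module_params = spec$modules,
    trait = trait,
    seed = spec$seed
  )
  structure(list(expr = expr, gene_ids = gene_ids,
                 region_labels = region_labels, trait = trait,
                 latent_factors = factors, ground_truth = truth),
            class = "expression_atlas")
}

#' @export
print.expression_atlas <- function(x, ...) {
  tab <- table(x$ground_truth$module_labels)
  cat("Expression atlas:", nrow(x$expr), "genes x", ncol(x$expr), "regions\n")
  cat("  planted modules:",
      paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Specification of a synthetic cell-type expression reference
#'
#' @param cell_type_names unique cell-type names.
#' @param enriched_module planted-module label (e.g. "M1") whose genes are
#'   boosted, or NA for no enrichment.
#' @param enrichment_fold multiplicative expression boost (>= 1) for the
#'   enriched module's genes in the first cell type.
#' @param target_cell_type cell type receiving the boost (default: first).
#' @param seed integer RNG seed.
#' @export
celltype_spec <- function(cell_type_names = c("GABAergic", "Glutamatergic",
                                              "Astrocyte", "Oligodendrocyte",
                                              "OPC", "Microglia",
                                              "Endothelial"),
                          enriched_module = NA, enrichment_fold = 1,
                          target_cell_type = cell_type_names[1L], seed = 1) {
  if (anyDuplicated(cell_type_names)) stop("cell type names must be unique")
  if (enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (!target_cell_type %in% cell_type_names) {
    stop("target_cell_type must be one of cell_type_names")
  }
  structure(list(cell_type_names = cell_type_names,
                 enriched_module = enriched_module,
                 enrichment_fold = enrichment_fold,
                 target_cell_type = target_cell_type,
                 seed = as.integer(seed)),
            class = "celltype_spec")
}

#' Generate a genes x cell-types mean-expression reference
#'
#' Baseline expression of gene g in every cell type is a shared gene level
#' times independent lognormal noise (sdlog 0.2), so with
#' `enrichment_fold = 1` specificity is uniform in expectation. Genes of
#' the enriched module have their expression multiplied by
#' `enrichment_fold` in the target cell type, so their expected
#' specificity there is approximately fold / (fold + C - 1).
#'
#' @param genes gene ids.
#' @param spec a [celltype_spec()].
#' @param module_labels named gene -> module vector (from the expression
#'   atlas ground truth); required when `enriched_module` is set.
#' @return nonnegative genes x cell-types matrix.
#' @export
generate_celltype_reference <- function(genes, spec, module_labels = NULL) {
  stopifnot(inherits(spec, "celltype_spec"), length(genes) > 0)
  set.seed(spec$seed)
  C <- length(spec$cell_type_names)
  base <- stats::rlnorm(length(genes), meanlog = log(10), sdlog = 1)
  m <- base * matrix(stats::rlnorm(length(genes) * C, 0, 0.2), ncol = C,
                     dimnames = list(genes, spec$cell_type_names))
  if (!is.na(spec$enriched_module) && spec$enrichment_fold > 1) {
    if (is.null(module_labels)) {
      stop("module_labels required when enriched_module is set")
    }
    members <- names(module_labels)[module_labels == spec$enriched_module]
    if (!length(members)) {
      stop("unknown module '", spec$enriched_module, "': no member genes")
    }
    members <- intersect(members, genes)
    m[members, spec$target_cell_type] <-
      m[members, spec$target_cell_type] * spec$enrichment_fold
  }
  m
}

#' Generate a two-group validation expression dataset
#'
#' Emulates an independent case/control expression study: all genes are
#' unit-variance Gaussian noise; genes in `de_genes` are shifted by their
#' `effect_sizes` (in sd units) in the second group.
#'
#' @param genes gene ids.
#' @param n_per_group samples per group (> 0).
#' @param de_genes subset of `genes` with true effects.
#' @param effect_sizes numeric vector matching `de_genes`.
#' @param seed integer RNG seed.
#' @param group_names two group labels.
#' @return list with `expr` (genes x samples), `group` (factor), and
#'   `ground_truth`.
#' @export
generate_validation_dataset <- function(genes, n_per_group, de_genes = character(),
                                        effect_sizes = numeric(), seed = 1,
                                        group_names = c("control", "case")) {
  if (n_per_group < 1) stop("n_per_group must be positive")
  if (!all(de_genes %in% genes)) {
    stop("de_genes must be a subset of genes: missing ",
         setdiff(de_genes, genes)[1L])
  }
  if (length(effect_sizes) != length(de_genes)) {
    stop("effect_sizes length (", length(effect_sizes),
         ") does not match de_genes length (", length(de_genes), ")")
  }
  set.seed(as.integer(seed))
  n <- 2L * n_per_group
  expr <- matrix(stats::rnorm(length(genes) * n), nrow = length(genes),
                 dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  group <- factor(rep(group_names, each = n_per_group), levels = group_names)
  if (length(de_genes)) {
    expr[de_genes, group == group_names[2L]] <-
      expr[de_genes, group == group_names[2L]] + effect_sizes
  }
  truth <- list(de_genes = de_genes, effect_sizes = effect_sizes, seed = seed)
  list(expr = expr, group = group, ground_truth = truth)
}

#' Generate donor-level tissue samples from an expression atlas
#'
#' Emulates multi-donor microarray sampling of the brain: each donor
#' contributes one sample near each region centroid (jittered by
#' `jitter_mm`), with expression equal to the region's atlas profile under
#' a donor-specific monotone affine distortion plus measurement noise.
#' Feeds the transcriptome-prep stage (assignment, robust-sigmoid
#' normalization, consistency filtering, aggregation).
#'
#' @param atlas an `expression_atlas`.
#' @param centroids region centroid coordinates (n_regions x 3, mm).
#' @param n_donors donor count.
#' @param jitter_mm sd of the spatial jitter around each centroid.
#' @param noise_sd sd of per-sample measurement noise.
#' @param dropout fraction of donor-region samples dropped at random
#'   (emulates incomplete spatial coverage).
#' @param seed integer RNG seed.
#' @return list with `donor`, `coords` (samples x 3), `expr` (samples x
#'   genes), `gene_ids`, `true_region`.
#' @export
generate_tissue_samples <- function(atlas, centroids, n_donors = 6,
                                    jitter_mm = 0.5, noise_sd = 0.2,
                                    dropout = 0.05, seed = 1) {
  stopifnot(inherits(atlas, "expression_atlas"))
  centroids <- as.matrix(centroids)
  n_r <- ncol(atlas$expr)
  if (nrow(centroids) != n_r) stop("centroids/atlas region count mismatch")
  set.seed(as.integer(seed))
  donor <- character(); coords <- NULL; expr <- NULL; true_region <- integer()
  for (dn in seq_len(n_donors)) {
    keep <- which(stats::runif(n_r) >= dropout)
    # donor-specific monotone affine distortion: scale + shift per donor
    a <- exp(stats::rnorm(1, 0, 0.2)); bshift <- stats::rnorm(1, 0, 0.5)
    xyz <- centroids[keep, , drop = FALSE] +
      matrix(stats::rnorm(length(keep) * 3, 0, jitter_mm), ncol = 3)
    e <- t(atlas$expr[, keep, drop = FALSE]) * a + bshift +
      matrix(stats::rnorm(length(keep) * nrow(atlas$expr), 0, noise_sd),
             nrow = length(keep))
    donor <- c(donor, rep(sprintf("donor%02d", dn), length(keep)))
    coords <- rbind(coords, xyz)
    expr <- rbind(expr, e)
    true_region <- c(true_region, keep)
  }
  colnames(expr) <- rownames(atlas$expr)
  list(donor = donor, coords = coords, expr = expr,
       gene_ids = rownames(atlas$expr), true_region = true_region)
}

#' Generate a synthetic GMT gene-set collection
#'
#' Builds `n_sets` random gene sets plus, for every planted module, one
#' set concentrated in that module's genes (a fraction `module_purity` of
#' its members drawn from the module), so over-representation analysis of
#' recovered module genes has a plantable positive.
#'
#' @param genes universe gene ids.
#' @param module_labels named gene -> module vector.
#' @param n_sets number of random background sets.
#' @param set_size size of every set.
#' @param module_purity fraction of a module set's members drawn from the
#'   module.
#' @param seed integer RNG seed.
#' @return named list of gene sets (GMT-compatible; see [write_gmt()]).
#' @export
generate_gene_sets <- function(genes, module_labels, n_sets = 30,
                               set_size = 80, module_purity = 0.6, seed = 1) {
  set.seed(as.integer(seed))
  sets <- list()
  mods <- setdiff(unique(module_labels), "none")
  for (m in mods) {
    members <- names(module_labels)[module_labels == m]
    n_in <- min(length(members), round(module_purity * set_size))
    sets[[paste0("PLANTED_", m)]] <-
      c(sample(members, n_in),
        sample(setdiff(genes, members), set_size - n_in))
  }
  for (i in seq_len(n_sets)) {
    sets[[sprintf("RANDOM_%02d", i)]] <- sample(genes, set_size)
  }
  sets
}
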