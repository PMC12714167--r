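# End-to-end orchestration: simulate -> controllability -> NBS (SI and SB)
# -> circuit trait -> transcriptome prep -> WGCNA -> hub genes -> ORA +
# EWCE -> validation, with a machine-readable report and per-stage seeds
# fanned out from one master seed by a plain counter.

#' Default pipeline configuration
#'
#' Builds the full configuration list with the package defaults and
#' applies any overrides (named after the top-level keys; nested lists are
#' merged shallowly per stage).
#'
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param ... stage overrides, e.g. `nbs = list(n_perm = 500)`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(
      n_per_group = c(HC = 37, MDDNSI = 31, MDDSI = 34, MDDSB = 22),
      n_regions = 90,
      planted_edges = "path10",  # 10-edge path, or a 2-column matrix
      edge_effect = 2.0,
      affected_group = "MDDSI",
      base_weight_range = c(0.2, 0.8),
      noise_sd = 0.1,
      density = 0.15
    ),
    # demo planting is strong-signal: within-module r 0.8 and trait r 0.7
    # give planted genes MM ~ 0.89 and GS ~ 0.63, so the MM > 0.8 / GS > 0.5
    # hub screen has true positives to find
    expression = list(
      n_genes = 1000,
      module_sizes = c(150, 150, 150, 150),
      within_cor = 0.8,
      trait_cors = c(0.7, 0, 0, 0)
    ),
    prep = list(n_donors = 6, max_distance_mm = 2, min_consistency = 0.1,
                jitter_mm = 0.5, noise_sd = 0.2, dropout = 0.05),
    celltype = list(enrichment_fold = 5, enriched_module = "M1"),
    nbs = list(primary_p = 0.001, n_perm = 5000),
    wgcna = list(power = 12, min_module_size = 100, target_r2 = 0.85,
                 cut_height = 0.99, merge_height = 0.25, mm_threshold = 0.8,
                 gs_threshold = 0.5),
    enrichment = list(p_cutoff = 0.01, min_overlap = 3, min_enrichment = 1.0,
                      top_n = 5, n_boot = 1000),
    validation = list(n_per_group = 30, n_de = 50, effect_size = 2.0)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; absent keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config` list.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seed <- raw$seed %||% 1
  raw$seed <- NULL
  if (!is.null(raw$cohort$n_per_group)) {
    raw$cohort$n_per_group <- unlist(raw$cohort$n_per_group)
  }
  do.call(pipeline_config, c(list(seed = seed), raw))
}

#' A null configuration with every planted effect switched off
#'
#' Zero differential-edge effect, zero module-trait couplings, unit
#' cell-type enrichment fold and zero validation effect sizes; the
#' correlation structure of the planted modules is kept so every detector
#' still runs and can be calibrated.
#'
#' @param seed master seed.
#' @param ... further overrides forwarded to [pipeline_config()].
#' @return a `pipeline_config` list.
#' @export
null_pipeline_config <- function(seed = 1, ...) {
  pipeline_config(seed = seed,
                  cohort = list(edge_effect = 0),
                  expression = list(trait_cors = c(0, 0, 0, 0)),
                  celltype = list(enrichment_fold = 1),
                  validation = list(effect_size = 0), ...)
}

# Default planted component: a 10-edge path over the first 11 regions.
planted_path_edges <- function(n_edges = 10L) {
  cbind(seq_len(n_edges), seq_len(n_edges) + 1L)
}

#' Run the full pipeline
#'
#' Executes every stage on synthetic data generated from the
#' configuration, compares each stage's findings against the generator's
#' ground truth, and (optionally) writes the data files, a
#' machine-readable `results.json`, and a human-readable summary to
#' `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory (created if needed).
#' @return object of class `pipeline_result`: list of stage outputs,
#'   `report` (significant findings + ground-truth recovery checks), and
#'   `log` (per-stage seeds and input hashes).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list(seed = config$seed, stages = list())
  note <- function(stage, seed) log$stages[[stage]] <<- list(seed = seed)

  # -- stage 1: simulate the cohort ---------------------------------------
  pe <- config$cohort$planted_edges
  if (identical(pe, "path10")) pe <- planted_path_edges(10L)
  s1 <- derive_seed(config$seed, 1)
  spec <- cohort_spec(n_per_group = config$cohort$n_per_group,
                      n_regions = config$cohort$n_regions,
                      planted_edges = pe,
                      edge_effect = config$cohort$edge_effect,
                      affected_group = config$cohort$affected_group,
                      base_weight_range = config$cohort$base_weight_range,
                      noise_sd = config$cohort$noise_sd,
                      density = config$cohort$density,
                      seed = s1)
  cohort <- generate_connectome_cohort(spec)
  note("simulate", s1)

  # -- stage 2: controllability ------------------------------------------
  anc <- cohort_controllability(cohort$networks)
  anc_groups <- compare_anc(anc, cohort$phenotypes)
  note("controllability", NA)

  # -- stage 3: NBS, SI and SB circuit contrasts --------------------------
  s3 <- derive_seed(config$seed, 3)
  ids <- vapply(cohort$networks, `[[`, character(1), "subject_id")
  run_contrast <- function(name) {
    ct <- circuit_contrast(cohort$phenotypes, name)
    sel <- ids %in% c(ct$group_a, ct$group_b)
    nbs_test(cohort$networks[sel],
             ifelse(ids[sel] %in% ct$group_a, "affected", "reference"),
             primary_p = config$nbs$primary_p, n_perm = config$nbs$n_perm,
             seed = s3, contrast_name = name)
  }
  nbs_si <- run_contrast("SI")
  nbs_sb <- run_contrast("SB")
  note("nbs", s3)

  # circuit-framework ANC comparisons on regions incident to the
  # significant components (whole-brain comparison already done)
  circuit_regions <- function(nbs) {
    sig <- significant_components(nbs)
    if (!length(sig)) return(character(0))
    labs <- nbs$stat_map$region_labels
    labs[sort(unique(unlist(lapply(sig, `[[`, "nodes"))))]
  }
  anc_circuit <- list()
  for (nm in c("SI", "SB")) {
    regs <- circuit_regions(if (nm == "SI") nbs_si else nbs_sb)
    if (length(regs)) {
      anc_circuit[[nm]] <- compare_anc(anc, cohort$phenotypes, regions = regs)
    }
  }

  # -- stage 4: circuit trait --------------------------------------------
  trait <- trait_from_nbs(nbs_si)

  # -- stage 5: expression atlas with planted modules ---------------------
  s5 <- derive_seed(config$seed, 5)
  ex <- config$expression
  modules <- lapply(seq_along(ex$module_sizes), function(i) {
    list(size = ex$module_sizes[i], cor = ex$within_cor,
         trait_cor = ex$trait_cors[i])
  })
  espec <- expression_spec(n_genes = ex$n_genes,
                           n_regions = config$cohort$n_regions,
                           modules = modules, trait = as.numeric(trait),
                           seed = s5)
  atlas <- generate_expression_atlas(espec)
  note("expression", s5)

  # -- stage 6: tissue samples and transcriptome prep ---------------------
  s6 <- derive_seed(config$seed, 6)
  samples <- generate_tissue_samples(atlas, cohort$centroids,
                                     n_donors = config$prep$n_donors,
                                     jitter_mm = config$prep$jitter_mm,
                                     noise_sd = config$prep$noise_sd,
                                     dropout = config$prep$dropout,
                                     seed = s6)
  prepped <- prep_expression(samples, cohort$centroids,
                             max_distance_mm = config$prep$max_distance_mm,
                             min_consistency = config$prep$min_consistency,
                             region_labels = colnames(atlas$expr))
  note("prep", s6)

  # -- stage 7: WGCNA ------------------------------------------------------
  wg <- config$wgcna
  trait_vec <- trait[colnames(prepped$expr)]
  modules_fit <- wgcna_modules(prepped$expr, trait = trait_vec,
                               power = wg$power,
                               min_module_size = wg$min_module_size,
                               cut_height = wg$cut_height,
                               merge_height = wg$merge_height,
                               mm_threshold = wg$mm_threshold,
                               gs_threshold = wg$gs_threshold,
                               target_r2 = wg$target_r2)
  note("wgcna", NA)

  # hub module: smallest adjusted module-trait p (reported significant
  # only if it clears FDR 0.05)
  mt <- modules_fit$module_trait
  hub_module <- NULL
  if (!is.null(mt) && nrow(mt)) {
    hub_module <- mt$module[which.min(mt$p_adj)]
  }
  hub_list <- if (!is.null(modules_fit$hubs)) {
    modules_fit$hubs$gene[modules_fit$hubs$hub &
                            modules_fit$hubs$module %in% hub_module]
  } else character(0)
  target_list <- if (!is.null(hub_module)) {
    names(modules_fit$labels)[modules_fit$labels == hub_module]
  } else character(0)

  # -- stage 8: ORA + EWCE -------------------------------------------------
  s8 <- derive_seed(config$seed, 8)
  universe <- rownames(prepped$expr)
  gene_sets <- generate_gene_sets(universe,
                                  atlas$ground_truth$module_labels[universe],
                                  seed = s8)
  en <- config$enrichment
  ora_res <- NULL; ewce_res <- NULL
  if (length(target_list)) {
    ora_res <- ora(intersect(target_list, universe), gene_sets, universe,
                   p_cutoff = en$p_cutoff, min_overlap = en$min_overlap,
                   min_enrichment = en$min_enrichment)
    cspec <- celltype_spec(enriched_module = config$celltype$enriched_module,
                           enrichment_fold = config$celltype$enrichment_fold,
                           seed = s8)
    ref <- generate_celltype_reference(
      universe, cspec, module_labels = atlas$ground_truth$module_labels[universe])
    ewce_res <- ewce_bootstrap(intersect(target_list, universe),
                               specificity(ref), n_boot = en$n_boot,
                               seed = s8)
  }
  note("enrichment", s8)

  # -- stage 9: validation -------------------------------------------------
  s9 <- derive_seed(config$seed, 9)
  va <- config$validation
  set.seed(s9)
  m1_genes <- names(atlas$ground_truth$module_labels)[
    atlas$ground_truth$module_labels == "M1"]
  de_genes <- sample(m1_genes, min(va$n_de, length(m1_genes)))
  dataset <- generate_validation_dataset(
    atlas$gene_ids, va$n_per_group, de_genes = de_genes,
    effect_sizes = rep(va$effect_size, length(de_genes)), seed = s9)
  overlap <- if (length(hub_list)) {
    suppressWarnings(deg_overlap(hub_list, dataset))
  } else NULL
  roc <- NULL
  if (!is.null(overlap) && overlap$n_overlap > 0) {
    top <- overlap$overlap[seq_len(min(3L, overlap$n_overlap))]
    roc <- lapply(top, function(g) {
      roc_auc(dataset$expr[g, ], dataset$group, positive = "case")
    })
    names(roc) <- top
  }
  note("validation", s9)

  # -- report: significant findings + ground-truth recovery ----------------
  sig_mods <- if (!is.null(mt)) mt[mt$p_adj < 0.05, , drop = FALSE] else mt
  sig_cells <- if (!is.null(ewce_res)) {
    ewce_res$cell_type[ewce_res$p_adj < 0.05]
  } else character(0)
  truth_labels <- atlas$ground_truth$module_labels[universe]
  planted <- cohort$ground_truth$planted_edges
  si_sig <- significant_components(nbs_si)
  recovery <- list(
    nbs_jaccard = if (!is.null(planted) && length(si_sig)) {
      max(vapply(si_sig, function(cp) edge_set_jaccard(cp$edges, planted),
                 numeric(1)))
    } else NA_real_,
    module_ari = adjusted_rand_index(truth_labels, modules_fit$labels),
    hub_module_is_planted = !is.null(hub_module) && {
      overlap_frac <- mean(truth_labels[target_list] == "M1")
      overlap_frac > 0.5
    },
    target_cell_type_detected = "GABAergic" %in% sig_cells,
    planted_trait_r = if (!is.null(mt) && !is.null(hub_module)) {
      mt$r[mt$module == hub_module][1L]
    } else NA_real_
  )
  report <- list(
    seed = config$seed,
    significant = list(
      nbs_si = lapply(si_sig, function(cp)
        list(n_edges = cp$n_edges, fwer_p = cp$fwer_p, mean_t = cp$mean_t)),
      nbs_sb = lapply(significant_components(nbs_sb), function(cp)
        list(n_edges = cp$n_edges, fwer_p = cp$fwer_p, mean_t = cp$mean_t)),
      anc_regions_fdr05 = sum(anc_groups$p_adj < 0.05),
      trait_modules = if (!is.null(sig_mods)) sig_mods$module else character(0),
      cell_types = sig_cells,
      overlap_genes = if (!is.null(overlap)) overlap$overlap else character(0),
      auc = if (!is.null(roc)) vapply(roc, `[[`, numeric(1), "auc")
            else numeric(0)
    ),
    recovery = recovery
  )

  result <- structure(list(
    config = config, cohort = cohort, anc = anc, anc_groups = anc_groups,
    anc_circuit = anc_circuit, nbs_si = nbs_si, nbs_sb = nbs_sb,
    trait = trait, atlas = atlas, prepped = prepped, modules = modules_fit,
    hub_module = hub_module, hub_genes = hub_list, ora = ora_res,
    ewce = ewce_res, validation = list(dataset = dataset, overlap = overlap,
                                       roc = roc),
    report = report, log = log), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# Write the pipeline's file outputs: phenotypes, atlas, module labels,
# ground-truth sidecars, BrainNet exports of significant components, the
# results JSON and a plain-text summary. File hashes land in the log.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_phenotypes(result$cohort$phenotypes, p("phenotypes.csv"))
  write_expression_matrix(result$prepped$expr, p("expression_atlas.tsv"))
  utils::write.csv(data.frame(gene = names(result$modules$labels),
                              module = unname(result$modules$labels)),
                   p("module_labels.csv"), row.names = FALSE)
  write_ground_truth(result$cohort$ground_truth, p("cohort_truth.json"))
  write_ground_truth(list(
    module_labels = as.list(result$atlas$ground_truth$module_labels),
    seed = result$atlas$ground_truth$seed), p("expression_truth.json"))
  sig <- significant_components(result$nbs_si)
  if (length(sig)) {
    n <- length(result$nbs_si$stat_map$region_labels)
    comp <- sig[[1L]]
    em <- matrix(0, n, n)
    em[comp$edges] <- abs(result$nbs_si$stat_map$t[comp$edges])
    em <- em + t(em)
    write_brainnet(result$cohort$centroids, em, p("nbs_si_component1"),
                   size = tabulate(comp$edges, n) + 1,
                   labels = result$nbs_si$stat_map$region_labels)
  }
  jsonlite::write_json(result$report, p("results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  writeLines(utils::capture.output(print(result)), p("summary.txt"))
  files <- list.files(out_dir, full.names = TRUE)
  result$log$hashes <- tools::md5sum(files)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("ctrlcircuit pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("Cohort:", length(x$cohort$networks), "subjects,",
      x$config$cohort$n_regions, "regions\n\n")
  print(x$nbs_si)
  print(x$nbs_sb)
  cat("\nANC regions with group differences (FDR < 0.05):",
      sum(x$anc_groups$p_adj < 0.05), "of", nrow(x$anc_groups), "\n\n")
  print(x$modules)
  if (!is.null(x$ewce)) {
    sig <- x$ewce$cell_type[x$ewce$p_adj < 0.05]
    cat("EWCE enriched cell types:",
        if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  }
  ov <- x$report$significant$overlap_genes
  cat("Validation overlap genes:",
      if (length(ov)) paste(ov, collapse = ", ") else "none", "\n")
  if (length(x$report$significant$auc)) {
    cat("AUC:", paste(sprintf("%s %.2f", names(x$report$significant$auc),
                              x$report$significant$auc), collapse = ", "),
        "\n")
  }
  invisible(x)
}
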