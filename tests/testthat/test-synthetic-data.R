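# Generators: determinism, planted-structure recoverability, degenerate
# and invalid specifications.

test_that("generators are fully determined by spec and seed", {
  s <- cohort_spec(n_per_group = c(MDDNSI = 5, MDDSI = 5), n_regions = 20,
                   planted_edges = path_edges(3), edge_effect = 1, seed = 9)
  a <- generate_connectome_cohort(s)
  b <- generate_connectome_cohort(s)
  expect_identical(a, b)
  ea <- generate_expression_atlas(expression_spec(n_genes = 100, n_regions = 30,
    modules = list(list(size = 20, cor = 0.6, trait_cor = 0.3)), seed = 4))
  eb <- generate_expression_atlas(expression_spec(n_genes = 100, n_regions = 30,
    modules = list(list(size = 20, cor = 0.6, trait_cor = 0.3)), seed = 4))
  expect_identical(ea, eb)
  va <- generate_validation_dataset(letters, 5, de_genes = "a",
                                    effect_sizes = 2, seed = 2)
  vb <- generate_validation_dataset(letters, 5, de_genes = "a",
                                    effect_sizes = 2, seed = 2)
  expect_identical(va, vb)
})

test_that("connectome cohort plants the stated edge attenuation", {
  # zero effect: planted-edge group means equal within sampling error on
  # 1000 subjects
  ch0 <- make_two_group_cohort(n = 500, n_regions = 30,
                               planted = path_edges(5), effect = 0, seed = 31)
  pe <- ch0$ground_truth$planted_edges
  mw <- vapply(ch0$networks, function(nt) mean(nt$A[pe]), numeric(1))
  grp <- ch0$phenotypes$group
  tt <- t.test(mw[grp == "MDDNSI"], mw[grp == "MDDSI"])
  expect_lt(abs(tt$statistic), 4)
  # effect 2.0, 90 regions, 10-edge path: group-mean difference of the
  # planted edges recomputed directly from the generated matrices
  ch <- make_two_group_cohort(n = 20, effect = 2, seed = 32)
  pe <- ch$ground_truth$planted_edges
  mw <- vapply(ch$networks, function(nt) mean(nt$A[pe]), numeric(1))
  grp <- ch$phenotypes$group
  diff_obs <- mean(mw[grp == "MDDNSI"]) - mean(mw[grp == "MDDSI"])
  expect_equal(diff_obs, 2 * 0.1, tolerance = 0.05)
  # matrices satisfy the structural-network invariants
  A <- ch$networks[[1]]$A
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A >= 0 & A <= 1))
})

test_that("cohort specs reject malformed planted structure", {
  expect_error(cohort_spec(n_regions = 20, planted_edges = cbind(19, 25)),
               "\\(19,25\\).*out of range")
  # two disconnected planted pairs
  expect_error(cohort_spec(n_regions = 20,
                           planted_edges = rbind(c(1, 2), c(5, 6))),
               "connected")
  expect_error(cohort_spec(n_regions = 5), "at least 10")
  expect_error(cohort_spec(edge_effect = -1), "nonnegative")
  expect_error(cohort_spec(n_per_group = c(20, 20)), "named")
})

test_that("expression atlas realises planted module structure", {
  # within-module correlation 1: member profiles identical up to affine
  at1 <- generate_expression_atlas(expression_spec(
    n_genes = 20, n_regions = 25,
    modules = list(list(size = 10, cor = 1, trait_cor = 0.5)), seed = 6))
  cors <- cor(t(at1$expr[1:10, ]))
  expect_equal(unname(cors), matrix(1, 10, 10), tolerance = 1e-12)
  # bookkeeping: 4 x 150 modules in 1000 genes leave exactly 400 background
  at <- generate_expression_atlas(expression_spec(seed = 8))
  expect_identical(sum(at$ground_truth$module_labels == "none"), 400L)
  expect_identical(as.integer(table(at$ground_truth$module_labels)[c("M1", "M2")]),
                   c(150L, 150L))
  # infeasible coupling rejected
  expect_error(expression_spec(modules = list(
    list(size = 10, cor = 0.5, trait_cor = 1))), "infeasible")
  expect_error(expression_spec(n_genes = 100, modules = list(
    list(size = 80, cor = 0.5, trait_cor = 0),
    list(size = 80, cor = 0.5, trait_cor = 0))), "more than n_genes")
})

test_that("uncoupled module eigengenes are uncorrelated with the trait", {
  # Monte-Carlo calibration: trait_cor = 0, 120 regions; the empirical
  # |cor(eigengene, trait)| stays below 0.2 in at least 95% of 200 seeds
  hits <- vapply(1:200, function(seed) {
    at <- generate_expression_atlas(expression_spec(
      n_genes = 160, n_regions = 120,
      modules = list(list(size = 150, cor = 0.7, trait_cor = 0)),
      seed = seed))
    me <- module_eigengene(at$expr,
                           names(at$ground_truth$module_labels)[
                             at$ground_truth$module_labels == "M1"])
    abs(cor(me, at$trait)) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("cell-type reference plants the stated specificity fold", {
  genes <- sprintf("g%03d", 1:300)
  labels <- setNames(rep(c("M1", "none"), each = 150), genes)
  # fold 1: specificity uniform in expectation
  ref0 <- generate_celltype_reference(genes,
    celltype_spec(cell_type_names = paste0("ct", 1:4), seed = 2))
  s0 <- specificity(ref0)
  expect_equal(unname(colMeans(s0)), rep(0.25, 4), tolerance = 0.02)
  # single cell type: the all-ones column
  ref1 <- generate_celltype_reference(genes,
    celltype_spec(cell_type_names = "only", seed = 2))
  expect_equal(unname(specificity(ref1)[, 1]), rep(1, 300))
  # fold 5 on module 1 of 4 cell types: closed form 5/8 vs 1/8
  ref5 <- generate_celltype_reference(genes,
    celltype_spec(cell_type_names = paste0("ct", 1:4), enriched_module = "M1",
                  enrichment_fold = 5, target_cell_type = "ct1", seed = 3),
    module_labels = labels)
  s5 <- specificity(ref5)
  m1 <- names(labels)[labels == "M1"]
  expect_equal(mean(s5[m1, "ct1"]), 5 / 8, tolerance = 0.03)
  expect_equal(mean(s5[m1, "ct2"]), 1 / 8, tolerance = 0.03)
  expect_error(generate_celltype_reference(genes,
    celltype_spec(enriched_module = "M9", enrichment_fold = 2),
    module_labels = labels), "unknown module")
  expect_error(celltype_spec(enrichment_fold = 0.5), ">= 1")
  expect_error(celltype_spec(cell_type_names = c("a", "a")), "unique")
})

test_that("validation dataset is null-calibrated and powered as planted", {
  genes <- sprintf("g%04d", 1:2000)
  # all effects zero: per-gene two-sample t p-values uniform
  d0 <- generate_validation_dataset(genes, 15, seed = 12)
  grp <- d0$group
  pvals <- apply(d0$expr, 1, function(x) {
    t.test(x[grp == "control"], x[grp == "case"])$p.value
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # effect 3.0, n = 30/30: per-gene AUC > 0.9 in at least 95% of 100 seeds
  hits <- vapply(1:100, function(seed) {
    d <- generate_validation_dataset("g1", 30, de_genes = "g1",
                                     effect_sizes = 3, seed = seed)
    roc_auc(d$expr[1, ], d$group, positive = "case")$auc > 0.9
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # degenerate and invalid inputs
  expect_error(generate_validation_dataset(genes, 0), "positive")
  expect_error(generate_validation_dataset(genes, 5, de_genes = "nope",
                                           effect_sizes = 1), "subset")
  expect_error(generate_validation_dataset(genes, 5, de_genes = "g0001",
                                           effect_sizes = c(1, 2)),
               "length")
})
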