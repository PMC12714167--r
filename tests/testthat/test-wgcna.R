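# Coexpression network construction: adjacency, TOM, soft-power
# selection, module detection, eigengenes, module-trait association, and
# the hub screen.

test_that("TOM matches hand-computed 3-gene fixtures and stays in [0,1]", {
  # all adjacencies 1: TOM_12 = (1 + 1) / (2 + 1 - 1) = 1
  a1 <- matrix(1, 3, 3)
  expect_equal(tom_matrix(a1)[1, 2], 1)
  # a_12 = 0, a_13 = a_23 = 1: TOM_12 = (1 + 0) / (1 + 1 - 0) = 0.5
  a2 <- matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 1), 3)
  expect_equal(tom_matrix(a2)[1, 2], 0.5)
  # a_12 = 1, all else 0: TOM_12 = (0 + 1) / (1 + 1 - 1) = 1
  a3 <- diag(3); a3[1, 2] <- a3[2, 1] <- 1
  expect_equal(tom_matrix(a3)[1, 2], 1)
  # random fixtures: TOM in [0,1], unit diagonal, permutation-equivariant
  set.seed(4)
  expr <- matrix(rnorm(40 * 25), 40)
  adj <- adjacency_matrix(expr, 6)
  tom <- tom_matrix(adj)
  expect_true(all(tom >= 0 & tom <= 1))
  expect_equal(unname(diag(tom)), rep(1, 40))
  expect_equal(tom, t(tom))
  perm <- sample(40)
  expect_equal(tom_matrix(adj[perm, perm]), tom[perm, perm],
               tolerance = 1e-12)
  expect_error(tom_matrix(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("raising the soft power shrinks sub-unit adjacencies", {
  set.seed(5)
  expr <- matrix(rnorm(30 * 20), 30)
  a6 <- adjacency_matrix(expr, 6)
  a8 <- adjacency_matrix(expr, 8)
  off <- upper.tri(a6)
  expect_true(all(a8[off] <= a6[off]))
  expect_true(all(a8[off][a6[off] < 1] < a6[off][a6[off] < 1]))
})

test_that("scale-free fit recognises power-law connectivity", {
  # planted Pareto degree sequence fits; equal connectivity does not
  set.seed(6)
  k <- (1 - runif(5000))^(-1 / 2.5)  # Pareto tail, alpha = 2.5
  expect_gte(ctrlcircuit:::scale_free_fit(k), 0.85)
  expect_identical(ctrlcircuit:::scale_free_fit(rep(3, 100)), 0)
  # degenerate expression: selection warns and returns the max-fit power
  set.seed(7)
  expr <- matrix(rnorm(30 * 15), 30)
  expect_warning(beta <- select_soft_power(expr, powers = 1:4), "no candidate")
  expect_true(beta %in% 1:4)
  expect_error(select_soft_power(expr[1:10, ]), "at least 20")
})

test_that("module detection recovers planted blocks and ignores noise", {
  # two duplicated 150-gene blocks: exactly two proper modules
  at <- generate_expression_atlas(expression_spec(
    n_genes = 320, n_regions = 60,
    modules = list(list(size = 150, cor = 0.95, trait_cor = 0),
                   list(size = 150, cor = 0.95, trait_cor = 0)),
    seed = 41))
  fit <- wgcna_modules(at$expr, min_module_size = 100)
  expect_length(fit$module_sizes, 2)
  expect_gte(adjusted_rand_index(at$ground_truth$module_labels, fit$labels),
             0.95)
  # pure noise: nearly everything lands in the background
  for (seed in 1:5) {
    set.seed(seed)
    noise <- matrix(rnorm(300 * 60), 300,
                    dimnames = list(sprintf("g%03d", 1:300), NULL))
    labels <- detect_modules(1 - tom_matrix(adjacency_matrix(noise, 12)),
                             min_module_size = 100)
    expect_gte(mean(labels == "grey"), 0.95)
  }
  # fewer genes than the minimum size: all background, with a warning
  d <- 1 - tom_matrix(adjacency_matrix(matrix(rnorm(30 * 20), 30), 6))
  expect_warning(lab <- detect_modules(d, min_module_size = 100),
                 "background")
  expect_true(all(lab == "grey"))
})

test_that("module eigengenes are oriented first principal components", {
  set.seed(8)
  profile <- rnorm(40)
  expr <- matrix(rep(profile, each = 10), 10, byrow = FALSE,
                 dimnames = list(paste0("g", 1:10), NULL))
  me <- module_eigengene(expr, paste0("g", 1:10))
  expect_equal(attr(me, "var_explained"), 1)
  expect_equal(abs(cor(me, profile)), 1, tolerance = 1e-12)
  # sign rule: flipping every input gene leaves the eigengene usable
  # (orientation re-aligns it with the members)
  me_f <- module_eigengene(-expr, paste0("g", 1:10))
  expect_gt(mean(cor(me_f, t(-expr))), 0.99)
  # anti-correlated halves: eigengene tracks one half positively, the
  # other negatively, both near 1 in magnitude
  half <- rbind(matrix(rep(profile, each = 5), 5, byrow = FALSE),
                matrix(rep(-profile, each = 5), 5, byrow = FALSE)) +
    matrix(rnorm(400, sd = 0.01), 10)
  rownames(half) <- paste0("h", 1:10)
  me_h <- module_eigengene(half, paste0("h", 1:10))
  cors <- cor(me_h, t(half))
  expect_true(all(abs(cors) > 0.99))
  expect_error(module_eigengene(expr, "g1"), "at least 2")
  # constant rows are dropped with a warning
  expr2 <- rbind(expr, g11 = rep(1, 40))
  expect_warning(module_eigengene(expr2, paste0("g", 1:11)), "constant")
})

test_that("module-trait association uses Pearson r with BH adjustment", {
  at <- generate_expression_atlas(expression_spec(
    n_genes = 120, n_regions = 50,
    modules = list(list(size = 50, cor = 0.8, trait_cor = 0.6),
                   list(size = 50, cor = 0.8, trait_cor = 0)),
    seed = 20))
  labels <- setNames(at$ground_truth$module_labels, at$gene_ids)
  me <- module_eigengenes(at$expr, labels)
  # a trait equal to an eigengene correlates at exactly 1
  mt_self <- module_trait(me, me[, 1])
  expect_equal(mt_self$r[mt_self$module == colnames(me)[1]], 1,
               tolerance = 1e-12)
  mt <- module_trait(me, at$trait)
  expect_true(all(mt$p_adj >= mt$p))
  expect_true(all(abs(mt$r) <= 1))
  expect_error(module_trait(me[1:3, , drop = FALSE], at$trait[1:3]),
               "fewer than 4")
})

test_that("the hub screen applies both the MM and GS thresholds", {
  n_r <- 60
  set.seed(22)
  trait <- rnorm(n_r)
  # module of 30 clones of the trait (hubs by construction) plus a module
  # orthogonal to the trait
  m1 <- matrix(rep(trait, each = 30), 30) + matrix(rnorm(30 * n_r, sd = 0.1), 30)
  ortho <- rnorm(n_r)
  m2 <- matrix(rep(ortho, each = 30), 30) + matrix(rnorm(30 * n_r, sd = 0.1), 30)
  expr <- rbind(m1, m2)
  rownames(expr) <- paste0("g", 1:60)
  labels <- setNames(rep(c("blue", "red"), each = 30), rownames(expr))
  hubs <- hub_genes(expr, labels, trait)
  expect_true(all(hubs$hub[hubs$module == "blue"]))
  # genes orthogonal to the trait are never hubs, whatever their MM
  expect_false(any(hubs$hub[hubs$module == "red"]))
  expect_true(all(abs(hubs$MM[hubs$module == "red"]) > 0.8))
  expect_error(hub_genes(expr, labels, trait, mm_threshold = 1.2), "mm_threshold")
})

test_that("near-duplicate modules merge by eigengene similarity", {
  set.seed(23)
  f <- rnorm(50)
  block <- function(n) matrix(rep(f, each = n), n) +
    matrix(rnorm(n * 50, sd = 0.15), n)
  expr <- rbind(block(120), block(120))
  rownames(expr) <- paste0("g", 1:240)
  labels <- setNames(rep(c("turquoise", "blue"), each = 120), rownames(expr))
  merged <- merge_similar_modules(expr, labels, merge_height = 0.25)
  expect_length(setdiff(unique(merged), "grey"), 1)
})

test_that("the NBS-derived trait sums |t| over significant circuit edges", {
  ch <- make_two_group_cohort(n = 12, n_regions = 30, planted = path_edges(4),
                              effect = 4, seed = 71)
  res <- nbs_test(ch$networks, ch$phenotypes$group == "MDDSI",
                  n_perm = 200, seed = 2)
  trait <- trait_from_nbs(res)
  sig <- significant_components(res)
  expect_gt(length(sig), 0)
  inside <- unique(unlist(lapply(sig, `[[`, "nodes")))
  expect_true(all(trait[inside] > 0))
  expect_true(all(trait[-inside] == 0))
  # interior path nodes accumulate two incident edges
  tmat <- res$stat_map$t
  comp <- sig[[which.max(vapply(sig, `[[`, integer(1), "n_edges"))]]
  e <- comp$edges
  manual <- numeric(30)
  for (r in seq_len(nrow(e))) {
    manual[e[r, 1]] <- manual[e[r, 1]] + abs(tmat[e[r, 1], e[r, 2]])
    manual[e[r, 2]] <- manual[e[r, 2]] + abs(tmat[e[r, 1], e[r, 2]])
  }
  if (length(sig) == 1) expect_equal(unname(trait), manual)
})
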