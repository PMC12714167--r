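# Network-based statistic: edgewise tests, component formation, the
# permutation FWER machinery, component strength, and behavioral partial
# correlations.

make_networks <- function(mats) {
  lapply(seq_along(mats), function(i) {
    structural_network(mats[[i]], subject_id = paste0("s", i))
  })
}

test_that("edgewise t-statistics behave like two-sample t-tests", {
  n <- 6
  base <- random_sym_matrix(n, seed = 1) / 2
  set.seed(2)
  jitter_net <- function(shift_edge = NULL, shift = 0) {
    A <- base + {
      e <- matrix(rnorm(n * n, sd = 0.05), n); e <- (e + t(e)) / 2; e
    }
    diag(A) <- 0
    A <- pmax(A, 0)
    if (!is.null(shift_edge)) {
      A[shift_edge[1], shift_edge[2]] <- A[shift_edge[1], shift_edge[2]] + shift
      A[shift_edge[2], shift_edge[1]] <- A[shift_edge[1], shift_edge[2]]
    }
    A
  }
  ga <- make_networks(replicate(5, jitter_net(c(1, 2), 0.5), simplify = FALSE))
  gb <- make_networks(replicate(5, jitter_net(), simplify = FALSE))
  st <- edgewise_tstats(ga, gb)
  # the shifted edge (+10 noise sd) carries the maximum |t|
  expect_equal(abs(st$t[1, 2]), max(abs(st$t)))
  expect_gt(st$t[1, 2], 0)
  # swapping groups negates every statistic
  st_sw <- edgewise_tstats(gb, ga)
  expect_equal(st_sw$t, -st$t)
  # identical constant groups: all statistics zero, p = 1
  const <- make_networks(replicate(6, base, simplify = FALSE))
  st0 <- edgewise_tstats(const[1:3], const[4:6])
  expect_true(all(st0$t == 0))
  expect_true(all(st0$p[upper.tri(st0$p)] == 1))
  expect_error(edgewise_tstats(ga[1:2], gb), "at least 3")
})

test_that("suprathreshold components are connected edge sets", {
  # hand-built statistic map: edges (1,2), (2,3), (4,5) suprathreshold
  n <- 6
  tmat <- matrix(0, n, n)
  for (e in list(c(1, 2), c(2, 3), c(4, 5))) {
    tmat[e[1], e[2]] <- tmat[e[2], e[1]] <- 10
  }
  sm <- list(t = tmat, df = 20, region_labels = paste0("R", 1:n))
  comps <- threshold_components(sm, primary_p = 0.001)
  sizes <- sort(vapply(comps, `[[`, integer(1), "n_edges"))
  expect_identical(sizes, c(1L, 2L))
  # empty suprathreshold set: no components
  sm0 <- list(t = matrix(0, n, n), df = 20, region_labels = sm$region_labels)
  expect_length(threshold_components(sm0), 0)
  # fully suprathreshold 5-clique: one component of 10 edges
  tc <- matrix(10, 5, 5); diag(tc) <- 0
  smc <- list(t = tc, df = 20, region_labels = paste0("R", 1:5))
  comps <- threshold_components(smc)
  expect_length(comps, 1)
  expect_identical(comps[[1]]$n_edges, 10L)
})

test_that("permutation FWER follows the (1+b)/(1+n_perm) convention", {
  ch <- make_two_group_cohort(n = 10, n_regions = 40, planted = path_edges(6),
                              effect = 4, seed = 51)
  labels <- ch$phenotypes$group == "MDDSI"
  res <- nbs_test(ch$networks, labels, n_perm = 100, seed = 3)
  sizes <- vapply(res$components, `[[`, integer(1), "n_edges")
  big <- which.max(sizes)
  # a dominant planted component beats every permutation: p = 1/101
  expect_equal(res$components[[big]]$fwer_p, 1 / 101)
  expect_true(all(vapply(res$components, `[[`, numeric(1), "fwer_p") > 0))
  # fixed seed reproduces the p-values exactly
  res2 <- nbs_test(ch$networks, labels, n_perm = 100, seed = 3)
  expect_identical(vapply(res$components, `[[`, numeric(1), "fwer_p"),
                   vapply(res2$components, `[[`, numeric(1), "fwer_p"))
  expect_error(nbs_test(ch$networks, labels, n_perm = 50), "at least 100")
})

test_that("component detection is invariant to region relabeling", {
  ch <- make_two_group_cohort(n = 10, n_regions = 30, planted = path_edges(5),
                              effect = 4, seed = 61)
  labels <- ch$phenotypes$group == "MDDSI"
  res <- nbs_test(ch$networks, labels, n_perm = 100, seed = 5)
  perm <- sample(30)
  permuted <- lapply(ch$networks, function(nt) {
    structural_network(nt$A[perm, perm], nt$region_labels[perm],
                       nt$subject_id)
  })
  res_p <- nbs_test(permuted, labels, n_perm = 100, seed = 5)
  sizes <- function(r) sort(vapply(r$components, `[[`, integer(1), "n_edges"))
  expect_identical(sizes(res), sizes(res_p))
  expect_identical(sort(vapply(res$components, `[[`, numeric(1), "fwer_p")),
                   sort(vapply(res_p$components, `[[`, numeric(1), "fwer_p")))
})

test_that("component strength is the plain mean of member edge weights", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.2
  A[2, 3] <- A[3, 2] <- 0.4
  A[3, 4] <- A[4, 3] <- 0.6
  net <- structural_network(A)
  comp <- list(edges = rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_equal(component_mean_strength(net, comp), 0.4)
  expect_equal(component_mean_strength(net, list(edges = rbind(c(2, 3)))), 0.4)
  expect_error(component_mean_strength(net, list(edges = NULL)), "no edges")
})

test_that("partial correlation residualizes on nuisance covariates", {
  set.seed(9)
  n <- 60
  covs <- data.frame(age = rnorm(n, 30, 8), sex = rbinom(n, 1, 0.5),
                     education = rnorm(n, 11, 3), med = rgamma(n, 2))
  x <- rnorm(n)
  # y = x exactly: partial r = 1 regardless of covariates
  out <- behavior_partial_correlation(x, data.frame(HAMD17 = x), covs)
  expect_equal(out$r, 1, tolerance = 1e-12)
  # all-zero covariates reduce to the plain Pearson correlation
  y <- rnorm(n)
  plain <- cor(x, y)
  zero_covs <- data.frame(a = rep(0, n), b = rep(0, n))
  out0 <- behavior_partial_correlation(x, data.frame(s = y), zero_covs)
  expect_equal(out0$r, plain, tolerance = 1e-12)
  # independent variables: partial r near zero at n = 1000
  set.seed(10)
  xx <- rnorm(1000); yy <- rnorm(1000)
  cc <- data.frame(c1 = rnorm(1000), c2 = rnorm(1000))
  expect_lt(abs(behavior_partial_correlation(xx, data.frame(s = yy), cc)$r),
            0.1)
  # Bonferroni multiplies by the number of scales in the battery
  batt <- behavior_partial_correlation(x, data.frame(s1 = y, s2 = rnorm(n),
                                                     s3 = rnorm(n)), covs)
  expect_equal(batt$p_bonf, pmin(1, batt$p * 3))
  # collinear covariates are rejected with the offending column named
  dup <- data.frame(age = covs$age, age2 = covs$age)
  expect_error(behavior_partial_correlation(x, data.frame(s = y), dup),
               "rank deficient")
})

test_that("circuit contrasts split the cohort as the merging rule states", {
  ch <- generate_connectome_cohort(cohort_spec(
    n_per_group = c(HC = 5, MDDNSI = 5, MDDSI = 6, MDDSB = 4),
    n_regions = 15, seed = 2))
  si <- circuit_contrast(ch$phenotypes, "SI")
  sb <- circuit_contrast(ch$phenotypes, "SB")
  ph <- ch$phenotypes
  expect_setequal(si$group_a, ph$subject_id[ph$group == "MDDSI"])
  expect_setequal(si$group_b, ph$subject_id[ph$group == "MDDNSI"])
  # non-SB group merges MDDNSI and MDDSI; HC appears in neither contrast
  expect_setequal(sb$group_b,
                  ph$subject_id[ph$group %in% c("MDDNSI", "MDDSI")])
  expect_length(intersect(ph$subject_id[ph$group == "HC"],
                          c(si$group_a, si$group_b, sb$group_a, sb$group_b)),
                0)
})
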