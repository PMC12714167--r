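# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (truncated series, exhaustive pairwise comparison, closed-form
# combinatorics) and never call the implementation they check.

path_edges <- function(n_edges = 10L) cbind(seq_len(n_edges), seq_len(n_edges) + 1L)

cycle_edges <- function(n_nodes = 10L) cbind(seq_len(n_nodes), c(seq_len(n_nodes)[-1], 1L))

# random symmetric nonnegative zero-diagonal matrix
random_sym_matrix <- function(n, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n), n)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# truncated-series oracle for average controllability:
# sum_{t=0}^{T} ||A^t e_k||^2 via repeated matrix-vector products
series_controllability <- function(A, k, T = 1000L) {
  v <- numeric(nrow(A)); v[k] <- 1
  total <- 0
  for (t in 0:T) {
    total <- total + sum(v^2)
    v <- A %*% v
  }
  total
}

# exhaustive pairwise AUC oracle (ties count 1/2)
brute_force_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# closed-form hypergeometric upper tail P(X >= k) via exact combinatorics
hyper_upper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# tiny two-group cohort used across NBS / controllability tests
make_two_group_cohort <- function(n = 20, n_regions = 90, planted = path_edges(10),
                                  effect = 2, seed = 1, noise_sd = 0.1) {
  spec <- cohort_spec(n_per_group = c(MDDNSI = n, MDDSI = n),
                      n_regions = n_regions, planted_edges = planted,
                      edge_effect = effect, affected_group = "MDDSI",
                      noise_sd = noise_sd, seed = seed)
  generate_connectome_cohort(spec)
}
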