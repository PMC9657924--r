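# Independent brute-force oracles used by the tests. These deliberately take
# the slow, literal route so they stay independent of the package internals.

# ssGSEA as the literal position-by-position running sum: walk genes in
# decreasing rank order and accumulate P_in - P_out.
naive_ssgsea <- function(ranks, in_set, alpha) {
  n <- length(ranks)
  walk <- order(ranks, decreasing = TRUE)
  w <- ifelse(in_set, ranks^alpha, 0)[walk]
  out <- (!in_set)[walk]
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(out) / sum(out)
  sum(p_in - p_out)
}

# BH step-up by direct evaluation of q_(i) = min_{j>=i} p_(j) m / j, O(m^2).
naive_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# Adaptive-kernel Markov operator evaluated entry by entry from a distance
# matrix (no truncation shortcuts beyond the literal k-neighbor rule).
naive_markov <- function(D, k, ka) {
  n <- nrow(D)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    others <- setdiff(order(D[i, ]), i)
    nb <- others[seq_len(k)]
    sigma <- D[i, nb[ka]]
    if (sigma == 0) sigma <- min(D[i, nb][D[i, nb] > 0], 1)
    for (j in c(i, nb)) A[i, j] <- exp(-(D[i, j] / sigma)^2)
  }
  A <- (A + t(A)) / 2
  A / rowSums(A)
}

# Macro-averaged per-class recall of predicted vs true TMM labels.
macro_accuracy <- function(truth, predicted) {
  mean(vapply(unique(truth), function(l) {
    mean(predicted[truth == l] == l)
  }, numeric(1)))
}

# Small simulated cohort shared by several tests.
small_cohort <- function(seed = 42, n_cells = 150, n_genes = 600, ...) {
  cfg <- sim_config(n_cells = n_cells, n_genes = n_genes, seed = seed, ...)
  sets <- demo_tmm_sets(cfg, genes_per_set = 20L)
  list(config = cfg, sets = sets, sim = simulate_cohort(cfg, sets))
}
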