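# Entropy, clustering, marker summaries and the ZINB two-part DE test.

test_that("entropy closed forms and bounds", {
  X <- rbind(uniform = rep(1, 100), onehot = c(1, rep(0, 99)))
  colnames(X) <- sprintf("g%03d", 1:100)
  H <- cell_entropy(X)
  expect_equal(unname(H["uniform"]), log(100))
  expect_equal(unname(H["onehot"]), 0)
  set.seed(61)
  Y <- matrix(rexp(50 * 80), 50, 80,
              dimnames = list(sprintf("c%02d", 1:50), sprintf("g%02d", 1:80)))
  H2 <- cell_entropy(Y)
  expect_true(all(H2 >= 0 & H2 < log(80)))   # strict: rexp draws never uniform
  expect_error(cell_entropy(rbind(Y, zero = 0)), "all-zero")
})

test_that("cluster_cells recovers planted blobs and is deterministic", {
  set.seed(62)
  lab <- rep(1:2, each = 30)
  X <- matrix(rnorm(60 * 20, mean = c(0, 6)[lab]), 60, 20,
              dimnames = list(sprintf("c%02d", 1:60), sprintf("g%02d", 1:20)))
  cl <- cluster_cells(X, cluster_params(n_clusters = 2, n_pcs = 5, seed = 1))
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl, lab), 1.0)
  cl2 <- cluster_cells(X, cluster_params(n_clusters = 2, n_pcs = 5, seed = 1))
  expect_identical(cl, cl2)
  # boundary: n_clusters = n_cells - 1 on 5 cells still yields valid labels
  small <- X[1:5, ]
  cl3 <- cluster_cells(small, cluster_params(n_clusters = 4, seed = 2))
  expect_length(cl3, 5L)
  expect_true(all(cl3 %in% 1:4))
  expect_error(cluster_cells(small, cluster_params(n_clusters = 5)),
               "smaller than the number of cells")
})

test_that("entropy_by_cluster summarizes and finds a planted high-entropy cluster", {
  set.seed(63)
  # cluster 2 cells spread mass evenly -> high entropy
  flat <- matrix(1 + rexp(30 * 50, 10), 30, 50)
  spiky <- matrix(rexp(30 * 50)^4 + 1e-3, 30, 50)
  X <- rbind(spiky, flat)
  dimnames(X) <- list(sprintf("c%02d", 1:60), sprintf("g%02d", 1:50))
  H <- cell_entropy(X)
  labels <- stats::setNames(rep(1:2, each = 30), rownames(X))
  calls <- data.frame(cell_id = rownames(X), tel_q = 1, alt_q = 1,
                      label = rep(c("NDTMM", "ALT-like"), 30),
                      stringsAsFactors = FALSE)
  tab <- entropy_by_cluster(H, labels, calls)
  expect_equal(tab$cluster, 1:2)
  expect_gt(tab$mean_entropy[2], tab$mean_entropy[1])
  expect_lt(tab$q_vs_rest[2], 0.05)
  pct_cols <- grep("^pct_", names(tab))
  expect_true(all(abs(rowSums(tab[, pct_cols]) - 100) < 1e-9))
  # constant-entropy cluster reports that value as mean and median
  Hc <- stats::setNames(c(rep(2, 5), rep(3, 5)), sprintf("c%02d", 1:10))
  lc <- stats::setNames(rep(1:2, each = 5), names(Hc))
  tc <- entropy_by_cluster(Hc, lc)
  expect_equal(tc$mean_entropy, c(2, 3))
  expect_equal(tc$median_entropy, c(2, 3))
})

test_that("marker_summary ranks planted shifts and handles degenerate groups", {
  set.seed(64)
  n <- 120
  labels <- sample(rep(TMM_LABELS, n / 4))
  X <- matrix(rexp(n * 3), n, 3,
              dimnames = list(sprintf("c%03d", 1:n),
                              c("MKI67", "PML", "FLAT")))
  X[labels == "TEL+ALT-like", "MKI67"] <- X[labels == "TEL+ALT-like",
                                            "MKI67"] * 2 + 2
  X[, "FLAT"] <- 1
  calls <- data.frame(cell_id = rownames(X), tel_q = 1, alt_q = 1,
                      label = labels, stringsAsFactors = FALSE)
  expect_warning(tab <- marker_summary(X, c("MKI67", "PML", "FLAT", "NOPE"),
                                       calls), "NOPE")
  mk <- tab[tab$marker == "MKI67", ]
  expect_equal(mk$label[which.max(mk$mean)], "TEL+ALT-like")
  expect_lt(mk$q_vs_rest[mk$label == "TEL+ALT-like"], 0.01)
  expect_true(all(tab$p_vs_rest[tab$marker == "FLAT"] == 1))
  # single-cell group -> mean reported, p-value NA
  calls2 <- calls
  calls2$label <- c("TEL", rep("NDTMM", n - 1))
  tab2 <- marker_summary(X, "PML", calls2)
  expect_equal(tab2$mean[tab2$label == "TEL"], X[1, "PML"])
  expect_true(is.na(tab2$p_vs_rest[tab2$label == "TEL"]))
  expect_error(suppressWarnings(marker_summary(X, "NOPE", calls)),
               "none of the markers")
})

rzinb <- function(n, pi, mu, theta) {
  ifelse(stats::runif(n) < pi, 0L, stats::rnbinom(n, mu = mu, size = theta))
}

test_that("zinb_fit recovers planted parameters and the pure-NB edge", {
  set.seed(1)
  x <- rzinb(2000, 0.3, 5, 2)
  fit <- zinb_fit(x)
  expect_lt(abs(fit$pi - 0.3), 0.1)
  expect_lt(abs(fit$mu - 5) / 5, 0.15)
  expect_lt(abs(fit$theta - 2) / 2, 0.15)
  # optimizer never degrades the deterministic start
  init <- scTMM:::zinb_init(x)
  expect_gte(fit$loglik,
             scTMM:::zinb_loglik(x, init["pi"], init["mu"], init["theta"]))
  # pure NB data -> near-zero inflation
  y <- stats::rnbinom(2000, mu = 5, size = 2)
  expect_lt(zinb_fit(y)$pi, 0.05)
  # degenerate all-zero vector -> boundary, no crash
  z <- zinb_fit(rep(0L, 50))
  expect_true(z$boundary)
  expect_equal(z$pi, 1)
  expect_true(is.na(z$mu))
  expect_error(zinb_fit(c(1.5, rep(1, 20))), "integers")
  expect_error(zinb_fit(c(1, 2, 3)), "at least 10")
})

test_that("two-group LRT statistics are non-negative with planted effects detected", {
  set.seed(66)
  n <- 200
  counts <- cbind(
    de_zero = c(rzinb(n, 0.6, 5, 2), rzinb(n, 0.2, 5, 2)),
    de_mu = c(rzinb(n, 0.3, 4, 2), rzinb(n, 0.3, 8, 2)),
    null1 = rzinb(2 * n, 0.3, 5, 2),
    null2 = rzinb(2 * n, 0.1, 2, 1)
  )
  rownames(counts) <- sprintf("c%03d", seq_len(2 * n))
  A <- rownames(counts)[1:n]; B <- rownames(counts)[(n + 1):(2 * n)]
  res <- de_two_group(counts, A, B)
  expect_true(all(res$p_overall >= 0 & res$p_overall <= 1))
  expect_equal(res$de_class[res$gene == "de_zero"], "DEs")
  expect_equal(res$de_class[res$gene == "de_mu"], "DEa")
  expect_true(all(res$de_class[res$gene %in% c("null1", "null2")] == "none"))
  expect_error(de_two_group(counts, A[1:5], B), "at least 10")
  expect_error(de_two_group(counts, A, c(A[1], B[-1])), "disjoint")
})
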