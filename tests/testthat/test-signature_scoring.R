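# Per-cell ssGSEA: ranking, the enrichment statistic, and matrix scoring.

test_that("rank_cell ranks, breaks ties by gene id, ignores monotone maps", {
  expect_equal(unname(rank_cell(c(4, 3, 2, 1))), c(4L, 3L, 2L, 1L))
  # constant vector: deterministic id-order ranks
  x <- stats::setNames(rep(1, 4), c("d", "b", "a", "c"))
  expect_equal(rank_cell(x), c(d = 4L, b = 2L, a = 1L, c = 3L))
  y <- stats::setNames(c(0.1, 5, 2, 0.1), c("g2", "g1", "g3", "g0"))
  expect_equal(rank_cell(y), rank_cell(exp(3 * y)))
  expect_error(rank_cell(1), "at least 2")
})

test_that("hand-computed enrichment scores come out exactly", {
  ranks <- stats::setNames(c(4L, 3L, 2L, 1L), c("a", "b", "c", "d"))
  # top-1 set, alpha = 1: running sum (1-0)+(1-1/3)+(1-2/3)+(1-1) = 2
  expect_equal(ssgsea_es(ranks, "a", alpha = 1), 2.0)
  expect_equal(ssgsea_es(ranks, "d", alpha = 1), -2.0)   # mirror case
  expect_error(ssgsea_es(ranks, c("a", "b", "c", "d")), "whole universe")
  expect_error(ssgsea_es(ranks, "zz"), "no overlap")
})

test_that("closed form matches the naive running-sum oracle exhaustively", {
  set.seed(41)
  for (rep in 1:200) {
    n <- sample(3:8, 1)
    g <- sample(seq_len(min(4, n - 1)), 1)
    ranks <- stats::setNames(sample.int(n), sprintf("g%02d", sample.int(n)))
    in_set <- seq_len(n) %in% sample.int(n, g)
    for (alpha in c(0, 0.25, 1)) {
      expect_equal(ssgsea_es(ranks, names(ranks)[in_set], alpha),
                   naive_ssgsea(unname(ranks), in_set, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("alpha = 0 scores of random sets are centered at zero", {
  set.seed(42)
  n <- 50; m <- 8
  ranks <- stats::setNames(sample.int(n), sprintf("g%02d", 1:n))
  es <- replicate(1e4, ssgsea_es(ranks, names(ranks)[sample.int(n, m)],
                                 alpha = 0))
  expect_lt(abs(mean(es)), 3 * stats::sd(es) / sqrt(length(es)))
})

test_that("score_matrix composes, skips thin sets, and is rank-invariant", {
  set.seed(43)
  X <- matrix(rexp(6 * 20), 6, 20,
              dimnames = list(sprintf("c%d", 1:6), sprintf("g%02d", 1:20)))
  gs <- gene_set_collection(list(A = c("g01", "g05", "g11"),
                                 B = c("g02", "g19"),
                                 C = c("zz1", "zz2", "zz3")),
                            groups = c(A = "TEL", B = "ALT"))
  expect_warning(S <- score_matrix(X, gs, scoring_params(normalize = FALSE)),
                 "skipping")
  expect_equal(colnames(S), "A")       # B under min overlap, C disjoint
  expect_equal(S["c3", "A"],
               ssgsea_es(rank_cell(X["c3", ]), gs$sets$A, 0.25))
  # scores ignore the expression scale entirely
  expect_equal(unname(suppressWarnings(score_matrix(X * 2, gs,
                                                    scoring_params()))),
               unname(suppressWarnings(score_matrix(X, gs,
                                                    scoring_params()))))
  # one cell, one set reduces to a single ssgsea_es value
  gs1 <- gene_set_collection(list(A = c("g01", "g05", "g11")))
  S1 <- score_matrix(X[1, , drop = FALSE], gs1,
                     scoring_params(normalize = FALSE))
  expect_equal(dim(S1), c(1L, 1L))
  expect_equal(S1[1, 1], ssgsea_es(rank_cell(X[1, ]), gs1$sets$A, 0.25))
  expect_error(suppressWarnings(score_matrix(X, gene_set_collection(
    list(C = "zz")))), "no usable")
})

test_that("normalized scores lie in [-1, 1] and keep their ordering", {
  h <- small_cohort(seed = 44)
  X <- as.matrix(lognormalize(h$sim$counts))
  raw <- score_matrix(X, h$sets, scoring_params(normalize = FALSE))
  nrm <- score_matrix(X, h$sets, scoring_params(normalize = TRUE))
  expect_true(all(nrm >= -1 & nrm <= 1))
  expect_equal(nrm * (max(raw) - min(raw)), raw, ignore_attr = TRUE)
})

test_that("planted activity raises scores in activated cells", {
  h <- small_cohort(seed = 45, n_cells = 400, signature_lfc = 2,
                    tmm_props = c("TEL" = 0.5, "ALT-like" = 0,
                                  "TEL+ALT-like" = 0, "NDTMM" = 0.5))
  X <- as.matrix(lognormalize(h$sim$counts))
  S <- score_matrix(X, h$sets)
  tel_sets <- names(h$sets$sets)[h$sets$group == "TEL"]
  active <- h$sim$truth$tmm_type == "TEL"
  for (s in tel_sets) {
    p <- stats::wilcox.test(S[active, s], S[!active, s],
                            alternative = "greater")$p.value
    expect_lt(p, 1e-4)
  }
})

test_that("mean planted-set score rises monotonically with signature_lfc", {
  means <- vapply(c(0, 0.5, 1, 1.5, 2), function(lfc) {
    h <- small_cohort(seed = 46, n_cells = 120, signature_lfc = lfc,
                      tmm_props = c("TEL" = 1, "ALT-like" = 0,
                                    "TEL+ALT-like" = 0, "NDTMM" = 0))
    X <- as.matrix(lognormalize(h$sim$counts))
    S <- score_matrix(X, h$sets, scoring_params(normalize = FALSE))
    mean(S[, h$sets$group == "TEL"])
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
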