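# Permutation significance, BH correction, and the four-type TMM call.

test_that("add-one permutation p-values hit their closed-form edges", {
  # one dominant cell: its observed ES should beat every null draw
  set.seed(51)
  n_genes <- 60
  X <- matrix(rexp(40 * n_genes), 40, n_genes,
              dimnames = list(sprintf("c%02d", 1:40),
                              sprintf("g%02d", 1:n_genes)))
  set_genes <- c("g05", "g17", "g29", "g41", "g53")
  X[1, set_genes] <- max(X) * c(5, 6, 7, 8, 9)    # top ranks in cell 1
  pp <- permutation_params(n_perm = 999, seed = 1, match_bins = 0L)
  p <- permutation_pvalues(X, set_genes, pp)
  expect_equal(unname(p["c01"]), 1 / 1000)
  expect_true(all(p > 0 & p <= 1))
  # a cell where the set genes are forced to the bottom -> p = 1
  X[2, set_genes] <- -1
  p2 <- permutation_pvalues(X, set_genes, pp)
  expect_equal(unname(p2["c02"]), 1)
  expect_error(permutation_params(n_perm = 50), "n_perm")
})

test_that("null-cohort p-values are approximately uniform per cell set", {
  pass <- 0L
  for (seed in 1:10) {
    cfg <- sim_config(n_cells = 300, n_genes = 800, seed = seed)
    sets <- demo_tmm_sets(cfg, genes_per_set = 25L)
    sim <- simulate_null_cohort(cfg, sets)
    X <- as.matrix(lognormalize(sim$counts))
    p <- permutation_pvalues(X, sets$sets[[1]],
                             permutation_params(n_perm = 1000,
                                                seed = seed + 100))
    ks <- suppressWarnings(stats::ks.test(p, "punif"))
    if (ks$p.value > 0.01) pass <- pass + 1L
  }
  expect_gte(pass, 9L)
})

test_that("bh_fdr reproduces the step-up by hand and by oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)            # m = 1
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(52)
  for (rep in 1:50) {
    p <- stats::runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), naive_bh(p), tolerance = 1e-12)
  }
})

test_that("classify_cells follows the four-type truth table", {
  qmat <- matrix(c(0.001, 0.5,
                   0.001, 0.005,
                   0.5,   0.5,
                   0.2,   0.003), ncol = 2, byrow = TRUE,
                 dimnames = list(paste0("c", 1:4), c("telset", "altset")))
  groups <- c(telset = "TEL", altset = "ALT")
  calls <- classify_cells(qmat, groups, permutation_params())
  expect_equal(calls$label, c("TEL", "TEL+ALT-like", "NDTMM", "ALT-like"))
  expect_equal(calls$tel_q, unname(qmat[, 1]))
  expect_error(classify_cells(qmat, c(telset = "TEL"), permutation_params()),
               "ALT-group")
})

test_that("group_rule any/majority/all order from permissive to strict", {
  qmat <- matrix(c(0.001, 0.5, 0.5, 0.9, 0.9, 0.9), nrow = 1,
                 dimnames = list("c1", paste0("s", 1:6)))
  groups <- stats::setNames(rep(c("TEL", "ALT"), each = 3), paste0("s", 1:6))
  q_any <- classify_cells(qmat, groups, permutation_params(group_rule = "any"))
  q_maj <- classify_cells(qmat, groups,
                          permutation_params(group_rule = "majority"))
  q_all <- classify_cells(qmat, groups, permutation_params(group_rule = "all"))
  expect_equal(q_any$tel_q, 0.001)
  expect_equal(q_maj$tel_q, 0.5)
  expect_equal(q_all$tel_q, 0.5)
  expect_equal(c(q_any$label, q_maj$label, q_all$label),
               c("TEL", "NDTMM", "NDTMM"))
})

test_that("tmm_classify is deterministic and recovers planted labels", {
  cfg <- sim_config(n_cells = 400, n_genes = 1200, seed = 53,
                    signature_lfc = 2)
  sets <- demo_tmm_sets(cfg, genes_per_set = 25L)
  sim <- simulate_cohort(cfg, sets)
  X <- magic_impute(lognormalize(sim$counts))
  pp <- permutation_params(n_perm = 1000, seed = 54)
  a <- tmm_classify(X, sets, pp)
  b <- tmm_classify(X, sets, pp)
  expect_identical(a$label, b$label)
  truth <- stats::setNames(sim$truth$tmm_type, sim$truth$cell_id)
  expect_gt(macro_accuracy(truth[a$cell_id], a$label), 0.85)
})

test_that("null cohorts stay almost entirely NDTMM at FDR 0.01", {
  cfg <- sim_config(n_cells = 500, n_genes = 1000, seed = 55)
  sets <- demo_tmm_sets(cfg, genes_per_set = 25L)
  sim <- simulate_null_cohort(cfg, sets)
  X <- as.matrix(lognormalize(sim$counts))
  calls <- tmm_classify(X, sets, permutation_params(n_perm = 1000, seed = 56))
  expect_lte(mean(calls$label != "NDTMM"), 0.02)
})

test_that("tmm_frequency tabulates counts and percentages per cell type", {
  calls <- data.frame(cell_id = sprintf("c%d", 1:10),
                      tel_q = 0.5, alt_q = 0.5,
                      label = c(rep("ALT-like", 4), rep("NDTMM", 6)),
                      stringsAsFactors = FALSE)
  freq <- tmm_frequency(calls, rep("adeno", 10))
  expect_equal(freq$pct[freq$label == "ALT-like"], 40)
  expect_equal(sum(freq$pct), 100)
  # two cell types: percentages sum to 100 within each
  types <- stats::setNames(rep(c("adeno", "fibro"), each = 5), calls$cell_id)
  freq2 <- tmm_frequency(calls, types)
  sums <- tapply(freq2$pct, freq2$cell_type, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
  # single cell -> a single 100% entry
  freq3 <- tmm_frequency(calls[1, ], "adeno")
  expect_equal(freq3$pct[freq3$label == "ALT-like"], 100)
  expect_error(tmm_frequency(calls, stats::setNames("adeno", "zz")),
               "not covered")
})
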