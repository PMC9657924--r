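#' Parameters for permutation significance and TMM calling
#'
#' @param n_perm Number of permutation null draws (>= 100). The default
#'   10,000 is a desk-scale choice; the original analysis scale (10^7 runs)
#'   is reachable by configuration.
#' @param seed Seed for the null draws.
#' @param fdr_threshold BH q-value threshold declaring a pathway group active
#'   in a cell (default 0.01).
#' @param group_rule How member-set q-values combine into a TEL/ALT group
#'   q-value: `"any"` (min, default), `"majority"` (median), `"all"` (max).
#' @param match_bins Number of mean-expression bins used to draw
#'   expression-matched null gene sets (Tirosh-style control sets); each null
#'   gene is sampled from the same bin as the signature gene it replaces.
#'   `0` disables matching (plain uniform resampling from the universe).
#' @return A validated `permutation_params` list.
#' @export
permutation_params <- function(n_perm = 10000L, seed = 1L,
                               fdr_threshold = 0.01,
                               group_rule = c("any", "majority", "all"),
                               match_bins = 25L) {
  group_rule <- match.arg(group_rule)
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  assert_that(fdr_threshold > 0 && fdr_threshold < 1,
              "fdr_threshold must lie in (0, 1)")
  assert_that(match_bins >= 0, "match_bins must be >= 0")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fdr_threshold = fdr_threshold, group_rule = group_rule,
                 match_bins = as.integer(match_bins)),
            class = "permutation_params")
}

#' Per-cell permutation p-values for one gene set
#'
#' The null is gene-label resampling: `n_perm` random gene sets of the same
#' effective size are drawn (without replacement, seeded) from the matrix
#' universe, and each cell's observed enrichment score is compared with its
#' own null scores. The identical null draws are shared by all cells, so the
#' null preserves each cell's rank distribution. By default the draws are
#' expression-matched (Tirosh-style control sets): genes are binned by mean
#' expression across cells and each null gene is sampled from the bin of the
#' signature gene it stands in for, so that a signature composed of
#' systematically strong (or weak) genes is not called active in every cell
#' merely because of its expression level. The add-one estimator
#' `p = (1 + #\{null ES >= observed ES\}) / (n_perm + 1)` is used.
#'
#' @param expr Cells x genes expression matrix (typically imputed).
#' @param gene_set Character vector of set member ids.
#' @param params A `permutation_params` object.
#' @param alpha ssGSEA weight exponent.
#' @param tie_break Tie-break rule for ranking, as in [scoring_params()].
#' @param ranks Optional precomputed internal rank matrix of `expr` (the
#'   matrix is then only used for dimnames and expression matching).
#' @return Named numeric vector of per-cell p-values in (0, 1\].
#' @export
permutation_pvalues <- function(expr, gene_set,
                                params = permutation_params(),
                                alpha = 0.25,
                                tie_break = c("cellwise", "lexicographic"),
                                ranks = NULL) {
  stopifnot(inherits(params, "permutation_params"))
  R <- ranks %||% rank_matrix(expr, match.arg(tie_break))
  universe <- colnames(R)
  m <- sum(universe %in% gene_set)
  assert_that(m >= 1 && m < ncol(R),
              "gene set must overlap the universe without covering it")

  obs_idx <- which(universe %in% gene_set)
  Zobs <- Matrix::sparseMatrix(i = obs_idx, j = rep(1L, m), x = 1,
                               dims = c(ncol(R), 1L))
  obs <- es_matrix(R, Zobs, m, alpha)[, 1L]

  null_idx <- withr::with_seed(params$seed, {
    if (params$match_bins > 0L) {
      draw_matched_sets(expr, universe %in% gene_set, params$n_perm,
                        params$match_bins)
    } else {
      matrix(unlist(lapply(seq_len(params$n_perm), function(i) {
        sample.int(ncol(R), m)
      })), nrow = m)
    }
  })
  Z <- Matrix::sparseMatrix(i = as.vector(null_idx),
                            j = rep(seq_len(params$n_perm), each = m),
                            x = 1, dims = c(ncol(R), params$n_perm))
  null_es <- es_matrix(R, Z, rep(m, params$n_perm), alpha)
  p <- (1 + rowSums(null_es >= obs)) / (params$n_perm + 1)
  stats::setNames(p, rownames(R))
}

# Expression-matched null index draws. Genes are cut into `nbins` groups of
# near-equal size by mean expression; for each permutation, every signature
# gene is replaced by a gene sampled without replacement from its own bin
# (falling back to the whole universe if a bin is exhausted).
draw_matched_sets <- function(expr, in_set, n_perm, nbins) {
  mean_expr <- Matrix::colMeans(expr)
  n <- length(mean_expr)
  nbins <- min(nbins, n)
  bin <- ceiling(rank(mean_expr, ties.method = "first") / (n / nbins))
  by_bin <- split(seq_len(n), bin)
  need <- table(bin[in_set])
  m <- sum(in_set)
  idx <- matrix(0L, nrow = m, ncol = n_perm)
  for (j in seq_len(n_perm)) {
    draw <- integer(0)
    for (b in names(need)) {
      pool <- by_bin[[b]]
      take <- min(need[[b]], length(pool))
      draw <- c(draw, pool[sample.int(length(pool), take)])
    }
    if (length(draw) < m) {
      extra <- setdiff(seq_len(n), draw)
      draw <- c(draw, extra[sample.int(length(extra), m - length(draw))])
    }
    idx[, j] <- draw
  }
  idx
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR control: `q_(i) = min_{j >= i} (p_(j) * m / j)`, capped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  assert_that(all(is.finite(pvalues)) && all(pvalues >= 0 & pvalues <= 1),
              "p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify cells into four TMM types from per-set q-values
#'
#' Member-set q-values are combined into one TEL and one ALT group q-value
#' per cell (`any` = min, `majority` = median, `all` = max); a group is
#' active when its q-value is below `fdr_threshold`. Labels follow the truth
#' table: TEL active only -> `TEL`; ALT active only -> `ALT-like`; both ->
#' `TEL+ALT-like`; neither -> `NDTMM`.
#'
#' @param qmat Cells x sets matrix of q-values (dimnames required).
#' @param groups Named character vector mapping set names to `TEL`/`ALT`;
#'   both groups must have at least one usable set among the columns.
#' @param params A `permutation_params` object.
#' @return Data frame with `cell_id`, `tel_q`, `alt_q`, `label`.
#' @export
classify_cells <- function(qmat, groups, params = permutation_params()) {
  stopifnot(inherits(params, "permutation_params"))
  tel_sets <- intersect(colnames(qmat), names(groups)[groups == "TEL"])
  alt_sets <- intersect(colnames(qmat), names(groups)[groups == "ALT"])
  assert_that(length(tel_sets) > 0, "no usable TEL-group sets")
  assert_that(length(alt_sets) > 0, "no usable ALT-group sets")
  combine <- switch(params$group_rule,
                    any = function(x) apply(x, 1L, min),
                    majority = function(x) apply(x, 1L, stats::median),
                    all = function(x) apply(x, 1L, max))
  tel_q <- combine(qmat[, tel_sets, drop = FALSE])
  alt_q <- combine(qmat[, alt_sets, drop = FALSE])
  tel_on <- tel_q < params$fdr_threshold
  alt_on <- alt_q < params$fdr_threshold
  label <- ifelse(tel_on & alt_on, "TEL+ALT-like",
                  ifelse(tel_on, "TEL",
                         ifelse(alt_on, "ALT-like", "NDTMM")))
  data.frame(cell_id = rownames(qmat), tel_q = tel_q, alt_q = alt_q,
             label = label, stringsAsFactors = FALSE, row.names = NULL)
}

#' End-to-end TMM typing of an expression matrix
#'
#' For every TEL- or ALT-tagged set in `sets`: per-cell permutation p-values
#' ([permutation_pvalues()], null draws shared across sets through the same
#' seed base), BH correction across cells within each set, then
#' [classify_cells()].
#'
#' @param expr Cells x genes expression matrix (typically imputed).
#' @param sets A `GeneSetCollection` with TEL/ALT group tags.
#' @param params A `permutation_params` object.
#' @param scoring A `scoring_params` object (only `alpha` and
#'   `min_set_overlap` are used here).
#' @return Data frame as [classify_cells()], with the per-set q-value matrix
#'   attached as attribute `qmat`.
#' @export
tmm_classify <- function(expr, sets, params = permutation_params(),
                         scoring = scoring_params()) {
  tmm_sets <- names(sets$sets)[sets$group %in% c("TEL", "ALT")]
  assert_that(length(tmm_sets) > 0, "collection has no TEL/ALT-tagged sets")
  universe <- colnames(expr)
  sizes <- vapply(sets$sets[tmm_sets],
                  function(g) sum(universe %in% g), integer(1))
  usable <- sizes >= scoring$min_set_overlap & sizes < ncol(expr)
  if (any(!usable)) {
    warning(sprintf("skipping TMM set(s) with insufficient overlap: %s",
                    paste(tmm_sets[!usable], collapse = ", ")))
  }
  tmm_sets <- tmm_sets[usable]
  assert_that(length(tmm_sets) > 0, "no usable TMM sets")

  R <- rank_matrix(expr, scoring$tie_break)
  qmat <- vapply(tmm_sets, function(nm) {
    p <- permutation_pvalues(expr, sets$sets[[nm]], params,
                             alpha = scoring$alpha, ranks = R)
    bh_fdr(p)
  }, numeric(nrow(expr)))
  dimnames(qmat) <- list(rownames(expr), tmm_sets)
  calls <- classify_cells(qmat, sets$group[tmm_sets], params)
  attr(calls, "qmat") <- qmat
  calls
}

#' TMM type frequencies by cell type
#'
#' @param calls Data frame from [tmm_classify()] / [classify_cells()].
#' @param cell_types Named character vector (names = cell ids) or character
#'   vector aligned with `calls$cell_id`.
#' @return Data frame with one row per (cell type, TMM label): `cell_type`,
#'   `label`, `n`, `pct`; percentages sum to 100 within each cell type.
#' @export
tmm_frequency <- function(calls, cell_types) {
  if (!is.null(names(cell_types))) {
    assert_that(all(calls$cell_id %in% names(cell_types)),
                "cell ids in calls not covered by cell_types")
    cell_types <- cell_types[calls$cell_id]
  } else {
    assert_that(length(cell_types) == nrow(calls),
                "cell_types length does not match calls")
  }
  out <- do.call(rbind, lapply(split(calls$label, cell_types), function(lab) {
    n <- vapply(TMM_LABELS, function(l) sum(lab == l), numeric(1))
    data.frame(label = TMM_LABELS, n = as.integer(n),
               pct = 100 * n / length(lab), stringsAsFactors = FALSE)
  }))
  out <- data.frame(cell_type = rep(names(split(calls$label, cell_types)),
                                    each = length(TMM_LABELS)),
                    out, row.names = NULL, stringsAsFactors = FALSE)
  out
}
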