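#' Scoring parameters for per-cell ssGSEA
#'
#' @param alpha Rank weight exponent (>= 0; 0.25 is the published ssGSEA
#'   default).
#' @param normalize Divide all raw enrichment scores by the global
#'   `max - min` of the score matrix (ssGSEA normalization).
#' @param min_set_overlap Minimum genes a set must share with the matrix
#'   universe to be scored (smaller sets are skipped with a warning).
#' @param tie_break How tied expression values are ordered when ranking a
#'   cell. `"cellwise"` (default) uses a deterministic pseudorandom order
#'   that differs from cell to cell, so the massive zero-count tie blocks of
#'   sparse data contribute per-cell noise rather than a fixed per-gene rank
#'   offset; `"lexicographic"` uses ascending gene-id order (identical in
#'   every cell, as in [rank_cell()]). Both are exactly reproducible.
#' @return A validated `scoring_params` list.
#' @export
scoring_params <- function(alpha = 0.25, normalize = TRUE,
                           min_set_overlap = 3L,
                           tie_break = c("cellwise", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  assert_that(alpha >= 0, "alpha must be >= 0")
  assert_that(min_set_overlap >= 1, "min_set_overlap must be >= 1")
  structure(list(alpha = alpha, normalize = isTRUE(normalize),
                 min_set_overlap = as.integer(min_set_overlap),
                 tie_break = tie_break),
            class = "scoring_params")
}

#' Rank a cell's expression vector
#'
#' Highest expression receives rank `N`; ties are broken deterministically by
#' ascending gene-id lexicographic order (the lexicographically smaller id of
#' a tied pair gets the lower rank). Ranks are invariant to any strictly
#' increasing transform of the expression values.
#'
#' @param x Numeric expression vector over `N >= 2` genes.
#' @param gene_ids Gene ids used for tie-breaking; defaults to `names(x)` or,
#'   failing that, positional order.
#' @return Integer ranks 1..N, named by `gene_ids`.
#' @export
rank_cell <- function(x, gene_ids = names(x)) {
  n <- length(x)
  assert_that(n >= 2, "need at least 2 genes")
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(n))
  ord <- order(x, gene_ids)              # increasing value, then id
  r <- integer(n)
  r[ord] <- seq_len(n)
  stats::setNames(r, gene_ids)
}

# Fixed base for the per-cell pseudorandom tie order; any constant works,
# it only has to be the same in every session.
TIE_SEED <- 982451653L

# Ranks for every cell of a matrix: cells x genes integer matrix, each row a
# permutation of 1..N. "lexicographic" applies the rank_cell tie rule
# identically in every cell; "cellwise" breaks ties by a pseudorandom order
# drawn deterministically from (TIE_SEED, cell position), so tied genes are
# ordered differently from cell to cell but identically across runs.
rank_matrix <- function(X, tie_break = c("cellwise", "lexicographic")) {
  tie_break <- match.arg(tie_break)
  X <- as_dense(X)
  n <- ncol(X)
  ids <- colnames(X) %||% sprintf("g%d", seq_len(n))
  R <- t(vapply(seq_len(nrow(X)), function(i) {
    tb <- if (tie_break == "cellwise") {
      withr::with_seed(TIE_SEED + i, sample.int(n))
    } else {
      ids
    }
    r <- integer(n)
    r[order(X[i, ], tb)] <- seq_len(n)
    r
  }, integer(n)))
  dimnames(R) <- dimnames(X)
  R
}

#' Single-sample GSEA enrichment score
#'
#' The Barbie-style statistic: walking the genes in decreasing rank order,
#' `ES = sum_i [P_in(i) - P_out(i)]` where `P_in` is the rank^alpha-weighted
#' cumulative fraction of set genes encountered and `P_out` the unweighted
#' cumulative fraction of non-set genes. Because the walk visits the gene of
#' rank r at position `N - r + 1`, the sum collapses to the exact closed form
#'
#'   `ES = sum_{g in G} r_g^(alpha+1) / sum_{g in G} r_g^alpha
#'         - (N(N+1)/2 - sum_{g in G} r_g) / (N - |G|)`
#'
#' which is what this function evaluates; it is positive when set genes
#' concentrate at high ranks.
#'
#' @param ranks Named integer vector from [rank_cell()] (a permutation of
#'   1..N).
#' @param gene_set Character vector of set member ids; the intersection with
#'   `names(ranks)` must be non-empty and a strict subset of the universe.
#' @param alpha Rank weight exponent.
#' @return The enrichment score (scalar).
#' @export
ssgsea_es <- function(ranks, gene_set, alpha = 0.25) {
  n <- length(ranks)
  idx <- which(names(ranks) %in% gene_set)
  m <- length(idx)
  assert_that(m >= 1, "gene set has no overlap with the ranked universe")
  assert_that(m < n, "gene set covers the whole universe; P_out is undefined")
  r <- as.numeric(ranks[idx])
  w <- r^alpha
  sum(w * r) / sum(w) - (n * (n + 1) / 2 - sum(r)) / (n - m)
}

# Vectorized ES for many cells x many index sets.
# R: cells x genes rank matrix; Z: genes x sets sparse 0/1 indicator;
# sizes: per-set overlap sizes. Returns cells x sets ES matrix.
es_matrix <- function(R, Z, sizes, alpha) {
  n_genes <- ncol(R)
  Ra <- R^alpha
  S0 <- as.matrix(Ra %*% Z)              # sum r^alpha over set
  S1 <- as.matrix((Ra * R) %*% Z)        # sum r^(alpha+1)
  SR <- as.matrix(R %*% Z)               # sum r
  tot <- n_genes * (n_genes + 1) / 2
  S1 / S0 - sweep(tot - SR, 2L, n_genes - sizes, `/`)
}

#' Score every cell against a gene set collection
#'
#' Applies [rank_cell()] and [ssgsea_es()] per (cell, set). Sets are first
#' intersected with the matrix gene universe; sets with fewer than
#' `min_set_overlap` surviving genes are skipped with a warning. When
#' `params$normalize` is `TRUE`, all raw scores are divided by the global
#' `max - min` of the raw score matrix.
#'
#' @param expr Cells x genes expression matrix (typically imputed); scores
#'   depend on within-cell ranks only.
#' @param sets A `GeneSetCollection`.
#' @param params A `scoring_params` object.
#' @return Cells x sets numeric matrix with attributes `normalized` (flag)
#'   and `effective_size` (per-set overlap with the universe).
#' @export
score_matrix <- function(expr, sets, params = scoring_params()) {
  stopifnot(inherits(sets, "GeneSetCollection"),
            inherits(params, "scoring_params"))
  assert_that(ncol(expr) >= 2, "expression matrix needs >= 2 genes")
  universe <- colnames(expr)
  idx_list <- lapply(sets$sets, function(g) which(universe %in% g))
  sizes <- lengths(idx_list)
  usable <- sizes >= params$min_set_overlap & sizes < ncol(expr)
  if (any(!usable)) {
    warning(sprintf("skipping %d set(s) with < %d genes in the universe: %s",
                    sum(!usable), params$min_set_overlap,
                    paste(names(idx_list)[!usable], collapse = ", ")))
  }
  if (!any(usable)) stop("no usable gene sets after universe intersection",
                         call. = FALSE)
  idx_list <- idx_list[usable]
  sizes <- sizes[usable]

  R <- rank_matrix(expr, params$tie_break)
  Z <- Matrix::sparseMatrix(
    i = unlist(idx_list),
    j = rep(seq_along(idx_list), lengths(idx_list)),
    x = 1, dims = c(ncol(expr), length(idx_list)))
  ES <- es_matrix(R, Z, sizes, params$alpha)
  dimnames(ES) <- list(rownames(expr), names(idx_list))
  normalized <- FALSE
  if (params$normalize) {
    rng <- max(ES) - min(ES)
    if (rng > 0) ES <- ES / rng
    normalized <- TRUE
  }
  attr(ES, "normalized") <- normalized
  attr(ES, "effective_size") <- sizes
  ES
}
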