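#' Per-cell quality-control metrics
#'
#' Computes, for each cell, the number of detected features (genes with
#' count > 0), the total count, and the mitochondrial percentage
#' `100 * mito counts / total counts` (0 when the total is 0, flagged in the
#' `zero_total` column).
#'
#' @param counts Cells x genes count matrix with dimnames.
#' @param mito_genes Character vector of mitochondrial gene ids; ids absent
#'   from the matrix raise a warning, an empty intersection yields an all-zero
#'   `pct_mito` column with a warning.
#' @return Data frame with columns `cell_id`, `n_features`, `total_counts`,
#'   `pct_mito`, `zero_total`.
#' @export
compute_qc <- function(counts, mito_genes = grep("^MT-", colnames(counts),
                                                 value = TRUE)) {
  validate_count_matrix(counts)
  missing <- setdiff(mito_genes, colnames(counts))
  if (length(missing)) {
    warning(sprintf("%d mito gene(s) not in the matrix: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")))
  }
  mito_genes <- intersect(mito_genes, colnames(counts))
  if (length(mito_genes) == 0) {
    warning("no mitochondrial genes found; pct_mito is 0 for all cells")
  }
  total <- Matrix::rowSums(counts)
  nfeat <- Matrix::rowSums(counts > 0)
  mito <- if (length(mito_genes)) {
    Matrix::rowSums(counts[, mito_genes, drop = FALSE])
  } else {
    rep(0, nrow(counts))
  }
  pct <- ifelse(total > 0, 100 * mito / total, 0)
  data.frame(cell_id = rownames(counts),
             n_features = as.integer(nfeat),
             total_counts = as.integer(total),
             pct_mito = pct,
             zero_total = total == 0,
             stringsAsFactors = FALSE)
}

#' QC thresholds for cell filtering
#'
#' Defaults keep cells with at least 200 detected features and below 5%
#' mitochondrial counts. `mito_rule = "keep_above"` inverts the
#' mitochondrial direction for completeness; keep-below is the conventional
#' reading (high-mito cells are damaged) and is the default.
#'
#' @param min_features Minimum detected features (>= 0).
#' @param mito_pct_threshold Mitochondrial percentage threshold in \[0, 100\].
#' @param mito_rule `"keep_below"` (default) or `"keep_above"`.
#' @return A validated `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_features = 200L, mito_pct_threshold = 5,
                          mito_rule = c("keep_below", "keep_above")) {
  mito_rule <- match.arg(mito_rule)
  assert_that(min_features >= 0, "min_features must be >= 0")
  assert_that(mito_pct_threshold >= 0 && mito_pct_threshold <= 100,
              "mito_pct_threshold must lie in [0, 100]")
  structure(list(min_features = as.integer(min_features),
                 mito_pct_threshold = mito_pct_threshold,
                 mito_rule = mito_rule),
            class = "qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' A cell is kept iff `n_features >= min_features` and its mitochondrial
#' percentage is strictly below (`keep_below`) or strictly above
#' (`keep_above`) the threshold. Input order is preserved; the operation is
#' idempotent.
#'
#' @param qc Data frame from [compute_qc()].
#' @param thresholds A `qc_thresholds` object.
#' @return Character vector of kept cell ids.
#' @export
filter_cells <- function(qc, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  mito_ok <- if (thresholds$mito_rule == "keep_below") {
    qc$pct_mito < thresholds$mito_pct_threshold
  } else {
    qc$pct_mito > thresholds$mito_pct_threshold
  }
  qc$cell_id[qc$n_features >= thresholds$min_features & mito_ok]
}

#' Library-size log-normalization
#'
#' Seurat-style: `x -> log(1 + scale * x / cell total)` with natural log.
#' Zeros map exactly to zero and sparsity is preserved; scaling a cell's
#' counts by any positive constant leaves its normalized vector unchanged.
#'
#' @param counts Cells x genes count matrix; no all-zero cells (filter first).
#' @param scale Size-factor target (default `1e4`).
#' @return Normalized matrix of the same class and dimnames.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  total <- Matrix::rowSums(counts)
  if (any(total == 0)) {
    stop("all-zero cell(s) present; run filter_cells() first", call. = FALSE)
  }
  if (inherits(counts, "CsparseMatrix")) {
    out <- counts
    out@x <- log1p(scale * counts@x / total[counts@i + 1L])
    out
  } else {
    log1p(scale * as_dense(counts) / total)
  }
}
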