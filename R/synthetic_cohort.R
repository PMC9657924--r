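#' Configuration for a synthetic single-cell cohort
#'
#' Bundles and validates the parameters of the negative-binomial +
#' logistic-dropout generative model used by [simulate_cohort()]. Defaults
#' emulate a droplet-based (10x-style) tumor cohort at desk scale: a few
#' thousand moderately expressed genes, strong gene-to-gene mean variation,
#' moderate overdispersion, and dropout concentrated on weakly expressed
#' genes.
#'
#' @param n_cells,n_genes Cohort dimensions (genes include the mito block).
#' @param cell_type_props Named simplex vector of cell-type proportions.
#' @param tmm_props Named simplex vector over the four TMM types
#'   `TEL`, `ALT-like`, `TEL+ALT-like`, `NDTMM`.
#' @param baseline_log_mean,gene_mean_sd Per-gene log-means are drawn from
#'   Normal(`baseline_log_mean`, `gene_mean_sd`^2) (natural log of the
#'   expected count).
#' @param nb_dispersion NB size parameter (> 0); smaller is more overdispersed.
#' @param dropout_midpoint,dropout_slope Each entry is zeroed with probability
#'   `plogis(dropout_slope * (dropout_midpoint - log(mean)))`;
#'   `dropout_midpoint = -Inf` disables dropout entirely.
#' @param signature_lfc log2 fold-change planted on the genes of every TMM
#'   signature set active in a cell (>= 0).
#' @param cell_type_lfc log2 fold-change on each cell type's marker gene block.
#' @param n_marker_genes Marker block size per cell type.
#' @param n_mito_genes Number of mitochondrial genes (ids prefixed `MT-`).
#' @param mito_fraction_range Per-cell mitochondrial count share is drawn
#'   uniformly from this interval (subset of \[0, 1)).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_cells = 1000L,
                       n_genes = 2000L,
                       cell_type_props = c(epithelial = 0.4, immune = 0.35,
                                           stromal = 0.25),
                       tmm_props = c("TEL" = 0.25, "ALT-like" = 0.25,
                                     "TEL+ALT-like" = 0.25, "NDTMM" = 0.25),
                       baseline_log_mean = 0,
                       gene_mean_sd = 1,
                       nb_dispersion = 1,
                       dropout_midpoint = log(0.5),
                       dropout_slope = 1,
                       signature_lfc = 1.5,
                       cell_type_lfc = 1,
                       n_marker_genes = 50L,
                       n_mito_genes = 10L,
                       mito_fraction_range = c(0.01, 0.04),
                       seed = 1L) {
  assert_that(n_cells >= 1 && n_genes >= 1, "n_cells and n_genes must be >= 1")
  check_simplex <- function(p, what) {
    assert_that(!is.null(names(p)) && all(p >= 0) &&
                  abs(sum(p) - 1) < 1e-9,
                sprintf("%s must be a named vector of proportions summing to 1",
                        what))
  }
  check_simplex(cell_type_props, "cell_type_props")
  check_simplex(tmm_props, "tmm_props")
  assert_that(setequal(names(tmm_props), TMM_LABELS),
              "tmm_props must be named over TEL, ALT-like, TEL+ALT-like, NDTMM")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(signature_lfc >= 0, "signature_lfc must be >= 0")
  assert_that(length(mito_fraction_range) == 2 &&
                mito_fraction_range[1] >= 0 && mito_fraction_range[2] < 1 &&
                mito_fraction_range[1] <= mito_fraction_range[2],
              "mito_fraction_range must be [lo, hi] within [0, 1)")
  assert_that(n_mito_genes + length(cell_type_props) * n_marker_genes < n_genes,
              "n_genes too small for the mito and marker blocks")
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    cell_type_props = cell_type_props,
    tmm_props = tmm_props[TMM_LABELS],
    baseline_log_mean = baseline_log_mean, gene_mean_sd = gene_mean_sd,
    nb_dispersion = nb_dispersion,
    dropout_midpoint = dropout_midpoint, dropout_slope = dropout_slope,
    signature_lfc = signature_lfc, cell_type_lfc = cell_type_lfc,
    n_marker_genes = as.integer(n_marker_genes),
    n_mito_genes = as.integer(n_mito_genes),
    mito_fraction_range = mito_fraction_range,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' The four TMM labels, in canonical order
#' @export
TMM_LABELS <- c("TEL", "ALT-like", "TEL+ALT-like", "NDTMM")

#' Gene universe of a synthetic cohort
#'
#' Deterministic gene ids for a given config: first the mitochondrial block
#' (`MT-01`, ...), then numbered genes. Marker blocks for the cell types
#' occupy the first genes after the mito block; [demo_tmm_sets()] draws its
#' signature genes from the tail so the two never overlap.
#'
#' @param config A `sim_config`.
#' @return Character vector of length `config$n_genes`.
#' @export
sim_gene_ids <- function(config) {
  c(sprintf("MT-%02d", seq_len(config$n_mito_genes)),
    sprintf("G%05d", seq_len(config$n_genes - config$n_mito_genes)))
}

# Deterministic layout of the functional gene blocks. Cell-type marker genes
# are strided evenly across the non-mito id range (not laid down as one
# contiguous block): within the big zero-count tie blocks of sparse data the
# deterministic id-order tie-break gives each gene a fixed position, so any
# functional block clustered in id space would be systematically rank-shifted
# against uniformly resampled gene sets.
sim_layout <- function(config) {
  p <- config$n_genes
  mito_idx <- seq_len(config$n_mito_genes)
  free <- setdiff(seq_len(p), mito_idx)
  n_types <- length(config$cell_type_props)
  n_mark <- n_types * config$n_marker_genes
  mark_pos <- free[round(seq(1L, length(free), length.out = n_mark))]
  marker_idx <- split(mark_pos, rep_len(seq_len(n_types), n_mark))
  names(marker_idx) <- names(config$cell_type_props)
  list(mito_idx = mito_idx, marker_idx = marker_idx,
       free_idx = setdiff(free, mark_pos))
}

#' Demo TMM signature sets over a synthetic gene universe
#'
#' Builds disjoint TEL-group and ALT-group signature sets (three each by
#' default, mirroring a six-pathway TMM signature) from the tail of the
#' simulated gene universe, away from mito and cell-type marker blocks. These
#' are placeholders standing in for a real TMM signature; any user-supplied
#' GMT with TEL/ALT group tags can be used instead.
#'
#' @param config A `sim_config`.
#' @param n_tel,n_alt Number of TEL-group and ALT-group sets.
#' @param genes_per_set Genes per set.
#' @return A `GeneSetCollection` with TEL/ALT group tags.
#' @export
demo_tmm_sets <- function(config, n_tel = 3L, n_alt = 3L,
                          genes_per_set = 30L) {
  ids <- sim_gene_ids(config)
  need <- (n_tel + n_alt) * genes_per_set
  reserved <- config$n_mito_genes +
    length(config$cell_type_props) * config$n_marker_genes
  assert_that(config$n_genes - reserved >= need,
              "gene universe too small for the requested signature sets")
  # Spread signature genes evenly across the free id range and deal them to
  # sets round-robin, for the same tie-block reason sim_layout() strides the
  # marker genes: an id-clustered set would be rank-biased against
  # uniformly drawn null sets wherever counts tie.
  free <- sim_layout(config)$free_idx
  pos <- free[round(seq(1L, length(free), length.out = need))]
  pool <- ids[pos]
  sets <- split(pool, rep_len(seq_len(n_tel + n_alt), need))
  names(sets) <- c(sprintf("TEL_pathway_%d", seq_len(n_tel)),
                   sprintf("ALT_pathway_%d", seq_len(n_alt)))
  groups <- stats::setNames(rep(c("TEL", "ALT"), c(n_tel, n_alt)), names(sets))
  gene_set_collection(sets, groups)
}

#' Simulate a single-cell cohort with planted TMM signature activity
#'
#' Generative model: per gene g, a log-mean is drawn from
#' Normal(`baseline_log_mean`, `gene_mean_sd`^2). Each cell gets a cell type
#' (marker block up-regulated by `2^cell_type_lfc`) and a TMM type; TEL cells
#' activate all TEL-group sets, ALT-like cells all ALT-group sets,
#' TEL+ALT-like both, NDTMM none. Active-set genes have their mean multiplied
#' by `2^signature_lfc`. Counts are NB(mean, size = `nb_dispersion`), then
#' each entry is zeroed with probability
#' `plogis(dropout_slope * (dropout_midpoint - log(mean)))`. Finally the mito
#' gene block is filled so each cell's mitochondrial share of total counts is
#' approximately a Uniform(`mito_fraction_range`) draw.
#'
#' @param config A `sim_config`.
#' @param sets A `GeneSetCollection` whose TEL/ALT-tagged sets are the TMM
#'   signature; all signature genes must exist in the simulated universe.
#' @return List with `counts` (sparse cells x genes `dgCMatrix`), `truth`
#'   (data frame: `cell_id`, `cell_type`, `tmm_type`, `planted_active_sets`
#'   as a `;`-separated string, empty iff NDTMM) and `gene_means` (the drawn
#'   baseline per-gene means, before any planted fold-change).
#' @export
simulate_cohort <- function(config, sets) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sim_gene_ids(config)
  tmm_set_names <- names(sets$sets)[sets$group %in% c("TEL", "ALT")]
  sig_genes <- unique(unlist(sets$sets[tmm_set_names]))
  missing <- setdiff(sig_genes, gene_ids)
  assert_that(length(missing) == 0,
              sprintf("signature genes absent from the simulated universe: %s",
                      paste(utils::head(missing, 5), collapse = ", ")))

  withr::with_seed(config$seed, {
    n <- config$n_cells
    p <- config$n_genes
    cell_ids <- sprintf("cell%05d", seq_len(n))
    cell_type <- sample(names(config$cell_type_props), n, replace = TRUE,
                        prob = config$cell_type_props)
    tmm_type <- sample(names(config$tmm_props), n, replace = TRUE,
                       prob = config$tmm_props)

    base_mean <- exp(stats::rnorm(p, config$baseline_log_mean,
                                  config$gene_mean_sd))
    names(base_mean) <- gene_ids

    # cells x genes expected-count matrix
    mu <- matrix(base_mean, nrow = n, ncol = p, byrow = TRUE,
                 dimnames = list(cell_ids, gene_ids))

    # cell-type marker blocks, strided across the id range (see sim_layout)
    layout <- sim_layout(config)
    for (ti in names(layout$marker_idx)) {
      block <- layout$marker_idx[[ti]]
      rows <- cell_type == ti
      mu[rows, block] <- mu[rows, block] * 2^config$cell_type_lfc
    }

    # planted TMM signature activity
    tel_genes <- unique(unlist(sets$sets[sets$group == "TEL"]))
    alt_genes <- unique(unlist(sets$sets[sets$group == "ALT"]))
    tel_active <- tmm_type %in% c("TEL", "TEL+ALT-like")
    alt_active <- tmm_type %in% c("ALT-like", "TEL+ALT-like")
    bump <- 2^config$signature_lfc
    if (length(tel_genes)) {
      mu[tel_active, match(tel_genes, gene_ids)] <-
        mu[tel_active, match(tel_genes, gene_ids)] * bump
    }
    if (length(alt_genes)) {
      mu[alt_active, match(alt_genes, gene_ids)] <-
        mu[alt_active, match(alt_genes, gene_ids)] * bump
    }

    counts <- matrix(stats::rnbinom(n * p, mu = mu,
                                    size = config$nb_dispersion),
                     nrow = n, dimnames = dimnames(mu))

    if (is.finite(config$dropout_midpoint)) {
      p_drop <- stats::plogis(config$dropout_slope *
                                (config$dropout_midpoint - log(mu)))
      counts[stats::runif(n * p) < p_drop] <- 0L
    }

    # mito block: per-cell share drawn uniformly from mito_fraction_range
    if (config$n_mito_genes > 0) {
      mito_idx <- seq_len(config$n_mito_genes)
      frac <- stats::runif(n, config$mito_fraction_range[1],
                           config$mito_fraction_range[2])
      nonmito_tot <- rowSums(counts[, -mito_idx, drop = FALSE])
      target <- round(frac / (1 - frac) * nonmito_tot)
      mito_prob <- base_mean[mito_idx]
      for (i in seq_len(n)) {
        counts[i, mito_idx] <- stats::rmultinom(1, target[i], mito_prob)[, 1]
      }
    }

    active <- character(n)
    tel_sets <- names(sets$sets)[sets$group == "TEL"]
    alt_sets <- names(sets$sets)[sets$group == "ALT"]
    active[tel_active & !alt_active] <- paste(tel_sets, collapse = ";")
    active[alt_active & !tel_active] <- paste(alt_sets, collapse = ";")
    active[tel_active & alt_active] <- paste(c(tel_sets, alt_sets),
                                             collapse = ";")

    truth <- data.frame(cell_id = cell_ids, cell_type = cell_type,
                        tmm_type = tmm_type, planted_active_sets = active,
                        stringsAsFactors = FALSE)
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE),
                          "CsparseMatrix")
    validate_count_matrix(counts)
    list(counts = counts, truth = truth, gene_means = base_mean)
  })
}

#' Simulate a null cohort (no TMM signal anywhere)
#'
#' Equivalent to [simulate_cohort()] with `signature_lfc` forced to 0 and all
#' cells labeled NDTMM; used to calibrate the permutation/FDR machinery.
#'
#' @param config A `sim_config`.
#' @param sets Optional `GeneSetCollection` (only used to validate gene ids;
#'   no set is ever activated).
#' @return As [simulate_cohort()]; `truth$tmm_type` is all `"NDTMM"`.
#' @export
simulate_null_cohort <- function(config, sets = NULL) {
  null_cfg <- config
  null_cfg$signature_lfc <- 0
  null_cfg$tmm_props <- stats::setNames(c(0, 0, 0, 1), TMM_LABELS)
  if (is.null(sets)) {
    sets <- gene_set_collection(stats::setNames(list("none"), "placeholder"))
    sets$sets <- list()
    sets$group <- character(0)
  }
  simulate_cohort(null_cfg, sets)
}
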