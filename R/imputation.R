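#' Parameters for Markov diffusion imputation
#'
#' Defaults follow the published MAGIC recommendations: `k = 15` neighbors,
#' adaptive kernel width set by the `ka = 5`-th neighbor, `t = 3` diffusion
#' steps, distances computed in the top `n_pcs = 20` principal components.
#'
#' @param k Number of nearest neighbors kept in the kernel (`ka <= k < n_cells`).
#' @param ka Neighbor index that sets the adaptive Gaussian bandwidth.
#' @param t Number of diffusion steps (>= 0; 0 leaves the matrix untouched).
#' @param n_pcs Number of principal components for the distance space.
#' @return A validated `diffusion_params` list.
#' @export
diffusion_params <- function(k = 15L, ka = 5L, t = 3L, n_pcs = 20L) {
  assert_that(ka >= 1 && ka <= k, "need 1 <= ka <= k")
  assert_that(t >= 0, "t must be >= 0")
  assert_that(n_pcs >= 1, "n_pcs must be >= 1")
  structure(list(k = as.integer(k), ka = as.integer(ka), t = as.integer(t),
                 n_pcs = as.integer(n_pcs)),
            class = "diffusion_params")
}

#' Build the cell-cell Markov diffusion operator
#'
#' Distances are Euclidean in the top `n_pcs` principal components of the
#' normalized matrix. The affinity is an adaptive Gaussian kernel,
#' `A_ij = exp(-(d_ij / sigma_i)^2)` with `sigma_i` the distance to cell i's
#' `ka`-th neighbor, truncated beyond the `k`-th neighbor (the cell itself is
#' always retained with affinity 1). The kernel is symmetrized by the
#' arithmetic mean and row-normalized into a row-stochastic Markov matrix.
#'
#' @param norm_matrix Cells x genes normalized expression matrix.
#' @param params A `diffusion_params` object; requires `k + 1 <= n_cells`.
#' @return Dense cells x cells row-stochastic matrix with positive diagonal.
#' @export
build_markov <- function(norm_matrix, params = diffusion_params()) {
  stopifnot(inherits(params, "diffusion_params"))
  X <- as_dense(norm_matrix)
  n <- nrow(X)
  assert_that(params$k < n, "k must be smaller than the number of cells")
  npc <- min(params$n_pcs, n - 1L, ncol(X))
  pcs <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = npc)$x
  D <- as.matrix(stats::dist(pcs))

  A <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
  warned <- FALSE
  for (i in seq_len(n)) {
    d <- D[i, ]
    ord <- order(d)                      # self first (d = 0)
    nb <- ord[ord != i][seq_len(params$k)]
    sigma <- D[i, nb[params$ka]]
    if (sigma == 0) {
      pos <- d[nb][d[nb] > 0]
      sigma <- if (length(pos)) min(pos) else 1
      if (!warned) {
        warning("duplicate cells: zero adaptive bandwidth replaced by the ",
                "smallest positive neighbor distance")
        warned <- TRUE
      }
    }
    keep <- c(i, nb)
    A[i, keep] <- exp(-(d[keep] / sigma)^2)
  }
  A <- (A + t(A)) / 2
  A / rowSums(A)
}

#' Diffuse an expression matrix through a Markov operator
#'
#' Returns `M^t %*% X` by repeated left-multiplication (no explicit matrix
#' power); `t = 0` returns `X` unchanged. Each diffusion step is an average
#' over graph neighbors, so per gene the imputed values stay within the
#' original value range.
#'
#' @param norm_matrix Cells x genes matrix.
#' @param markov Row-stochastic cells x cells matrix from [build_markov()].
#' @param t Number of steps (integer >= 0).
#' @return Dense imputed matrix with the input dimnames.
#' @export
diffuse <- function(norm_matrix, markov, t) {
  assert_that(t >= 0, "t must be >= 0")
  X <- as_dense(norm_matrix)
  rs <- rowSums(markov)
  assert_that(max(abs(rs - 1)) < 1e-8, "markov matrix is not row-stochastic")
  for (i in seq_len(t)) X <- markov %*% X
  dimnames(X) <- dimnames(norm_matrix)
  X
}

#' MAGIC-style imputation: build the operator and diffuse
#'
#' @inheritParams build_markov
#' @return Dense imputed cells x genes matrix.
#' @export
magic_impute <- function(norm_matrix, params = diffusion_params()) {
  M <- build_markov(norm_matrix, params)
  diffuse(norm_matrix, M, params$t)
}
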