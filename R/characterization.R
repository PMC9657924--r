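#' Per-cell transcriptome entropy
#'
#' Shannon entropy of the cell's normalized expression distribution
#' (`p_g = x_g / sum(x)`, `H = -sum p log p`, natural log, `0 log 0 = 0`);
#' the StemID-style stemness proxy. Bounds: `0 <= H <= log(N)` with equality
#' exactly at one-hot and uniform cells.
#'
#' @param expr Cells x genes non-negative matrix; every cell must have a
#'   positive total.
#' @return Named numeric vector of entropies (nats).
#' @export
cell_entropy <- function(expr) {
  X <- as_dense(expr)
  assert_that(all(X >= 0), "expression must be non-negative")
  tot <- rowSums(X)
  if (any(tot == 0)) stop("all-zero cell(s); filter before computing entropy",
                          call. = FALSE)
  P <- X / tot
  H <- -rowSums(ifelse(P > 0, P * log(P), 0))
  stats::setNames(H, rownames(X))
}

#' Cluster parameters
#'
#' @param n_clusters Number of k-means clusters (`2 <= n_clusters < n_cells`).
#' @param n_pcs Principal components used as the clustering space.
#' @param seed Seed for the k-means initialization.
#' @return A validated `cluster_params` list.
#' @export
cluster_params <- function(n_clusters = 10L, n_pcs = 20L, seed = 1L) {
  assert_that(n_clusters >= 2, "n_clusters must be >= 2")
  assert_that(n_pcs >= 1, "n_pcs must be >= 1")
  structure(list(n_clusters = as.integer(n_clusters),
                 n_pcs = as.integer(n_pcs), seed = as.integer(seed)),
            class = "cluster_params")
}

#' Cluster cells by k-means on principal components
#'
#' Deterministic given the seed; labels are 1..n_clusters.
#'
#' @param expr Cells x genes matrix (typically imputed).
#' @param params A `cluster_params` object.
#' @return Named integer vector of cluster labels.
#' @export
cluster_cells <- function(expr, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  X <- as_dense(expr)
  assert_that(params$n_clusters < nrow(X),
              "n_clusters must be smaller than the number of cells")
  npc <- min(params$n_pcs, nrow(X) - 1L, ncol(X))
  pcs <- stats::prcomp(X, center = TRUE, rank. = npc)$x
  km <- withr::with_seed(params$seed, {
    stats::kmeans(pcs, centers = params$n_clusters, nstart = 10L,
                  iter.max = 100L)
  })
  stats::setNames(as.integer(km$cluster), rownames(X))
}

#' Entropy and TMM composition by cluster
#'
#' Per cluster: mean and median entropy, a Wilcoxon rank-sum test of the
#' cluster's entropies against all other cells (BH-corrected across
#' clusters), and, when calls are supplied, the percentage of each TMM label
#' (summing to 100 within the cluster).
#'
#' @param entropy Named vector from [cell_entropy()].
#' @param labels Named cluster labels from [cluster_cells()].
#' @param calls Optional TMM call data frame ([tmm_classify()]).
#' @return Data frame with one row per cluster.
#' @export
entropy_by_cluster <- function(entropy, labels, calls = NULL) {
  assert_that(setequal(names(entropy), names(labels)),
              "entropy and cluster labels cover different cells")
  labels <- labels[names(entropy)]
  if (!is.null(calls)) {
    assert_that(setequal(calls$cell_id, names(entropy)),
                "TMM calls cover different cells")
    tmm <- stats::setNames(calls$label, calls$cell_id)[names(entropy)]
  }
  cl <- sort(unique(labels))
  rows <- lapply(cl, function(k) {
    inside <- labels == k
    p <- if (sum(inside) >= 1 && sum(!inside) >= 1) {
      stats::wilcox.test(entropy[inside], entropy[!inside], exact = FALSE)$p.value
    } else NA_real_
    row <- data.frame(cluster = k, n = sum(inside),
                      mean_entropy = mean(entropy[inside]),
                      median_entropy = stats::median(entropy[inside]),
                      p_vs_rest = p, stringsAsFactors = FALSE)
    if (!is.null(calls)) {
      for (l in TMM_LABELS) {
        row[[paste0("pct_", gsub("[+]", "_", l))]] <-
          100 * sum(tmm[inside] == l) / sum(inside)
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  out$q_vs_rest <- bh_fdr(out$p_vs_rest)
  out
}

#' Marker expression summaries by TMM type
#'
#' Per (TMM label, marker): mean and median expression plus a Wilcoxon
#' rank-sum p-value of that label's cells against all other cells,
#' BH-corrected across all (label, marker) tests. Groups with fewer than 3
#' cells get `NA` p-values.
#'
#' @param expr Cells x genes matrix (typically imputed).
#' @param markers Character vector of marker gene ids (e.g. `MKI67`, `PML`);
#'   markers missing from the matrix are dropped with a warning.
#' @param calls TMM call data frame covering the matrix cells.
#' @return Data frame with one row per (label, marker).
#' @export
marker_summary <- function(expr, markers, calls) {
  X <- as_dense(expr)
  missing <- setdiff(markers, colnames(X))
  if (length(missing)) {
    warning(sprintf("marker(s) not in matrix: %s",
                    paste(missing, collapse = ", ")))
  }
  markers <- intersect(markers, colnames(X))
  assert_that(length(markers) > 0, "none of the markers are in the matrix")
  assert_that(all(rownames(X) %in% calls$cell_id),
              "calls do not cover all cells")
  lab <- stats::setNames(calls$label, calls$cell_id)[rownames(X)]
  grid <- expand.grid(label = intersect(TMM_LABELS, unique(lab)),
                      marker = markers, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    l <- grid$label[i]; g <- grid$marker[i]
    inside <- lab == l
    x <- X[inside, g]; y <- X[!inside, g]
    p <- if (sum(inside) >= 3 && sum(!inside) >= 3) {
      if (stats::sd(c(x, y)) == 0) 1 else {
        stats::wilcox.test(x, y, exact = FALSE)$p.value
      }
    } else NA_real_
    data.frame(label = l, marker = g, n = sum(inside), mean = mean(x),
               median = stats::median(x), p_vs_rest = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_vs_rest <- bh_fdr(ifelse(is.na(out$p_vs_rest), 1, out$p_vs_rest))
  out$q_vs_rest[is.na(out$p_vs_rest)] <- NA_real_
  out
}

# ---- Zero-inflated negative binomial ----------------------------------------

# ZINB log-likelihood on counts x for (pi, mu, theta).
zinb_loglik <- function(x, pi, mu, theta) {
  p0 <- stats::dnbinom(0, mu = mu, size = theta)
  ll0 <- log(pi + (1 - pi) * p0)
  llpos <- log1p(-pi) + stats::dnbinom(x, mu = mu, size = theta, log = TRUE)
  sum(ifelse(x == 0, ll0, llpos))
}

# Deterministic initialization: mu0 = positive-part mean, theta0 =
# method-of-moments on all data, pi0 = excess-zero fraction beyond NB(0).
zinb_init <- function(x) {
  pos <- x[x > 0]
  mu0 <- if (length(pos)) mean(pos) else 1
  m <- mean(x); v <- stats::var(x)
  theta0 <- if (is.finite(v) && v > m && m > 0) m^2 / (v - m) else 10
  theta0 <- min(max(theta0, 1e-3), 1e3)
  p0 <- stats::dnbinom(0, mu = mu0, size = theta0)
  zf <- mean(x == 0)
  pi0 <- max(0, (zf - p0) / (1 - p0))
  pi0 <- min(max(pi0, 1e-4), 1 - 1e-4)
  c(pi = pi0, mu = mu0, theta = theta0)
}

PI_MAX <- 1 - 1e-6

#' Fit a zero-inflated negative binomial to a count vector
#'
#' Model: `P(x = 0) = pi + (1 - pi) NB(0; mu, theta)`,
#' `P(x = k > 0) = (1 - pi) NB(k; mu, theta)`. Maximum likelihood by
#' quasi-Newton optimization on (logit pi, log mu, log theta) from a
#' deterministic moment-based start, with `pi` bounded in `[0, 1 - 1e-6]`.
#' The fitted log-likelihood never falls below the log-likelihood at the
#' start.
#'
#' @param x Non-negative integer vector, length >= 10.
#' @return List with `pi`, `mu`, `theta`, `loglik`, `boundary` (TRUE for the
#'   degenerate all-zero fit, where `mu` and `theta` are `NA`).
#' @export
zinb_fit <- function(x) {
  assert_that(length(x) >= 10, "need at least 10 observations")
  assert_that(all(x >= 0) && all(x == floor(x)),
              "counts must be non-negative integers")
  if (all(x == 0)) {
    return(list(pi = 1, mu = NA_real_, theta = NA_real_, loglik = 0,
                boundary = TRUE))
  }
  init <- zinb_init(x)
  par0 <- c(stats::qlogis(init["pi"] / PI_MAX), log(init["mu"]),
            log(init["theta"]))
  nll <- function(par) {
    pi <- PI_MAX * stats::plogis(par[1])
    mu <- exp(min(max(par[2], -20), 20))
    theta <- exp(min(max(par[3], -10), 10))
    -zinb_loglik(x, pi, mu, theta)
  }
  fit <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 500))
  pi <- PI_MAX * stats::plogis(fit$par[1])
  list(pi = unname(pi), mu = unname(exp(fit$par[2])),
       theta = unname(exp(fit$par[3])), loglik = -fit$value,
       boundary = FALSE)
}

# Two-group ZINB fits with a shared theta. Parameterizations:
#   full:       (piA, piB, muA, muB, theta)  5 params
#   pooled:     (pi, mu, theta)              3 params -> overall LRT df = 2
#   pi shared:  (pi, muA, muB, theta)        4 params -> zero-part LRT df = 1
#   mu shared:  (piA, piB, mu, theta)        4 params -> abundance LRT df = 1
zinb_two_group_fits <- function(xA, xB, share_theta = TRUE) {
  tr_pi <- function(u) PI_MAX * stats::plogis(u)
  tr_pos <- function(u) exp(min(max(u, -20), 20))
  iA <- zinb_init(xA); iB <- zinb_init(xB); iP <- zinb_init(c(xA, xB))
  lp <- function(p) stats::qlogis(p / PI_MAX)

  nll_full <- function(par) {
    -zinb_loglik(xA, tr_pi(par[1]), tr_pos(par[3]), tr_pos(par[5])) -
      zinb_loglik(xB, tr_pi(par[2]), tr_pos(par[4]),
                  if (share_theta) tr_pos(par[5]) else tr_pos(par[6]))
  }
  nll_pooled <- function(par) {
    -zinb_loglik(c(xA, xB), tr_pi(par[1]), tr_pos(par[2]), tr_pos(par[3]))
  }
  nll_pi_shared <- function(par) {
    -zinb_loglik(xA, tr_pi(par[1]), tr_pos(par[2]), tr_pos(par[4])) -
      zinb_loglik(xB, tr_pi(par[1]), tr_pos(par[3]), tr_pos(par[4]))
  }
  nll_mu_shared <- function(par) {
    -zinb_loglik(xA, tr_pi(par[1]), tr_pos(par[3]), tr_pos(par[4])) -
      zinb_loglik(xB, tr_pi(par[2]), tr_pos(par[3]), tr_pos(par[4]))
  }
  opt <- function(f, par0) stats::optim(par0, f, method = "BFGS",
                                        control = list(maxit = 500))
  th0 <- log(iP["theta"])
  full0 <- c(lp(iA["pi"]), lp(iB["pi"]), log(iA["mu"]), log(iB["mu"]), th0)
  if (!share_theta) full0 <- c(full0, th0)
  full <- opt(nll_full, full0)
  pooled <- opt(nll_pooled, c(lp(iP["pi"]), log(iP["mu"]), th0))
  pish <- opt(nll_pi_shared, c(lp(iP["pi"]), log(iA["mu"]), log(iB["mu"]), th0))
  mush <- opt(nll_mu_shared, c(lp(iA["pi"]), lp(iB["pi"]), log(iP["mu"]), th0))

  list(
    pi_A = PI_MAX * stats::plogis(full$par[1]),
    pi_B = PI_MAX * stats::plogis(full$par[2]),
    mu_A = exp(full$par[3]), mu_B = exp(full$par[4]),
    theta = exp(full$par[5]),
    ll_full = -full$value, ll_pooled = -pooled$value,
    ll_pi_shared = -pish$value, ll_mu_shared = -mush$value
  )
}

#' Two-group zero-inflated negative binomial differential expression
#'
#' DESingle-style two-part test per gene. A ZINB with shared NB size `theta`
#' across groups is fitted jointly to both groups (full model), against
#' three nested alternatives: fully pooled (overall likelihood-ratio test,
#' 2 df), shared zero-inflation weight (`p_zero`, 1 df) and shared NB mean
#' (`p_abund`, 1 df). All three p-value columns are BH-corrected across
#' genes; genes significant overall are classified `DEs` (zero-part
#' component significant only), `DEa` (abundance only) or `DEg` (both, or
#' neither component individually resolvable).
#'
#' @param counts Cells x genes raw count matrix.
#' @param cells_A,cells_B Disjoint character vectors of cell ids, each of
#'   length >= 10.
#' @param q_threshold BH q-value threshold on the overall test (default 0.05).
#' @param share_theta Share the NB size across groups (default `TRUE`).
#' @return Data frame, one row per tested gene: ZINB parameters per group,
#'   the three p-values, `q_overall` and `de_class` in
#'   `{DEs, DEa, DEg, none}` (`none` iff `q_overall >= q_threshold`). Genes
#'   all-zero in both groups are skipped.
#' @export
de_two_group <- function(counts, cells_A, cells_B, q_threshold = 0.05,
                         share_theta = TRUE) {
  validate_count_matrix(counts)
  assert_that(length(cells_A) >= 10 && length(cells_B) >= 10,
              "both groups need at least 10 cells")
  assert_that(length(intersect(cells_A, cells_B)) == 0,
              "groups must be disjoint")
  assert_that(all(c(cells_A, cells_B) %in% rownames(counts)),
              "unknown cell ids")
  A <- as_dense(counts[cells_A, , drop = FALSE])
  B <- as_dense(counts[cells_B, , drop = FALSE])
  keep <- colSums(A) + colSums(B) > 0
  genes <- colnames(counts)[keep]

  rows <- lapply(genes, function(g) {
    f <- zinb_two_group_fits(A[, g], B[, g], share_theta)
    lrt <- function(ll0, df) {
      stat <- max(0, 2 * (f$ll_full - ll0))
      stats::pchisq(stat, df = df, lower.tail = FALSE)
    }
    data.frame(gene = g, pi_A = f$pi_A, pi_B = f$pi_B,
               mu_A = f$mu_A, mu_B = f$mu_B, theta = f$theta,
               p_overall = lrt(f$ll_pooled, 2),
               p_zero = lrt(f$ll_pi_shared, 1),
               p_abund = lrt(f$ll_mu_shared, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_overall <- bh_fdr(out$p_overall)
  out$q_zero <- bh_fdr(out$p_zero)
  out$q_abund <- bh_fdr(out$p_abund)
  sig <- out$q_overall < q_threshold
  zero_sig <- out$q_zero < 0.05
  ab_sig <- out$q_abund < 0.05
  cls <- rep("none", nrow(out))
  cls[sig & zero_sig & !ab_sig] <- "DEs"
  cls[sig & !zero_sig & ab_sig] <- "DEa"
  cls[sig & zero_sig & ab_sig] <- "DEg"
  cls[sig & !zero_sig & !ab_sig] <- "DEg"
  out$de_class <- cls
  out
}
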