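#' Read a MatrixMarket count matrix with gene/cell id sidecars
#'
#' Reads a 10x-style triplet of files: a MatrixMarket coordinate file of
#' non-negative integer counts plus two TSV sidecars giving the gene and cell
#' identifiers in matrix order (first column of each sidecar is the id).
#' Gzipped inputs (`.gz`) are handled transparently.
#'
#' @param matrix_path Path to the `.mtx` (or `.mtx.gz`) file.
#' @param genes_path Path to the gene id sidecar (one gene per line, id in the
#'   first tab-separated column).
#' @param cells_path Path to the cell id sidecar.
#' @param orientation On-disk orientation of the matrix. The 10x convention
#'   (`"genes_by_cells"`, the default) stores genes as rows; the returned
#'   matrix is always cells x genes.
#'
#' @return A sparse `dgCMatrix` of counts, cells as rows and genes as columns,
#'   with ids as dimnames.
#' @export
read_mtx <- function(matrix_path, genes_path, cells_path,
                     orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  m <- Matrix::readMM(open_input(matrix_path))
  genes <- read_id_column(genes_path)
  cells <- read_id_column(cells_path)
  if (orientation == "genes_by_cells") {
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      stop(sprintf(
        "MTX header is %d x %d but sidecars give %d genes and %d cells",
        nrow(m), ncol(m), length(genes), length(cells)), call. = FALSE)
    }
    m <- Matrix::t(m)
  } else {
    if (nrow(m) != length(cells) || ncol(m) != length(genes)) {
      stop(sprintf(
        "MTX header is %d x %d but sidecars give %d cells and %d genes",
        nrow(m), ncol(m), length(cells), length(genes)), call. = FALSE)
    }
  }
  if (any(m@x < 0)) stop("MTX file contains negative entries", call. = FALSE)
  if (any(m@x != floor(m@x))) {
    stop("MTX file contains non-integer entries", call. = FALSE)
  }
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(cells, genes)
  validate_count_matrix(m)
  m
}

read_id_column <- function(path) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  assert_that(!anyDuplicated(ids), sprintf("duplicate ids in %s", path))
  ids
}

#' Write a count matrix as MatrixMarket plus id sidecars
#'
#' Inverse of [read_mtx()]; writes the matrix in the 10x genes x cells
#' orientation by default.
#'
#' @param counts Cells x genes matrix with dimnames.
#' @param dir Output directory (created if missing).
#' @param orientation On-disk orientation, as in [read_mtx()].
#' @return Invisibly, the paths written (matrix, genes, cells).
#' @export
write_mtx <- function(counts, dir,
                      orientation = c("genes_by_cells", "cells_by_genes")) {
  orientation <- match.arg(orientation)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "genes.tsv", "cells.tsv"))
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  out <- if (orientation == "genes_by_cells") Matrix::t(m) else m
  Matrix::writeMM(out, paths[1])
  writeLines(colnames(counts), paths[2])
  writeLines(rownames(counts), paths[3])
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene<TAB>gene...`.
#' Duplicate genes within a set are dropped keeping the first occurrence.
#' Sets are optionally tagged with a TMM group (`TEL`, `ALT` or `other`)
#' through a two-column mapping (set name, group), given either as a named
#' character vector or as a path to a headerless TSV; unmapped sets default
#' to `"other"`. Membership of set genes in a particular count matrix is
#' checked at use time, not here.
#'
#' @param path Path to the GMT file (optionally gzipped).
#' @param groups Optional named character vector `set name -> group`, or path
#'   to a two-column TSV with the same content.
#' @return A `GeneSetCollection`: list with `sets` (named list of character
#'   vectors) and `group` (named character vector over the same names).
#' @export
read_gmt <- function(path, groups = NULL) {
  con <- open_input(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]),
         call. = FALSE)
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    stop(sprintf("duplicate gene set name: %s", names_[duplicated(names_)][1]),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  gene_set_collection(sets, groups)
}

#' Construct a gene set collection
#'
#' @param sets Named list of character vectors (gene symbols). Gene identity
#'   is by symbol string, case-sensitive; no alias resolution is attempted.
#' @param groups Optional group tags as in [read_gmt()].
#' @return A `GeneSetCollection` object.
#' @export
gene_set_collection <- function(sets, groups = NULL) {
  assert_that(length(sets) == 0 || !is.null(names(sets)),
              "gene sets must be named")
  assert_that(!anyDuplicated(names(sets)), "duplicate gene set names")
  assert_that(all(lengths(sets) > 0), "every gene set must be non-empty")
  grp <- rep("other", length(sets))
  names(grp) <- names(sets)
  if (!is.null(groups)) {
    if (is.character(groups) && is.null(names(groups)) &&
        length(groups) == 1L && file.exists(groups)) {
      tab <- utils::read.delim(groups, header = FALSE,
                               stringsAsFactors = FALSE)
      groups <- stats::setNames(as.character(tab[[2]]), tab[[1]])
    }
    bad <- setdiff(unique(groups), c("TEL", "ALT", "other"))
    assert_that(length(bad) == 0,
                sprintf("unknown TMM group tag: %s", paste(bad, collapse = ", ")))
    hit <- intersect(names(groups), names(grp))
    grp[hit] <- groups[hit]
  }
  structure(list(sets = sets, group = grp), class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(x$sets)))
  if (length(x$sets)) {
    info <- sprintf("  %s [%s] (%d genes)", names(x$sets), x$group,
                    lengths(x$sets))
    cat(paste(utils::head(info, 10), collapse = "\n"), "\n")
    if (length(info) > 10) cat(sprintf("  ... and %d more\n", length(info) - 10))
  }
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Write a gene set collection to GMT
#'
#' @param sets A `GeneSetCollection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets$sets), function(nm) {
    paste(c(nm, sets$group[[nm]], sets$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a table artifact as TSV
#'
#' Writes a data frame with a header row, tab-separated, no quoting or row
#' names. Numeric columns are rendered at 12 significant digits so that a
#' write/read round trip is lossless at that precision.
#'
#' @param table A data frame; one row per cell or per gene.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(table, path) {
  assert_that(is.data.frame(table), "table must be a data frame")
  out <- table
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 12, format = "g")
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table artifact
#'
#' @param path Path written by [write_table()] (or any headered TSV).
#' @return A data frame.
#' @export
read_table_artifact <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
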