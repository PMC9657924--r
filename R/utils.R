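# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Open a path as a connection, transparently handling gzip by extension.
open_input <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

# Coerce to a base dense matrix, preserving dimnames.
as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

# Validate a cells x genes count matrix against its id sidecars.
validate_count_matrix <- function(x) {
  assert_that(!is.null(rownames(x)) && !is.null(colnames(x)),
              "count matrix must carry cell (row) and gene (column) ids")
  assert_that(!anyDuplicated(rownames(x)), "duplicate cell ids")
  assert_that(!anyDuplicated(colnames(x)), "duplicate gene ids")
  vals <- if (inherits(x, "sparseMatrix")) x@x else as.vector(x)
  assert_that(all(vals >= 0), "count matrix has negative entries")
  assert_that(all(vals == floor(vals)), "count matrix has non-integer entries")
  invisible(x)
}
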