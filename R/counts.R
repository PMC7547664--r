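# Count tables travel as tibbles: one id column (first) plus one numeric
# column per gene. Internally every numeric routine works on an integer
# matrix with observation rownames; these two helpers convert between the
# representations and enforce the invariants (non-negative integer counts,
# unique observation and gene ids).

#' Coerce a count table to an integer matrix
#'
#' Accepts either a data frame whose first column holds observation
#' identifiers (cells or spots) with one numeric column per gene, or a
#' numeric matrix with rownames. Validates the count invariants: entries
#' must be finite, non-negative and integer-valued, and both observation
#' and gene identifiers must be unique.
#'
#' @param x A data frame (first column = observation ids) or a numeric
#'   matrix with observation rownames and gene colnames.
#' @param what Label used in error messages ("cell" or "spot").
#' @return An integer-valued numeric matrix, observations in rows.
#' @export
as_count_matrix <- function(x, what = "observation") {
  if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort(sprintf("count table must have an id column and >= 1 gene column"))
    }
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    if (is.null(rownames(m))) {
      abort("count matrix must carry observation ids as rownames")
    }
  } else {
    abort("counts must be a data frame or a matrix")
  }
  storage.mode(m) <- "double"
  validate_counts(m, what = what)
  m
}

validate_counts <- function(m, what = "observation") {
  if (is.null(colnames(m))) abort("count matrix must carry gene ids as colnames")
  if (anyDuplicated(rownames(m))) {
    abort(sprintf("duplicated %s ids in count table", what))
  }
  if (anyDuplicated(colnames(m))) abort("duplicated gene ids in count table")
  if (any(!is.finite(m))) abort("counts contain NA/NaN/Inf entries")
  if (any(m < 0)) abort("counts contain negative entries")
  if (any(m != round(m))) abort("counts contain non-integer entries")
  invisible(m)
}

#' Convert a count matrix back to a tibble
#'
#' Inverse of [as_count_matrix()]: observation ids become the first column,
#' named by `id_col`.
#'
#' @param m Numeric matrix with observation rownames.
#' @param id_col Name of the id column in the output.
#' @return A tibble with one row per observation.
#' @export
counts_as_tibble <- function(m, id_col = "obs") {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble(!!id_col := rownames(m)) %>% dplyr::bind_cols(out)
  out
}

# Annotation tables are two-column tibbles: cell id, type label.
validate_annotation <- function(ann) {
  if (!is.data.frame(ann) || ncol(ann) < 2) {
    abort("annotation must be a data frame with columns (cell, label)")
  }
  cell <- as.character(ann[[1]])
  label <- as.character(ann[[2]])
  if (anyDuplicated(cell)) abort("duplicated cell ids in annotation")
  if (any(is.na(label) | !nzchar(label))) abort("missing or empty type labels")
  tibble(cell = cell, label = label)
}

# Match annotation to the rows of a count matrix, in matrix order.
labels_for <- function(m, ann) {
  ann <- validate_annotation(ann)
  idx <- match(rownames(m), ann$cell)
  if (anyNA(idx)) {
    abort(sprintf(
      "%d cells in the count table have no annotation (first: %s)",
      sum(is.na(idx)), rownames(m)[which(is.na(idx))[1]]
    ))
  }
  ann$label[idx]
}
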