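# Readers and writers for the plain-text formats the package exchanges:
# TSV count tables (observations x genes, header = gene ids, first column =
# observation ids), MatrixMarket sparse counts with sidecar id lists,
# two-column annotation TSVs, and proportion TSVs.

#' Read a count matrix from TSV or MatrixMarket
#'
#' TSV layout: a header row of gene identifiers and a first column of
#' observation identifiers (cells or capture locations), tab-delimited.
#' MatrixMarket (`fmt = "mtx"`) expects coordinate integer files with two
#' sidecars next to the matrix: `<prefix>.obs.txt` and `<prefix>.genes.txt`,
#' one identifier per line, where `<prefix>` is `path` without its
#' extension. Rows are observations, columns genes; pass `transpose = TRUE`
#' for matrices stored genes-by-observations.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param fmt Input format, `"tsv"` or `"mtx"`; guessed from the extension
#'   by default.
#' @param transpose If `TRUE`, transpose the stored matrix after reading.
#' @return A count tibble: first column `obs`, one integer column per gene.
#' @export
read_counts <- function(path, fmt = c("auto", "tsv", "mtx"), transpose = FALSE) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (fmt == "auto") {
    fmt <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "tsv"
  }
  m <- if (fmt == "tsv") read_counts_tsv(path) else read_counts_mtx(path)
  if (transpose) m <- t(m)
  validate_counts(m)
  counts_as_tibble(m)
}

read_counts_tsv <- function(path) {
  if (file.size(path) == 0) abort(sprintf("empty count file: %s", path))
  df <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, name_repair = "minimal",
                    progress = FALSE),
    error = function(e) abort(sprintf("malformed TSV %s: %s", path, conditionMessage(e)))
  )
  if (ncol(df) < 2 || nrow(df) < 1) {
    abort(sprintf("count TSV %s needs a header of gene ids and >= 1 row", path))
  }
  ids <- as.character(df[[1]])
  genes <- names(df)[-1]
  if (anyDuplicated(genes)) abort(sprintf("duplicated gene ids in header of %s", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(sprintf("non-numeric count entries in %s", path))
  rownames(m) <- ids
  colnames(m) <- genes
  m
}

read_counts_mtx <- function(path) {
  prefix <- sub("\\.[^.]*$", "", path)
  obs_file <- paste0(prefix, ".obs.txt")
  gene_file <- paste0(prefix, ".genes.txt")
  for (f in c(obs_file, gene_file)) {
    if (!file.exists(f)) abort(sprintf("missing MTX sidecar: %s", f))
  }
  sp <- tryCatch(Matrix::readMM(path),
    error = function(e) abort(sprintf("malformed MatrixMarket file %s: %s",
                                      path, conditionMessage(e))))
  m <- as.matrix(sp)
  obs <- readLines(obs_file)
  genes <- readLines(gene_file)
  if (length(obs) != nrow(m) || length(genes) != ncol(m)) {
    abort("MTX sidecar id counts do not match matrix dimensions")
  }
  rownames(m) <- obs
  colnames(m) <- genes
  m
}

#' Write a count table as TSV
#'
#' @param counts Count tibble or matrix (see [as_count_matrix()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  m <- as_count_matrix(counts)
  df <- counts_as_tibble(m)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read per-cell type annotations
#'
#' Reads a tab-delimited table whose first column holds cell identifiers
#' and whose remaining column(s) hold type labels. When several label
#' columns are selected they are joined with `sep` into a single composite
#' label (e.g. a class identifier joined with a cluster identifier).
#'
#' @param path Two-or-more-column TSV.
#' @param header Does the file carry a header row?
#' @param label_cols Indices (into the columns after the id column) of the
#'   label columns to use; defaults to the first.
#' @param sep Separator used when joining multiple label columns.
#' @return A tibble with columns `cell` and `label`.
#' @export
read_annotation <- function(path, header = TRUE, label_cols = 1, sep = "_") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort(sprintf("empty annotation file: %s", path))
  df <- readr::read_tsv(path, col_names = header, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()),
                        name_repair = "minimal")
  if (!header) names(df) <- paste0("V", seq_len(ncol(df)))
  if (ncol(df) < 2) abort("annotation file needs >= 2 columns (cell id, label)")
  lab_idx <- label_cols + 1L
  if (any(lab_idx > ncol(df))) abort("label_cols index beyond available columns")
  labels <- df[lab_idx]
  if (any(vapply(labels, function(x) any(is.na(x) | !nzchar(x)), logical(1)))) {
    abort("missing labels in annotation file")
  }
  label <- do.call(paste, c(as.list(labels), sep = sep))
  validate_annotation(tibble(cell = df[[1]], label = label))
}

#' Intersect a selected gene list with the spatial genes
#'
#' After selecting genes on the single-cell side (typically the top
#' expressed genes), the working gene set is the intersection of that
#' selection with the genes present in the spatial data. Order follows the
#' selection, so downstream matrices stay ranked by single-cell expression.
#'
#' @param sc Single-cell count tibble/matrix.
#' @param sp Spatial count tibble/matrix.
#' @param selected Character vector of selected single-cell gene ids; all
#'   single-cell genes by default.
#' @return Character vector of gene ids, in `selected` order.
#' @export
intersect_genes <- function(sc, sp, selected = NULL) {
  sc_genes <- colnames(as_count_matrix(sc, "cell"))
  sp_genes <- colnames(as_count_matrix(sp, "spot"))
  if (is.null(selected)) selected <- sc_genes
  missing <- setdiff(selected, sc_genes)
  if (length(missing) > 0) {
    abort(sprintf("selected genes absent from single-cell data (first: %s)",
                  missing[1]))
  }
  out <- selected[selected %in% sp_genes]
  if (length(out) == 0) {
    abort("no genes shared between the selection and the spatial data")
  }
  out
}

#' Write a proportion table as TSV
#'
#' Rows are capture locations, columns cell types. Refuses to write rows
#' that do not lie on the simplex (sum 1 within 1e-6); an optional
#' `dummy_share` column is written as-is and excluded from that check.
#'
#' @param pm Proportion tibble: first column `spot`, one column per type,
#'   optionally a `dummy_share` column.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_proportions <- function(pm, path) {
  validate_proportions(pm)
  readr::write_tsv(pm, path)
  invisible(path)
}

#' Read a proportion table written by [write_proportions()]
#'
#' @param path TSV file with a `spot` column and one column per type.
#' @return A validated proportion tibble.
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pm <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(spot = readr::col_character(),
                                                .default = readr::col_double()))
  validate_proportions(pm)
  pm
}

# Proportion tibbles: `spot` id column, numeric type columns, optional
# `dummy_share`. Rows must sum to 1 within tol (dummy excluded, matching
# the normalization that leaves the dummy type out).
validate_proportions <- function(pm, tol = 1e-6) {
  if (!is.data.frame(pm) || names(pm)[1] != "spot") {
    abort("proportions must be a data frame with first column `spot`")
  }
  if (anyDuplicated(pm$spot)) abort("duplicated spot ids in proportions")
  w <- proportion_matrix(pm)
  if (ncol(w) < 1) abort("proportions need >= 1 cell-type column")
  if (any(!is.finite(w)) || any(w < -tol) || any(w > 1 + tol)) {
    abort("proportions outside [0, 1]")
  }
  bad <- abs(rowSums(w) - 1) > tol
  if (any(bad)) {
    abort(sprintf("%d proportion rows do not sum to 1 (first: %s)",
                  sum(bad), pm$spot[which(bad)[1]]))
  }
  invisible(pm)
}

# Numeric matrix of the type columns of a proportion tibble.
proportion_matrix <- function(pm) {
  keep <- setdiff(names(pm), c("spot", "dummy_share"))
  w <- as.matrix(pm[keep])
  rownames(w) <- pm$spot
  w
}
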