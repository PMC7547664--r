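# Light preprocessing: the model deliberately works on raw counts, so the
# only steps are gene selection by total expression, bounded per-type cell
# subsampling, and library-size computation.

#' Select the top expressed genes
#'
#' Ranks genes by total count across all cells and returns the top `n`
#' identifiers. Genes with zero total count are never selected (their rate
#' is unidentifiable). Ties in total expression break by ascending
#' lexicographic gene id so the selection is deterministic.
#'
#' @param sc Count tibble or matrix, cells in rows.
#' @param n Number of genes to keep (default 5000, the value used for real
#'   data sets; the capped result may be shorter if fewer genes are
#'   expressed).
#' @return Character vector of at most `n` gene ids, descending by total
#'   expression.
#' @export
select_top_genes <- function(sc, n = 5000) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single integer >= 1")
  }
  m <- as_count_matrix(sc, "cell")
  totals <- colSums(m)
  totals <- totals[totals > 0]
  ord <- order(-totals, names(totals), method = "radix")
  head(names(totals)[ord], n)
}

#' Bounded per-type subsampling of cells
#'
#' Applies the bounded subsampling rule used to keep reference fitting
#' tractable: a type with fewer than `lower` cells is excluded entirely, a
#' type with between `lower` and `upper` cells is kept whole, and a type
#' with more than `upper` cells is downsampled to exactly `upper` cells,
#' drawn uniformly without replacement. Deterministic given `seed`; the
#' draw uses a local RNG stream and does not disturb the global RNG.
#'
#' @param sc Count tibble or matrix, cells in rows.
#' @param ann Annotation tibble (`cell`, `label`); every cell in `sc` must
#'   be annotated.
#' @param lower,upper Inclusive bounds on per-type cell counts.
#' @param seed Integer seed for the downsampling draws.
#' @return A list with `counts` (tibble restricted to kept cells) and
#'   `annotation` (matching annotation tibble).
#' @export
subsample_cells <- function(sc, ann, lower = 25, upper = 250, seed = 1) {
  if (lower < 1 || upper < lower) abort("need 1 <= lower <= upper")
  m <- as_count_matrix(sc, "cell")
  labels <- labels_for(m, ann)
  keep <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(m)), labels), function(idx) {
      nz <- length(idx)
      if (nz < lower) return(integer(0))
      if (nz <= upper) return(idx)
      sort(sample(idx, upper))
    }), use.names = FALSE)
  })
  if (length(keep) == 0) abort("no cell type survives the subsampling bounds")
  keep <- sort(keep)
  list(
    counts = counts_as_tibble(m[keep, , drop = FALSE]),
    annotation = tibble(cell = rownames(m)[keep], label = labels[keep])
  )
}

#' Library sizes
#'
#' Total count per observation (row sum); the scaling factor that absorbs
#' sequencing depth in the single-cell model.
#'
#' @param x Count tibble or matrix.
#' @return Named numeric vector of per-observation totals.
#' @export
library_sizes <- function(x) {
  m <- as_count_matrix(x)
  rowSums(m)
}
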