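# Evaluation protocol: per-spot RMSE against ground truth, a one-sided
# paired Wilcoxon comparison between methods, a Dirichlet null
# distribution that contextualizes RMSE values, pairwise cell-type
# co-localization, and the max-scaling used for display.

# Align two proportion tibbles on spot ids and type columns; errors on
# any mismatch. Returns list of two matrices in matching order.
align_proportions <- function(w, truth) {
  validate_proportions(w)
  validate_proportions(truth)
  mw <- proportion_matrix(w)
  mt <- proportion_matrix(truth)
  if (!setequal(rownames(mw), rownames(mt))) {
    abort("spot ids differ between estimate and truth")
  }
  if (!setequal(colnames(mw), colnames(mt))) {
    abort("cell-type labels differ between estimate and truth")
  }
  mt <- mt[rownames(mw), colnames(mw), drop = FALSE]
  list(w = mw, truth = mt)
}

#' Per-spot RMSE between estimated and true proportions
#'
#' For each spot `s`, `sqrt(mean_z (w[s, z] - what[s, z])^2)` over the
#' `|Z|` cell types. Spots and types are aligned by id; a `dummy_share`
#' column, if present, is ignored.
#'
#' @param w Estimated proportion tibble.
#' @param truth Ground-truth proportion tibble (same spots and types).
#' @return A tibble with columns `spot` and `rmse`.
#' @export
rmse <- function(w, truth) {
  al <- align_proportions(w, truth)
  tibble(
    spot = rownames(al$w),
    rmse = unname(sqrt(rowMeans((al$w - al$truth)^2)))
  )
}

#' One-sided paired Wilcoxon comparison of per-spot RMSE
#'
#' Tests whether the first method's per-spot RMSE values are
#' asymmetrically distributed below the second's (signed-rank test,
#' `alternative = "less"`, paired by spot). Zero differences are dropped
#' by the standard signed-rank procedure; if all differences are zero the
#' test is degenerate and an error is raised.
#'
#' @param rmse_a,rmse_b Numeric vectors of per-spot RMSE, paired by
#'   position (or tibbles from [rmse()], paired by spot id).
#' @return A tibble with `statistic` and `p_value`.
#' @export
paired_wilcoxon <- function(rmse_a, rmse_b) {
  if (is.data.frame(rmse_a)) {
    if (!is.data.frame(rmse_b)) abort("both arguments must have the same form")
    idx <- match(rmse_a$spot, rmse_b$spot)
    if (anyNA(idx)) abort("spot ids differ between the two RMSE tables")
    rmse_b <- rmse_b$rmse[idx]
    rmse_a <- rmse_a$rmse
  }
  if (length(rmse_a) != length(rmse_b)) abort("RMSE vectors must be paired")
  if (all(rmse_a == rmse_b)) {
    abort("degenerate comparison: all paired differences are zero")
  }
  ht <- suppressWarnings(
    wilcox.test(rmse_a, rmse_b, alternative = "less", paired = TRUE,
                conf.int = TRUE)
  )
  tibble(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Dirichlet null distribution of RMSE
#'
#' Replaces the estimates by draws from a flat Dirichlet (all
#' concentrations 1) over the `|Z|` types, once per spot, and records the
#' mean per-spot RMSE against the ground truth; repeating this `reps`
#' times yields a null distribution that contextualizes an achieved RMSE.
#' `compare = "draws"` scores two independent Dirichlet draws against
#' each other instead of draw-vs-truth.
#'
#' @param truth Ground-truth proportion tibble.
#' @param reps Number of repetitions (default 1000).
#' @param seed Integer seed.
#' @param compare `"truth"` (default) or `"draws"`.
#' @return A tibble with columns `rep` and `mean_rmse`.
#' @export
dirichlet_null <- function(truth, reps = 1000, seed = 1,
                           compare = c("truth", "draws")) {
  compare <- match.arg(compare)
  if (reps < 1) abort("`reps` must be >= 1")
  validate_proportions(truth)
  mt <- proportion_matrix(truth)
  n_s <- nrow(mt)
  n_z <- ncol(mt)
  if (n_z < 2) abort("need >= 2 cell types for a Dirichlet null")
  draw <- function() {
    g <- matrix(rgamma(n_s * n_z, 1), n_s, n_z)
    g / rowSums(g)
  }
  means <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      d <- draw()
      ref <- if (compare == "truth") mt else draw()
      mean(sqrt(rowMeans((d - ref)^2)))
    }, numeric(1))
  })
  tibble(rep = seq_len(reps), mean_rmse = means)
}

#' Pairwise cell-type co-localization
#'
#' Pearson correlation between the proportions of every pair of cell
#' types, treating each capture location as one data point; positively
#' correlated types share a spatial distribution. Two-sided p-values come
#' from the standard correlation test; the significance mask applies
#' `p <= alpha_level` (default 0.01), uncorrected by default.
#'
#' @param w Proportion tibble (`dummy_share` ignored).
#' @param alpha_level Significance threshold for the mask.
#' @param adjust Multiple-testing adjustment passed to
#'   [stats::p.adjust()]; `"none"` by default.
#' @return An object of class `coloc` holding the correlation matrix
#'   `r`, `p_values`, and the logical `significant` mask.
#' @export
colocalization <- function(w, alpha_level = 0.01, adjust = "none") {
  validate_proportions(w)
  m <- proportion_matrix(w)
  if (nrow(m) < 3) abort("need >= 3 spots to correlate")
  if (ncol(m) < 2) abort("need >= 2 cell types to correlate")
  types <- colnames(m)
  n_z <- length(types)
  r <- matrix(NA_real_, n_z, n_z, dimnames = list(types, types))
  pv <- r
  diag(r) <- 1
  diag(pv) <- 0
  sds <- apply(m, 2, stats::sd)
  for (i in seq_len(n_z - 1)) {
    for (j in seq(i + 1, n_z)) {
      if (sds[i] == 0 || sds[j] == 0) next  # undefined, left missing
      ht <- cor.test(m[, i], m[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ht$estimate)
      pv[i, j] <- pv[j, i] <- ht$p.value
    }
  }
  padj <- pv
  off <- upper.tri(pv)
  padj[off] <- stats::p.adjust(pv[off], method = adjust)
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(
    list(type_labels = types, r = r, p_values = padj,
         significant = padj <= alpha_level, alpha_level = alpha_level,
         n_spots = nrow(m)),
    class = "coloc"
  )
}

#' @export
print.coloc <- function(x, ...) {
  cat(sprintf("<coloc> %d cell types over %d spots (significance at p <= %g)\n",
              length(x$type_labels), x$n_spots, x$alpha_level))
  print(round(x$r, 3))
  invisible(x)
}

#' @describeIn colocalization Long tibble of the upper triangle: one row
#'   per type pair with `estimate`, `p_value`, `significant`.
#' @param x A `coloc` object.
#' @param ... Unused.
#' @method tidy coloc
#' @export
tidy.coloc <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    type_a = x$type_labels[idx[, 1]],
    type_b = x$type_labels[idx[, 2]],
    estimate = x$r[idx],
    p_value = x$p_values[idx],
    significant = x$significant[idx]
  ) %>% arrange(.data$type_a, .data$type_b)
}

#' @describeIn colocalization Correlation heatmap with significant pairs
#'   marked.
#' @param object A `coloc` object.
#' @method autoplot coloc
#' @export
autoplot.coloc <- function(object, ...) {
  df <- as_tibble(as.data.frame(as.table(object$r),
                                responseName = "estimate"))
  names(df)[1:2] <- c("type_a", "type_b")
  sig <- as.vector(object$significant)
  df$label <- ifelse(!is.na(sig) & sig & df$type_a != df$type_b, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type_a, y = .data$type_b,
                                   fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r",
                  title = "Cell-type co-localization") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Max-scale proportions for display
#'
#' Divides each cell type's proportions by the largest value observed for
#' that type (within the table, i.e. one section), so every column's
#' maximum becomes 1 — emphasizing each type's spatial pattern. No
#' thresholding or further adjustment is applied. All-zero columns are
#' left as zeros, with a warning.
#'
#' @param w Proportion tibble.
#' @return A tibble of the same shape (no longer on the simplex); the
#'   `dummy_share` column, if present, is carried through unscaled.
#' @export
scale_proportions <- function(w) {
  validate_proportions(w)
  m <- proportion_matrix(w)
  maxima <- apply(m, 2, max)
  if (any(maxima == 0)) {
    warn(sprintf("all-zero proportion column(s) left unscaled: %s",
                 paste(colnames(m)[maxima == 0], collapse = ", ")))
    maxima[maxima == 0] <- 1
  }
  scaled <- sweep(m, 2, maxima, "/")
  out <- dplyr::bind_cols(
    tibble(spot = w$spot),
    as_tibble(as.data.frame(scaled, check.names = FALSE))
  )
  if ("dummy_share" %in% names(w)) out$dummy_share <- w$dummy_share
  out
}

#' Per-type spatial pattern plot
#'
#' Plots max-scaled proportions per spot and type as a tile strip —
#' a coordinate-free view of which spots each type occupies.
#'
#' @param w Proportion tibble.
#' @param scale Max-scale each type first? (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_proportions <- function(w, scale = TRUE) {
  if (scale) w <- suppressWarnings(scale_proportions(w))
  keep <- setdiff(names(w), "dummy_share")
  long <- tidyr::pivot_longer(w[keep], -"spot", names_to = "type",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$spot, y = .data$type,
                                     fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "capture location", y = NULL,
                  fill = if (scale) "scaled\nproportion" else "proportion") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
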