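# Semi-synthetic spot generation: spots are assembled by pooling real
# (or simulated) single cells, deliberately NOT by sampling from the
# negative binomial model, so benchmarks do not favour the model family.
# Also a fully synthetic NB single-cell generator for parameter-recovery
# tests.

# Nearest integer, half away from zero: round(2.5) -> 3, round(-2.5) -> -3.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Generate semi-synthetic spatial spots with known proportions
#'
#' For each of `n_spots` capture locations: draw the number of
#' contributing cells `C_s ~ Unif{lb..ub}`; draw how many types are
#' present, uniform on 1..|Z|, and pick that many types without
#' replacement; draw unadjusted proportions from a flat Dirichlet over the
#' picked types; convert to integer per-type cell counts by
#' nearest-integer rounding (half away from zero); then pool the counts of
#' that many real cells, sampled uniformly without replacement within each
#' type, each cell's counts scaled by `alpha` and re-rounded. The recorded
#' ground truth is the per-spot normalization of the rounded cell counts.
#'
#' Rounding repairs: if every type rounds to zero cells, the largest-
#' proportion type is set to one cell; if a type's demand exceeds its
#' available cells, it is capped at the available count (sampling is
#' without replacement) and the truth renormalized.
#'
#' @param sc Single-cell count tibble or matrix (the generation set).
#' @param ann Annotation tibble (`cell`, `label`).
#' @param n_spots Number of spots to generate (1000 in the reference
#'   benchmark).
#' @param lb,ub Bounds on cells per spot: 10-30 emulates classic ST
#'   arrays, 1-10 the Visium platform.
#' @param alpha Count scaling factor applied to each pooled cell
#'   (default 1).
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `synthetic_spots`: `counts` (spot x gene
#'   tibble), `truth` (proportion tibble over all types in `ann`),
#'   `members` (tibble spot/type/cell), and the `config` echo.
#' @export
generate_spots <- function(sc, ann, n_spots, lb = 10, ub = 30, alpha = 1,
                           seed = 1) {
  if (lb < 1 || ub < lb) abort("need 1 <= lb <= ub")
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (n_spots < 1) abort("`n_spots` must be >= 1")
  y <- as_count_matrix(sc, "cell")
  labels <- labels_for(y, ann)
  types <- sort(unique(labels))
  cells_by_type <- split(rownames(y), labels)

  res <- withr::with_seed(seed, {
    spots <- matrix(0, n_spots, ncol(y),
                    dimnames = list(sprintf("spot_%d", seq_len(n_spots)),
                                    colnames(y)))
    truth <- matrix(0, n_spots, length(types),
                    dimnames = list(rownames(spots), types))
    members <- vector("list", n_spots)
    for (s in seq_len(n_spots)) {
      C_s <- sample(lb:ub, 1)
      k <- sample(seq_along(types), 1)
      zs <- sample(types, k)
      p <- rgamma(k, 1)
      p <- p / sum(p)
      n_cells <- round_half_away(p * C_s)
      if (all(n_cells == 0)) n_cells[which.max(p)] <- 1
      avail <- lengths(cells_by_type)[zs]
      n_cells <- pmin(n_cells, avail)
      keep <- n_cells > 0
      zs <- zs[keep]
      n_cells <- n_cells[keep]
      picked <- purrr::map2(zs, n_cells, function(z, n) {
        pool <- cells_by_type[[z]]
        if (n == length(pool)) pool else sample(pool, n)
      })
      ids <- unlist(picked, use.names = FALSE)
      contrib <- round_half_away(alpha * y[ids, , drop = FALSE])
      spots[s, ] <- colSums(contrib)
      truth[s, zs] <- n_cells / sum(n_cells)
      members[[s]] <- tibble(
        spot = rownames(spots)[s],
        type = rep(zs, n_cells),
        cell = ids
      )
    }
    list(spots = spots, truth = truth, members = dplyr::bind_rows(members))
  })

  truth_tbl <- dplyr::bind_cols(
    tibble(spot = rownames(res$truth)),
    as_tibble(as.data.frame(res$truth, check.names = FALSE))
  )
  validate_proportions(truth_tbl)
  structure(
    list(
      counts = counts_as_tibble(res$spots, id_col = "obs"),
      truth = truth_tbl,
      members = res$members,
      config = list(n_spots = n_spots, lb = lb, ub = ub, alpha = alpha,
                    seed = seed)
    ),
    class = "synthetic_spots"
  )
}

#' @export
print.synthetic_spots <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_spots> %d spots x %d genes (%d-%d cells/spot, alpha = %g, seed = %d)\n",
    cfg$n_spots, ncol(x$counts) - 1, cfg$lb, cfg$ub, cfg$alpha, cfg$seed
  ))
  invisible(x)
}

#' Split single-cell data into generation and validation halves
#'
#' Stratified by type: each type's cells are split into two equal,
#' mutually exclusive halves, so spots assembled from one half can be
#' deconvolved against a reference fitted on the other without
#' information leakage. Odd counts give the extra cell to the generation
#' half; a single-cell type goes to the generation half only, with a
#' warning.
#'
#' @param sc Count tibble or matrix, cells in rows.
#' @param ann Annotation tibble (`cell`, `label`).
#' @param seed Integer seed for the within-type shuffles.
#' @return A list with elements `generation` and `validation`, each a
#'   list of `counts` and `annotation`.
#' @export
split_generation_validation <- function(sc, ann, seed = 1) {
  y <- as_count_matrix(sc, "cell")
  labels <- labels_for(y, ann)
  singletons <- names(which(table(labels) == 1))
  if (length(singletons) > 0) {
    warn(sprintf("type(s) with a single cell go to the generation set only: %s",
                 paste(singletons, collapse = ", ")))
  }
  gen_idx <- withr::with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(y)), labels), function(idx) {
      idx <- idx[sample.int(length(idx))]
      idx[seq_len(ceiling(length(idx) / 2))]
    }), use.names = FALSE)
  })
  gen_idx <- sort(gen_idx)
  val_idx <- setdiff(seq_len(nrow(y)), gen_idx)
  half <- function(idx) list(
    counts = counts_as_tibble(y[idx, , drop = FALSE]),
    annotation = tibble(cell = rownames(y)[idx], label = labels[idx])
  )
  list(generation = half(gen_idx), validation = half(val_idx))
}

#' Ground-truth parameters for the NB single-cell generator
#'
#' @param rates Positive genes x types matrix (dimnames used as ids if
#'   present).
#' @param probs Per-gene success probabilities in (0, 1).
#' @param lib_size Library-size scaling factor(s) for the simulated cells
#'   (recycled per cell).
#' @return A list of class `nb_truth`.
#' @export
nb_ground_truth <- function(rates, probs, lib_size = 1) {
  rates <- as.matrix(rates)
  if (any(rates <= 0)) abort("rates must be positive")
  if (length(probs) != nrow(rates)) abort("need one prob per gene")
  if (any(probs <= 0 | probs >= 1)) abort("probs must lie in (0, 1)")
  if (any(lib_size <= 0)) abort("lib_size must be positive")
  if (is.null(rownames(rates))) {
    rownames(rates) <- sprintf("g%d", seq_len(nrow(rates)))
  }
  if (is.null(colnames(rates))) {
    colnames(rates) <- sprintf("type%d", seq_len(ncol(rates)))
  }
  names(probs) <- rownames(rates)
  structure(list(rates = rates, probs = probs, lib_size = lib_size),
            class = "nb_truth")
}

#' Simulate annotated single-cell counts from the NB model
#'
#' Forward-samples `y[g, c] ~ NB(s_c * r[g, z_c], p_g)` under the pinned
#' parameterization (mean `s_c * r * p / (1 - p)`), producing a labelled
#' data set whose true parameters are known — the input for
#' parameter-recovery tests of the single-cell fit.
#'
#' @param truth An [nb_ground_truth()].
#' @param cells_per_type Cells to simulate per type (recycled across
#'   types).
#' @param seed Integer seed.
#' @return A list with `counts` (cell x gene tibble) and `annotation`.
#' @export
generate_nb_sc <- function(truth, cells_per_type, seed = 1) {
  stopifnot(inherits(truth, "nb_truth"))
  n_z <- ncol(truth$rates)
  n_g <- nrow(truth$rates)
  per_type <- rep_len(cells_per_type, n_z)
  n_c <- sum(per_type)
  zidx <- rep(seq_len(n_z), per_type)
  s <- rep_len(truth$lib_size, n_c)
  y <- withr::with_seed(seed, {
    mu_size <- t(truth$rates[, zidx, drop = FALSE]) * s    # C x G of s_c*r
    m <- matrix(
      stats::rnbinom(n_c * n_g, size = as.vector(mu_size),
                     prob = rep(1 - truth$probs, each = n_c)),
      n_c, n_g
    )
    m
  })
  rownames(y) <- sprintf("cell_%d", seq_len(n_c))
  colnames(y) <- rownames(truth$rates)
  list(
    counts = counts_as_tibble(y, id_col = "obs"),
    annotation = tibble(cell = rownames(y),
                        label = colnames(truth$rates)[zidx])
  )
}
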