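# Fixtures are built in code. Conventions: small deterministic matrices
# for I/O and arithmetic tests; NB ground truths with lognormal
# expression-fraction rates (column-normalized so a rate is roughly a
# gene's share of a cell's transcripts) for recovery tests.

make_counts <- function(m, obs = NULL, genes = NULL) {
  if (is.null(obs)) obs <- sprintf("c%d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  dimnames(m) <- list(obs, genes)
  counts_as_tibble(m)
}

# Lognormal expression-fraction rates: each type's rates sum to 1, so
# lib_size sets the expected depth scale.
make_nb_truth <- function(n_genes, n_types, seed, lib_size = 1500,
                          p_range = c(0.2, 0.8), sdlog = 1.3) {
  withr::with_seed(seed, {
    raw <- matrix(exp(rnorm(n_genes * n_types, 0, sdlog)), n_genes, n_types)
    rates <- sweep(raw, 2, colSums(raw), "/")
    nb_ground_truth(rates, probs = runif(n_genes, p_range[1], p_range[2]),
                    lib_size = lib_size)
  })
}

# A tiny annotated data set used across I/O and preprocessing tests.
tiny_sc <- function() {
  m <- matrix(c(1, 0, 3,
                3, 2, 0,
                0, 5, 1,
                2, 2, 2), 4, 3, byrow = TRUE)
  list(
    counts = make_counts(m),
    annotation = tibble::tibble(cell = sprintf("c%d", 1:4),
                                label = c("A", "A", "B", "B"))
  )
}

make_proportions <- function(w, spots = NULL, types = NULL) {
  if (is.null(spots)) spots <- sprintf("s%d", seq_len(nrow(w)))
  if (is.null(types)) types <- sprintf("t%d", seq_len(ncol(w)))
  dimnames(w) <- list(NULL, types)
  dplyr::bind_cols(tibble::tibble(spot = spots),
                   tibble::as_tibble(as.data.frame(w, check.names = FALSE)))
}
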