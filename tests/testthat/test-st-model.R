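# Spatial MAP fitting: the rate assembly, proportion normalization,
# mixture recovery on simulated spots, and the effect of the dummy-type
# prior.

test_that("spot rate assembles mixture, bias and dummy contributions", {
  # dummy off
  expect_equal(spot_rate(c(1, 1), 1, c(2, 3), gamma = 0), 5)
  # pure-noise spot: only the dummy term remains
  eps <- 0.5
  expect_equal(spot_rate(c(1e-12, 1e-12), 1, c(2, 3), gamma = 2, eps = eps),
               2 * (log1p(exp(-abs(eps))) + max(eps, 0)), tolerance = 1e-9)
  # doubling the bias and halving the quantities leaves the rate unchanged
  expect_equal(spot_rate(c(0.5, 1.5), 2, c(2, 3)),
               spot_rate(c(1, 3), 1, c(2, 3)))
  expect_error(spot_rate(c(1, NA), 1, c(2, 3)), "non-finite")
  expect_error(spot_rate(c(1, 1), -1, c(2, 3)), "positivity")
})

test_that("proportions are the simplex normalization of v, dummy excluded", {
  fit <- structure(list(
    spot_ids = c("s1", "s2"), type_labels = c("A", "B", "C"),
    v = matrix(c(2, 1, 2, 1e-9, 4, 1e-9), 2, 3,
               dimnames = list(c("s1", "s2"), c("A", "B", "C"))),
    gamma = c(1, 3), dummy = TRUE
  ), class = "st_fit")
  w <- compute_proportions(fit)
  expect_equal(unlist(w[1, c("A", "B", "C")], use.names = FALSE),
               c(0.25, 0.25, 0.5))
  expect_equal(unlist(w[2, c("A", "B", "C")], use.names = FALSE),
               c(1, 0, 0), tolerance = 1e-8)
  expect_equal(w$dummy_share, c(1 / 9, 3 / 4), tolerance = 1e-8)
  # scale invariance: multiplying a spot's v by c > 0 leaves w unchanged
  fit2 <- fit
  fit2$v[1, ] <- fit$v[1, ] * 17
  expect_equal(compute_proportions(fit2)[, c("A", "B", "C")],
               w[, c("A", "B", "C")])
})

test_that("known mixtures are recovered from simulated spots", {
  truth <- make_nb_truth(100, 2, seed = 41, lib_size = 1200)
  src <- generate_nb_sc(truth, cells_per_type = 120, seed = 42)
  spots <- generate_spots(src$counts, src$annotation, n_spots = 50,
                          lb = 10, ub = 30, seed = 43)
  scfit <- fit_sc(src$counts, src$annotation, fit_config(epochs = 1500, seed = 44))
  stfit <- fit_st(spots$counts, scfit,
                  fit_config(epochs = 3000, learning_rate = 0.03, seed = 45))
  w <- compute_proportions(stfit)
  rr <- rmse(w, spots$truth)
  expect_lt(mean(rr$rmse), 0.1)
  # every row on the simplex
  expect_lt(max(abs(rowSums(as.matrix(w[, scfit$type_labels])) - 1)), 1e-6)
  # descent
  h <- stfit$loss_history
  expect_lte(h[length(h)], h[1])
})

test_that("spots built from a single type are assigned to it", {
  truth <- make_nb_truth(60, 3, seed = 51, lib_size = 200)
  src <- generate_nb_sc(truth, cells_per_type = 60, seed = 52)
  scfit <- fit_sc(src$counts, src$annotation, fit_config(epochs = 1200, seed = 53))
  # pool disjoint groups of 5 first-type cells into pure spots; identical
  # compositions cannot constrain a free per-gene bias, so beta stays at 1
  y <- as_count_matrix(src$counts)
  idx <- which(src$annotation$label == scfit$type_labels[1])
  spots <- t(vapply(1:4, function(i) {
    colSums(y[idx[((i - 1) * 5 + 1):(i * 5)], , drop = FALSE])
  }, numeric(ncol(y))))
  rownames(spots) <- sprintf("s%d", 1:4)
  stfit <- fit_st(spots, scfit,
                  fit_config(epochs = 8000, learning_rate = 0.1, seed = 54),
                  fit_beta = FALSE)
  w <- compute_proportions(stfit)
  expect_true(all(w[[scfit$type_labels[1]]] >= 0.9))
})

test_that("gene alignment is by id, not column position", {
  truth <- make_nb_truth(30, 2, seed = 61, lib_size = 500)
  src <- generate_nb_sc(truth, cells_per_type = 40, seed = 62)
  spots <- generate_spots(src$counts, src$annotation, n_spots = 10,
                          lb = 5, ub = 10, seed = 63)
  scfit <- fit_sc(src$counts, src$annotation, fit_config(epochs = 400, seed = 64))
  m <- as_count_matrix(spots$counts)
  perm <- withr::with_seed(66, m[, sample(ncol(m)), drop = FALSE])
  f1 <- fit_st(m, scfit, fit_config(epochs = 300, seed = 65))
  f2 <- fit_st(perm, scfit, fit_config(epochs = 300, seed = 65))
  expect_equal(f1$v, f2$v)
  expect_identical(f1$gene_ids, f2$gene_ids)
})

test_that("the dummy prior restrains noise absorption", {
  truth <- make_nb_truth(40, 2, seed = 71, lib_size = 800)
  src <- generate_nb_sc(truth, cells_per_type = 50, seed = 72)
  scfit <- fit_sc(src$counts, src$annotation, fit_config(epochs = 800, seed = 73))
  # pure-noise spots: counts unrelated to the reference profiles
  noise <- withr::with_seed(74, {
    matrix(rpois(12 * 40, 20), 12, 40,
           dimnames = list(sprintf("n%d", 1:12), scfit$gene_ids))
  })
  with_prior <- fit_st(noise, scfit, fit_config(epochs = 1500, seed = 75))
  no_prior <- fit_st(noise, scfit, fit_config(epochs = 1500, seed = 75),
                     prior = FALSE)
  share <- function(f) mean(f$gamma / (f$gamma + rowSums(f$v)))
  expect_gt(share(no_prior), share(with_prior))
})

test_that("degenerate spatial inputs are handled", {
  truth <- make_nb_truth(10, 2, seed = 81, lib_size = 200)
  src <- generate_nb_sc(truth, cells_per_type = 15, seed = 82)
  scfit <- fit_sc(src$counts, src$annotation, fit_config(epochs = 100, seed = 83))
  spot <- matrix(c(rep(1, 10), rep(0, 10)), 2, 10, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), scfit$gene_ids))
  expect_warning(fit_st(spot, scfit, fit_config(epochs = 5, seed = 84)),
                 "zero total count")
  nomatch <- matrix(1, 1, 2, dimnames = list("s1", c("zz1", "zz2")))
  expect_error(fit_st(nomatch, scfit, fit_config(epochs = 2)), "no genes shared")
})
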