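# Semi-synthetic spot generator contracts: cell-count bounds, ground-truth
# simplex rows, count conservation at alpha = 1, seed determinism; the
# generation/validation split; and the fully synthetic NB generator.

test_that("per-spot cell totals respect both platform regimes", {
  truth <- make_nb_truth(25, 4, seed = 1, lib_size = 400)
  src <- generate_nb_sc(truth, cells_per_type = 60, seed = 2)
  for (bounds in list(c(10, 30), c(1, 10))) {
    spots <- generate_spots(src$counts, src$annotation, n_spots = 40,
                            lb = bounds[1], ub = bounds[2], seed = 3)
    totals <- dplyr::count(spots$members, spot)$n
    expect_length(totals, 40)
    expect_true(all(totals >= bounds[1] & totals <= bounds[2]))
  }
})

test_that("ground-truth rows lie on the simplex and match the members table", {
  truth <- make_nb_truth(25, 4, seed = 4, lib_size = 400)
  src <- generate_nb_sc(truth, cells_per_type = 60, seed = 5)
  spots <- generate_spots(src$counts, src$annotation, n_spots = 30,
                          lb = 10, ub = 30, seed = 6)
  w <- as.matrix(spots$truth[-1])
  expect_lt(max(abs(rowSums(w) - 1)), 1e-9)
  expect_true(all(w >= 0))
  # truth equals the per-spot normalization of sampled cell counts
  memb <- dplyr::count(spots$members, spot, type)
  for (i in seq_len(5)) {
    sp <- spots$truth$spot[i]
    sub <- memb[memb$spot == sp, ]
    expect_equal(unlist(spots$truth[i, sub$type], use.names = FALSE),
                 sub$n / sum(sub$n))
  }
})

test_that("alpha = 1 conserves counts: spots are exact sums of their cells", {
  truth <- make_nb_truth(25, 3, seed = 7, lib_size = 400)
  src <- generate_nb_sc(truth, cells_per_type = 50, seed = 8)
  spots <- generate_spots(src$counts, src$annotation, n_spots = 20,
                          lb = 5, ub = 15, alpha = 1, seed = 9)
  y <- as_count_matrix(src$counts)
  x <- as_count_matrix(spots$counts, "spot")
  for (sp in unique(spots$members$spot)[1:5]) {
    cells <- spots$members$cell[spots$members$spot == sp]
    expect_identical(x[sp, ], colSums(y[cells, , drop = FALSE]))
  }
  # totals equal the sum of member cells' library sizes
  libs <- library_sizes(src$counts)
  totals_by_spot <- tapply(libs[spots$members$cell], spots$members$spot, sum)
  expect_identical(unname(rowSums(x)[names(totals_by_spot)]),
                   unname(as.numeric(totals_by_spot)))
})

test_that("a single-cell spot reproduces that cell's row exactly", {
  truth <- make_nb_truth(25, 3, seed = 10, lib_size = 400)
  src <- generate_nb_sc(truth, cells_per_type = 30, seed = 11)
  spots <- generate_spots(src$counts, src$annotation, n_spots = 10,
                          lb = 1, ub = 1, alpha = 1, seed = 12)
  y <- as_count_matrix(src$counts)
  x <- as_count_matrix(spots$counts, "spot")
  expect_true(all(dplyr::count(spots$members, spot)$n == 1))
  for (i in seq_len(10)) {
    sp <- spots$members$spot[i]
    expect_identical(x[sp, ], y[spots$members$cell[i], ])
  }
  # one-hot ground truth
  w <- as.matrix(spots$truth[-1])
  expect_true(all(apply(w, 1, max) == 1))
})

test_that("generation is byte-identical under the same seed", {
  truth <- make_nb_truth(20, 3, seed = 13, lib_size = 300)
  src <- generate_nb_sc(truth, cells_per_type = 40, seed = 14)
  a <- generate_spots(src$counts, src$annotation, n_spots = 15,
                      lb = 5, ub = 15, seed = 99)
  b <- generate_spots(src$counts, src$annotation, n_spots = 15,
                      lb = 5, ub = 15, seed = 99)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$members, b$members)
  c <- generate_spots(src$counts, src$annotation, n_spots = 15,
                      lb = 5, ub = 15, seed = 100)
  expect_false(identical(a$counts, c$counts))
})

test_that("scaling factor alpha rescales pooled counts", {
  truth <- make_nb_truth(20, 2, seed = 15, lib_size = 300)
  src <- generate_nb_sc(truth, cells_per_type = 30, seed = 16)
  a1 <- generate_spots(src$counts, src$annotation, n_spots = 10,
                       lb = 3, ub = 8, alpha = 1, seed = 17)
  a2 <- generate_spots(src$counts, src$annotation, n_spots = 10,
                       lb = 3, ub = 8, alpha = 2, seed = 17)
  expect_identical(a1$members, a2$members)
  expect_identical(as_count_matrix(a2$counts) , as_count_matrix(a1$counts) * 2)
})

test_that("generation/validation split is stratified, disjoint and odd-aware", {
  n_per <- c(A = 10, B = 11, C = 2)
  m <- matrix(rpois(sum(n_per) * 4, 4), sum(n_per), 4)
  cnt <- make_counts(m)
  ann <- tibble::tibble(cell = cnt$obs, label = rep(names(n_per), n_per))
  halves <- split_generation_validation(cnt, ann, seed = 18)
  gen <- halves$generation$annotation
  val <- halves$validation$annotation
  expect_length(intersect(gen$cell, val$cell), 0)
  expect_identical(sort(c(gen$cell, val$cell)), sort(ann$cell))
  expect_identical(as.integer(table(gen$label)[c("A", "B")]), c(5L, 6L))
  expect_identical(as.integer(table(val$label)[c("A", "B")]), c(5L, 5L))

  # a singleton type goes to the generation set only, with a warning
  ann1 <- ann
  ann1$label[ann1$label == "C"] <- c("C", "D")[1:2]
  expect_warning(h2 <- split_generation_validation(cnt, ann1, seed = 19),
                 "single cell")
  expect_true(all(c("C", "D") %in% h2$generation$annotation$label))
  expect_false(any(c("C", "D") %in% h2$validation$annotation$label))
})

test_that("NB single-cell generator matches its closed-form mean", {
  # one type, few genes, many cells: empirical means within 3 SE
  rates <- matrix(c(0.05, 0.2, 0.5), 3, 1,
                  dimnames = list(c("g1", "g2", "g3"), "A"))
  probs <- c(0.3, 0.5, 0.7)
  truth <- nb_ground_truth(rates, probs, lib_size = 10)
  sim <- generate_nb_sc(truth, cells_per_type = 5000, seed = 20)
  y <- as_count_matrix(sim$counts)
  mu <- 10 * rates[, 1] * probs / (1 - probs)
  sigma <- sqrt(mu / (1 - probs))
  se <- sigma / sqrt(5000)
  dev <- abs(colMeans(y) - mu)
  expect_true(all(dev < 3 * se))
})

test_that("NB generator edge cases behave", {
  # p -> 0 gives a near-all-zero matrix
  rates <- matrix(0.5, 4, 1)
  truth <- nb_ground_truth(rates, probs = rep(1e-6, 4), lib_size = 100)
  sim <- generate_nb_sc(truth, cells_per_type = 200, seed = 21)
  expect_lt(sum(as_count_matrix(sim$counts)), 5)
  # identical rates for two types give statistically indistinguishable fits
  truth2 <- make_nb_truth(25, 1, seed = 22, lib_size = 600)
  rates2 <- cbind(t1 = truth2$rates[, 1], t2 = truth2$rates[, 1])
  truth2 <- nb_ground_truth(rates2, truth2$probs, lib_size = 600)
  sim2 <- generate_nb_sc(truth2, cells_per_type = 150, seed = 23)
  fit <- fit_sc(sim2$counts, sim2$annotation, fit_config(epochs = 800, seed = 24))
  logratio <- log(fit$rates[, 1] / fit$rates[, 2])
  expect_lt(median(abs(logratio)), 0.25)
  expect_gt(stats::t.test(logratio)$p.value, 0.01)
})
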