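kl_result <- function(H_rows, m) {
  H <- do.call(rbind, H_rows)
  result_from_matrices(matrix(0.5, m, 4),
                       list(a = matrix(0, m, 4), b = matrix(0, m, 4)),
                       list(a = H, b = H[1, , drop = FALSE]))
}

test_that("per-sample KL divergence matches closed forms", {
  m <- 4
  res <- kl_result(list(rep(1, m), c(1, 0, 0, 0), c(0.5, 0.5, 0, 0),
                        rep(0, m)), m)
  kl <- sample_kl_divergences(res)
  expect_equal(kl[1], 0)                 # uniform loadings
  expect_equal(kl[2], log(4))            # one-hot
  expect_equal(kl[3], log(2))            # two equal factors of four
  expect_equal(kl[4], 0)                 # zero row treated as uniform
  # one-hot at m = 100
  res100 <- result_from_matrices(
    matrix(0.5, 100, 4),
    list(a = matrix(0, 100, 4), b = matrix(0, 100, 4)),
    list(a = matrix(c(1, rep(0, 99)), 1, 100), b = matrix(1 / 100, 1, 100)))
  expect_equal(sample_kl_divergences(res100), c(log(100), 0))
})

test_that("KL values stay within [0, log m] on random loadings", {
  set.seed(5)
  H <- matrix(runif(200), 40, 5)
  res <- result_from_matrices(matrix(1, 5, 4),
                              list(a = matrix(0, 5, 4), b = matrix(0, 5, 4)),
                              list(a = H, b = H))
  kl <- sample_kl_divergences(res)
  expect_true(all(kl >= 0 & kl <= log(5)))
})

test_that("saturation rule picks the smallest m within (1-eps) of the max", {
  curve <- data.frame(m = c(20L, 40L, 60L, 80L, 100L),
                      median_kl = c(0.5, 2.0, 2.8, 2.9, 2.95))
  expect_identical(select_saturation(curve, epsilon = 0.05), 80L)
  expect_identical(select_saturation(data.frame(m = 1:3, median_kl = rep(2, 3))),
                   1L)
  inc <- data.frame(m = c(5L, 10L, 15L), median_kl = c(1, 2, 3))
  expect_identical(select_saturation(inc, epsilon = 0), 15L)
  expect_warning(out <- select_saturation(
    data.frame(m = c(2L, 4L), median_kl = c(0, 0))), "all-zero")
  expect_identical(out, 2L)
  # monotone in epsilon: larger slack never selects a larger m
  eps <- seq(0, 0.9, by = 0.1)
  sel <- vapply(eps, function(e) select_saturation(curve, e), integer(1))
  expect_true(all(diff(sel) <= 0))
  expect_true(all(sel %in% curve$m))
})

test_that("KL curve saturates near the planted factor number", {
  sim <- generate_planted_collection(synthetic_config(
    k = 2, n_per_dataset = 40, g = 60, m = 6, n_shared_factors = 2,
    n_specific_factors = 2, shared_module_size = 10,
    specific_module_size = 10, noise = "none", seed = 8))
  curve <- kl_selection_curve(sim$collection, m_values = c(1L, 2L, 4L, 8L),
                              lambda1 = 1, lambda2 = 1, seed = 8,
                              max_iter = 30)
  expect_equal(curve$median_kl[1], 0)            # m = 1 is always uniform
  expect_gt(curve$median_kl[3], curve$median_kl[2])
  # beyond the per-dataset factor count the curve flattens
  expect_lt(curve$median_kl[4] - curve$median_kl[3],
            curve$median_kl[3] - curve$median_kl[2])
})

test_that("alignment score hits its analytic endpoints and clips", {
  expect_equal(alignment_score(xbar = 10 / 2, k_nn = 10, k = 2), 1)
  expect_equal(alignment_score(xbar = 10, k_nn = 10, k = 2), 0)
  expect_equal(alignment_score(xbar = 3, k_nn = 10, k = 2), 1)  # clipped
  expect_equal(alignment_score(xbar = 7.5, k_nn = 10, k = 2), 0.5)
})

test_that("alignment metric separates mixed from disjoint loading spaces", {
  set.seed(3)
  Hs <- matrix(runif(80 * 4), 80, 4)
  mixed <- result_from_matrices(matrix(1, 4, 6),
                                list(a = matrix(0, 4, 6), b = matrix(0, 4, 6)),
                                list(a = Hs, b = Hs))
  expect_gte(alignment_metric(mixed, seed = 1), 0.8)

  H1 <- cbind(matrix(runif(80 * 2), 80, 2), matrix(0, 80, 2))
  H2 <- cbind(matrix(0, 80, 2), matrix(runif(80 * 2), 80, 2))
  disjoint <- result_from_matrices(matrix(1, 4, 6),
                                   list(a = matrix(0, 4, 6),
                                        b = matrix(0, 4, 6)),
                                   list(a = H1, b = H2))
  expect_lte(alignment_metric(disjoint, seed = 1), 0.1)
  # invariant to dataset order and to a common permutation of the factors
  disjoint_sw <- result_from_matrices(matrix(1, 4, 6),
                                      list(b = matrix(0, 4, 6),
                                           a = matrix(0, 4, 6)),
                                      list(b = H2, a = H1))
  expect_equal(alignment_metric(disjoint_sw, seed = 1),
               alignment_metric(disjoint, seed = 1))
  perm <- c(3, 1, 4, 2)
  disjoint_p <- result_from_matrices(matrix(1, 4, 6),
                                     list(a = matrix(0, 4, 6),
                                          b = matrix(0, 4, 6)),
                                     list(a = H1[, perm], b = H2[, perm]))
  expect_equal(alignment_metric(disjoint_p, seed = 1),
               alignment_metric(disjoint, seed = 1))
  expect_error(alignment_metric(mixed, k_nn = 1000, seed = 1), "k_nn")
})

test_that("reconstruction MSE matches its per-dataset formula", {
  coll <- expression_collection(list(
    expression_dataset(matrix(2, 1, 1), "s1", "gA", "d1"),
    expression_dataset(matrix(3, 1, 1), "s2", "gA", "d2")))
  # dataset 1 reconstructed as 1.5 (error 0.25), dataset 2 exactly
  res <- result_from_matrices(matrix(1, 1, 1),
                              list(d1 = matrix(0.5, 1, 1),
                                   d2 = matrix(2, 1, 1)),
                              list(d1 = matrix(1, 1, 1),
                                   d2 = matrix(1, 1, 1)))
  expect_equal(reconstruction_mse(coll, res), 0.25)
  # an exactly reconstructed dataset adds nothing
  sim <- generate_planted_collection(synthetic_config(
    k = 2, n_per_dataset = 10, g = 20, m = 4, n_shared_factors = 2,
    n_specific_factors = 1, shared_module_size = 5, specific_module_size = 5,
    noise = "none", seed = 2))
  expect_equal(reconstruction_mse(sim$collection, result_from_truth(sim$truth)),
               0)
})

test_that("lambda grid search returns a ranked table and breaks ties small", {
  coll <- make_random_collection(k = 2, n = 14, g = 10, seed = 17)
  one <- lambda_grid_search(coll, m = 2, lambda_values = 1, seed = 17,
                            max_iter = 15, k_nn = 5)
  expect_equal(nrow(one$table), 1L)
  expect_equal(unname(one$best), c(1, 1))

  grid <- lambda_grid_search(coll, m = 2, lambda_values = c(0.1, 10),
                             seed = 17, max_iter = 15, k_nn = 5)
  expect_equal(nrow(grid$table), 4L)
  ok <- grid$table[!grid$table$failed, ]
  expect_equal(unname(grid$best[["lambda1"]]),
               ok$lambda1[which.min(ok$alignment)])
  expect_true(all(diff(ok$alignment) >= 0))
})
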