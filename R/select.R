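# Model selection: number of factors m via the KL-divergence saturation
# curve of per-sample loading distributions, and the regularization pair
# (lambda1, lambda2) via a grid search minimizing the kNN alignment metric.

#' Per-sample KL divergence of factor loadings from uniform
#'
#' Each row of each `H_i` is normalized to a probability vector `p` over the
#' `m` factors and its Kullback-Leibler divergence from the uniform
#' distribution, `KL = log(m) + sum(p * log(p))` in nats, is returned. Rows
#' summing to zero get KL 0 (treated as uniform). When `m` is far below the
#' true number of modules, samples load diffusely and KL is small; near the
#' true number each sample loads on few factors and KL saturates.
#'
#' @param result An `irnmf_result`.
#' @return Numeric vector, one value per sample across all datasets, in
#'   `[0, log(m)]`.
#' @export
sample_kl_divergences <- function(result) {
  m <- nrow(result$W)
  unlist(lapply(result$H, function(H) {
    if (min(H) < 0) stopf("negative loadings in H")
    apply(H, 1L, function(row) {
      s <- sum(row)
      if (s == 0) return(0)
      p <- row / s
      p <- p[p > 0]
      log(m) + sum(p * log(p))
    })
  }), use.names = FALSE)
}

#' KL saturation curve over a grid of factor numbers
#'
#' Fits the factorization for each candidate `m` (shared seed and penalties,
#' so curves differ only through `m`) and records the median per-sample KL
#' divergence. A failed fit yields `NA` for that `m` with a warning.
#'
#' @param collection An [expression_collection].
#' @param m_values Increasing positive integers to try.
#' @param lambda1,lambda2,seed,tol,max_iter Passed to [fit_irnmf()].
#' @return Data frame of class `kl_curve` with columns `m`, `median_kl`.
#' @seealso [select_saturation()]
#' @export
kl_selection_curve <- function(collection, m_values, lambda1 = 1,
                               lambda2 = 10, seed = 1L, tol = 1e-5,
                               max_iter = 50L) {
  if (!length(m_values)) stopf("m_values must be non-empty")
  med <- vapply(m_values, function(m) {
    fit <- tryCatch(
      fit_irnmf(collection, m = m, lambda1 = lambda1, lambda2 = lambda2,
                tol = tol, max_iter = max_iter, seed = seed),
      error = function(e) {
        warning(sprintf("fit failed at m = %d: %s", m, conditionMessage(e)),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) NA_real_ else stats::median(sample_kl_divergences(fit))
  }, numeric(1L))
  structure(data.frame(m = as.integer(m_values), median_kl = med),
            class = c("kl_curve", "data.frame"))
}

#' Select the saturation point of a KL curve
#'
#' Returns the smallest `m` whose median KL reaches `(1 - epsilon)` times the
#' curve maximum — an explicit, reproducible reading of "the saturation point
#' of the curve". The curve itself should always be inspected alongside.
#'
#' @param curve A [kl_selection_curve()] result (columns `m`, `median_kl`).
#' @param epsilon Saturation slack in `(0, 1)`; larger values select smaller
#'   `m`. Default 0.05.
#' @return The selected `m` (an element of `curve$m`).
#' @export
select_saturation <- function(curve, epsilon = 0.05) {
  ok <- is.finite(curve$median_kl)
  if (!any(ok)) stopf("no finite KL values in curve")
  m <- curve$m[ok]
  kl <- curve$median_kl[ok]
  if (max(kl) == 0) {
    warning("all-zero KL curve; returning smallest m", call. = FALSE)
    return(min(m))
  }
  thr <- (1 - epsilon) * max(kl)
  min(m[kl >= thr])
}

#' Alignment score from a mean same-dataset neighbor count
#'
#' The analytic core of [alignment_metric()]:
#' `1 - (xbar - k_nn/k) / (k_nn - k_nn/k)`, clipped to `[0, 1]`. `xbar =
#' k_nn/k` (perfect mixing expectation) gives 1; `xbar = k_nn` (every
#' neighbor from the point's own dataset) gives 0.
#'
#' @param xbar Mean number of same-dataset neighbors among the `k_nn`
#'   nearest neighbors.
#' @param k_nn Number of neighbors used.
#' @param k Number of datasets.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_score <- function(xbar, k_nn, k) {
  raw <- 1 - (xbar - k_nn / k) / (k_nn - k_nn / k)
  min(1, max(0, raw))
}

#' kNN alignment metric of the joint loading space
#'
#' Measures how uniformly samples from the `k` datasets mix in the shared
#' low-dimensional space: `min_i n_i` samples are drawn from each dataset,
#' rows of the concatenated loadings are L2-normalized, and for each sampled
#' point the fraction of same-dataset points among its `k_nn` Euclidean
#' nearest neighbors is averaged into [alignment_score()]. High values mean
#' the datasets share populations; datasets of genuinely different cell
#' types should score low, which is why regularization is chosen at the
#' *minimum* alignment in [lambda_grid_search()].
#'
#' @param result An `irnmf_result` with `k >= 2` datasets.
#' @param k_nn Neighbor count, or `"auto"` for
#'   `max(10, floor(0.01 * N_sampled))`.
#' @param seed Seed for the per-dataset subsampling.
#' @return Scalar in `[0, 1]`.
#' @export
alignment_metric <- function(result, k_nn = "auto", seed = 1L) {
  k <- length(result$H)
  if (k < 2L) stopf("alignment metric needs >= 2 datasets")
  ns <- vapply(result$H, nrow, integer(1L))
  n_min <- min(ns)
  rows <- with_seed(seed, lapply(result$H, function(H) {
    H[sort(sample.int(nrow(H), n_min)), , drop = FALSE]
  }))
  M <- do.call(rbind, rows)
  origin <- rep(seq_len(k), each = n_min)
  norms <- sqrt(rowSums(M^2))
  norms[norms == 0] <- 1
  M <- M / norms
  N <- nrow(M)
  if (identical(k_nn, "auto")) k_nn <- max(10L, floor(0.01 * N))
  if (k_nn >= N) stopf("k_nn (%d) must be smaller than the %d sampled points",
                       k_nn, N)
  D <- as.matrix(stats::dist(M))
  diag(D) <- Inf
  same <- vapply(seq_len(N), function(i) {
    nb <- order(D[i, ])[seq_len(k_nn)]
    sum(origin[nb] == origin[i])
  }, numeric(1L))
  alignment_score(mean(same), k_nn, k)
}

#' Summed per-dataset mean squared reconstruction error
#'
#' `sum_i ||X_i - H_i(W + V_i)||_F^2 / (n_i * g)` — the sum over datasets of
#' per-entry mean squared errors, used as an auxiliary diagnostic next to
#' the KL curve.
#'
#' @inheritParams evaluate_objective
#' @return Non-negative scalar, 0 iff every dataset is reconstructed exactly.
#' @export
reconstruction_mse <- function(collection, result) {
  check_result_dims(collection, result)
  g <- length(collection$gene_names)
  total <- 0
  for (i in seq_along(collection$datasets)) {
    X <- collection$datasets[[i]]$values
    total <- total + sq_frob(X - reconstruct(result, i)) / (nrow(X) * g)
  }
  total
}

#' Grid search for the regularization pair
#'
#' Fits the factorization for every `(lambda1, lambda2)` pair on the grid
#' (all fits share the same seed, so differences reflect the penalties, not
#' initialization), and reports alignment, MSE and the final objective per
#' pair. The selected pair minimizes the alignment metric; ties are broken
#' toward smaller `lambda1`, then smaller `lambda2`. A failed fit is marked
#' in the table and skipped in the ranking.
#'
#' @param collection An [expression_collection].
#' @param m Number of factors.
#' @param lambda_values Candidate penalty values; the default grid is
#'   `c(0.01, 0.1, 1, 10, 100)` for both penalties.
#' @param seed,tol,max_iter Passed to [fit_irnmf()].
#' @param k_nn Passed to [alignment_metric()].
#' @return List of class `lambda_grid` with `table` (one row per pair:
#'   `lambda1`, `lambda2`, `alignment`, `mse`, `objective`, `failed`) and
#'   `best` (named vector `lambda1`, `lambda2`).
#' @export
lambda_grid_search <- function(collection, m,
                               lambda_values = c(0.01, 0.1, 1, 10, 100),
                               seed = 1L, tol = 1e-5, max_iter = 50L,
                               k_nn = "auto") {
  if (!length(lambda_values)) stopf("lambda_values must be non-empty")
  grid <- expand.grid(lambda1 = lambda_values, lambda2 = lambda_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    l1 <- grid$lambda1[r]
    l2 <- grid$lambda2[r]
    fit <- tryCatch(
      fit_irnmf(collection, m = m, lambda1 = l1, lambda2 = l2, tol = tol,
                max_iter = max_iter, seed = seed),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(lambda1 = l1, lambda2 = l2, alignment = NA_real_,
                 mse = NA_real_, objective = NA_real_, failed = TRUE)
    } else {
      data.frame(lambda1 = l1, lambda2 = l2,
                 alignment = alignment_metric(fit, k_nn = k_nn, seed = seed),
                 mse = reconstruction_mse(collection, fit),
                 objective = utils::tail(fit$objective_trace, 1L),
                 failed = FALSE)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- tab[!tab$failed, , drop = FALSE]
  if (!nrow(ok)) stopf("every fit in the lambda grid failed")
  ord <- order(ok$alignment, ok$lambda1, ok$lambda2)
  best <- ok[ord[1L], ]
  structure(list(table = tab[order(tab$alignment, tab$lambda1, tab$lambda2), ],
                 best = c(lambda1 = best$lambda1, lambda2 = best$lambda2)),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("lambda grid search: best (lambda1 = %g, lambda2 = %g)\n",
              x$best[["lambda1"]], x$best[["lambda2"]]))
  print(utils::head(x$table, 10L), row.names = FALSE)
  invisible(x)
}
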