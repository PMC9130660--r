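# Independent oracles and fixture builders used across the test files.

# Exhaustive active-set NNLS oracle: tries every passive-set pattern,
# solves the unconstrained least squares on it, keeps the best feasible
# candidate. Exact for q <= ~12 variables; independent of the pivoting path.
brute_nnls <- function(A, b) {
  q <- ncol(A)
  best <- rep(0, q)
  best_obj <- sum(b^2)
  for (code in seq_len(2^q) - 1L) {
    f <- as.logical(bitwAnd(code, 2^(seq_len(q) - 1L)) > 0)
    if (!any(f)) next
    Af <- A[, f, drop = FALSE]
    G <- crossprod(Af)
    if (rcond(G) < 1e-12) next
    xf <- solve(G, crossprod(Af, b))
    if (any(xf < -1e-9)) next
    x <- rep(0, q)
    x[f] <- pmax(xf, 0)
    obj <- sum((A %*% x - b)^2)
    if (obj < best_obj - 1e-12) {
      best_obj <- obj
      best <- x
    }
  }
  best
}

# Exact hypergeometric upper tail by direct enumeration over binomial
# coefficients (exact in double precision for N <= ~50).
exact_hyper_tail <- function(N, K, n, x) {
  hi <- min(K, n)
  if (x > hi) return(0)
  i <- x:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All permutations of a small vector (assignment brute force).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(all_perms(v[-i]), function(p) c(v[i], p))))
}

# Random non-negative collection of k datasets.
make_random_collection <- function(k = 2, n = 12, g = 15, seed = 1) {
  set.seed(seed)
  ds <- lapply(seq_len(k), function(i)
    expression_dataset(matrix(runif(n * g), n, g),
                       sprintf("d%d_s%02d", i, seq_len(n)),
                       sprintf("g%03d", seq_len(g)),
                       paste0("d", i)))
  expression_collection(ds)
}

# Wrap given factor matrices as an irnmf_result (for metric tests that do
# not need a fit).
result_from_matrices <- function(W, V, H, lambda1 = 0, lambda2 = 0) {
  cfg <- irnmf_config(nrow(W), lambda1, lambda2)
  structure(list(W = W, V = V, H = H, objective_trace = numeric(0),
                 config = cfg, converged = TRUE, n_sweeps = 0L, log = list()),
            class = "irnmf_result")
}

# The planted truth expressed as an irnmf_result.
result_from_truth <- function(truth, lambda1 = 0, lambda2 = 0) {
  result_from_matrices(truth$W, truth$V, truth$H, lambda1, lambda2)
}

# Independently coded iNMF objective (no shared-contribution penalty):
# deliberately written with explicit loops and norm(), unlike the package's
# crossprod-based implementation.
inmf_objective_reference <- function(collection, result, lambda1) {
  total <- 0
  for (i in seq_along(collection$datasets)) {
    X <- collection$datasets[[i]]$values
    H <- result$H[[i]]
    r <- X - H %*% (result$W + result$V[[i]])
    total <- total + norm(r, "F")^2 + lambda1 * norm(H %*% result$V[[i]], "F")^2
  }
  total
}

# Hand-built enrichment table row block for the specificity-logic tests.
fake_ora_table <- function(module, terms, sig) {
  data.frame(module = module, term_id = terms,
             term_name = paste0("name_", terms),
             term_size = 15L, module_size = 30L, overlap = 5L,
             raw_p = seq(0.001, 0.05, length.out = length(terms)),
             q = seq(0.002, 0.08, length.out = length(terms)),
             significant = sig, stringsAsFactors = FALSE)
}
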