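#' Non-negative least squares via block principal pivoting
#'
#' Solves `argmin_{X >= 0} || design %*% X - targets ||_F^2` for every column
#' of `targets` simultaneously, using block principal pivoting on the KKT
#' system: index sets are exchanged in full while the number of infeasible
#' variables keeps shrinking, and a backup rule that exchanges only the
#' largest infeasible index bounds the number of full exchanges once cycling
#' is suspected, which guarantees termination at the exact KKT point.
#'
#' Columns with identical passive sets share one Cholesky solve, which makes
#' the solver fast for the many-right-hand-side subproblems of [fit_irnmf()].
#'
#' @param design `p x q` matrix with full column rank (near-singular principal
#'   subsystems are stabilised with a tiny ridge on the Gram matrix).
#' @param targets `p x r` matrix (a vector is treated as one column).
#' @param tol KKT feasibility tolerance, relative to the problem scale.
#' @param max_cycles Safety cap on pivoting rounds; exceeding it is an error
#'   reporting the worst KKT violation.
#' @return `q x r` non-negative matrix.
#' @examples
#' A <- rbind(c(1, 0), c(0, 1), c(1, 1))
#' nnls_bpp(A, c(1, 1, 0))  # both coordinates 1/3
#' @references Kim & Park (2011), SIAM J. Sci. Comput. 33(6):3261-3281.
#' @export
nnls_bpp <- function(design, targets, tol = 1e-12, max_cycles = NULL) {
  design <- as.matrix(design)
  targets <- as.matrix(targets)
  if (!all(is.finite(design)) || !all(is.finite(targets)))
    stopf("nnls_bpp: non-finite entries in design or targets")
  if (nrow(design) != nrow(targets))
    stopf("nnls_bpp: design has %d rows, targets %d", nrow(design), nrow(targets))
  nnls_bpp_gram(crossprod(design), crossprod(design, targets),
                tol = tol, max_cycles = max_cycles)
}

# Gram-form kernel: minimizes x' AtA x / 2 - x' Atb columnwise, x >= 0.
# Used directly by the BCD updates, which assemble AtA and AtB without
# materializing stacked designs.
nnls_bpp_gram <- function(AtA, AtB, tol = 1e-12, max_cycles = NULL,
                          ridge = 1e-12) {
  q <- ncol(AtA)
  AtB <- as.matrix(AtB)
  r <- ncol(AtB)
  if (is.null(max_cycles)) max_cycles <- 20L * (q + 10L)
  scale <- max(abs(AtB), abs(AtA), 1)
  thresh <- tol * scale

  X <- matrix(0, q, r)
  Y <- -AtB                      # gradient AtA X - AtB at X = 0
  passive <- matrix(FALSE, q, r)
  backup <- rep(3L, r)           # remaining full exchanges before backup rule
  lowest <- rep(q + 1L, r)       # fewest infeasibilities seen per column

  # Solve G x = b for a principal Gram submatrix. Fast path: Cholesky with a
  # tiny ridge. Near rank deficiency (dead factors give Gram eigenvalues at
  # rounding level) the Cholesky solution can explode along the null space,
  # so fall back to the minimal-norm solution via truncated eigendecomposition.
  chol_solve <- function(G, B) {
    Gr <- G + diag(max(ridge * max(diag(G)), ridge), nrow(G))
    R <- tryCatch(chol(Gr), error = function(e) NULL)
    if (!is.null(R)) {
      piv <- diag(R)
      if (min(piv) > 1e-7 * max(piv))
        return(backsolve(R, backsolve(R, B, transpose = TRUE)))
    }
    e <- eigen(G, symmetric = TRUE)
    keep <- e$values > 1e-12 * max(e$values, ridge)
    if (!any(keep)) return(matrix(0, nrow(G), ncol(as.matrix(B))))
    U <- e$vectors[, keep, drop = FALSE]
    U %*% (crossprod(U, as.matrix(B)) / e$values[keep])
  }

  refresh <- function(cols) {
    pat <- apply(passive[, cols, drop = FALSE], 2L,
                 function(z) paste(which(z), collapse = ","))
    for (p in unique(pat)) {
      J <- cols[pat == p]
      f <- passive[, J[1L]]
      if (!any(f)) {
        X[, J] <<- 0
        Y[, J] <<- -AtB[, J, drop = FALSE]
        next
      }
      sol <- chol_solve(AtA[f, f, drop = FALSE], AtB[f, J, drop = FALSE])
      Xn <- matrix(0, q, length(J))
      Yn <- matrix(0, q, length(J))
      Xn[f, ] <- sol
      if (any(!f))
        Yn[!f, ] <- AtA[!f, f, drop = FALSE] %*% sol - AtB[!f, J, drop = FALSE]
      X[, J] <<- Xn
      Y[, J] <<- Yn
    }
  }

  refresh(seq_len(r))
  for (cycle in seq_len(max_cycles)) {
    infeas <- (passive & (X < -thresh)) | (!passive & (Y < -thresh))
    n_bad <- colSums(infeas)
    bad <- which(n_bad > 0L)
    if (!length(bad)) {
      X[X < 0] <- 0
      return(X)
    }
    for (j in bad) {
      if (n_bad[j] < lowest[j]) {        # progress: full exchange, reset
        lowest[j] <- n_bad[j]
        backup[j] <- 3L
        flip <- which(infeas[, j])
      } else if (backup[j] > 0L) {       # allow a few non-improving full swaps
        backup[j] <- backup[j] - 1L
        flip <- which(infeas[, j])
      } else {                           # backup rule: single largest index
        flip <- max(which(infeas[, j]))
      }
      passive[flip, j] <- !passive[flip, j]
    }
    refresh(bad)
  }
  worst <- max(pmax(ifelse(passive, -X, -Y), 0))
  stopf("nnls_bpp did not converge in %d cycles; worst KKT violation %.3e",
        max_cycles, worst)
}
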