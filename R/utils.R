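# Internal helpers shared across modules.

# Deterministic derivation of sub-seeds so that block order / replicate order
# never changes results. Kept below .Machine$integer.max.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 1009) %% 2147483647L)
}

# Smallest eigenvalue of a symmetric matrix.
lambda_min <- function(A) {
  min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
}

check_symmetric <- function(A, tol = 1e-8, arg = "matrix") {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (max(abs(A - t(A))) > tol) {
    abort(sprintf("`%s` must be symmetric (max asymmetry > %g).", arg, tol))
  }
  invisible(A)
}

# Solve Sigma^{-1} B with a ridge fallback for ill-conditioned LD.
solve_ridge <- function(Sigma, B = diag(nrow(Sigma)), ridge = 1e-10,
                        cond_max = 1e12) {
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  kap <- max(ev) / max(min(ev), .Machine$double.eps)
  if (!is.finite(kap) || kap > cond_max || min(ev) <= 0) {
    Sigma <- Sigma + ridge * diag(nrow(Sigma))
  }
  solve(Sigma, B)
}
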