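#' Solve for the knockoff decoupling diagonal s
#'
#' The diagonal matrix `D = diag(s)` controls how much each knockoff copy is
#' decoupled from its original variant, subject to the multiple-knockoff
#' feasibility constraint `((M + 1) / M) * Sigma - D >= 0` (PSD) and
#' `s_j >= 0`. Two solvers are provided:
#'
#' * `equi`: the equicorrelated closed form
#'   `s_j = min(1, ((M + 1) / M) * lambda_min(Sigma))`, the scalable default.
#' * `sdp`: coordinate ascent on `sum(s)` with `s_j <= 1`, using
#'   Schur-complement caps; equivalent to minimizing `sum(|1 - s_j|)` subject
#'   to the same PSD constraint. Exact for small blocks, O(p^3) per coordinate.
#'
#' @param Sigma An [ld_matrix()] (or PSD correlation matrix).
#' @param M Number of knockoff copies per variant, `>= 1`.
#' @param method `"equi"` (default) or `"sdp"`.
#' @param tol Convergence tolerance for the `sdp` coordinate ascent.
#' @return Nonnegative numeric vector `s` of length `p`.
#' @export
solve_s <- function(Sigma, M = 5, method = c("equi", "sdp"), tol = 1e-8) {
  method <- match.arg(method)
  check_symmetric(unclass(Sigma), arg = "Sigma")
  if (M < 1 || M != round(M)) abort("`M` must be a positive integer.")
  lmin <- lambda_min(unclass(Sigma))
  if (lmin < -1e-8) {
    abort("`Sigma` is not PSD; run psd_repair() before solving for s.")
  }
  p <- nrow(Sigma)
  cM <- (M + 1) / M
  if (method == "equi") {
    return(rep(min(1, cM * max(lmin, 0)), p))
  }
  sdp_s(unclass(Sigma), cM, tol = tol)
}

# Interior-point solver for the SDP: maximize sum(s) subject to
# 0 <= s <= 1 and A(s) = cM * Sigma - diag(s) PSD (restricting s <= 1 is
# without loss for the |1 - s| objective). Log-barrier with damped Newton;
# the barrier gradient/Hessian of log det A(s) are -diag(A^-1) and
# -(A^-1 o A^-1), so each Newton step is a p x p solve.
sdp_s <- function(Sigma, cM, tol = 1e-8) {
  p <- nrow(Sigma)
  lmin <- lambda_min(cM * Sigma)
  if (lmin <= 0) abort("Sigma must be strictly PD for the sdp solver.")
  s <- rep(min(0.5, 0.5 * lmin), p)   # strictly interior start
  mu <- 0.1
  obj <- function(s, mu) {
    A <- cM * Sigma - diag(s, p)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch) || any(s <= 0) || any(s >= 1)) return(-Inf)
    sum(s) + mu * (2 * sum(log(diag(ch))) + sum(log(s)) + sum(log(1 - s)))
  }
  while (mu > 1e-10) {
    for (iter in 1:50) {
      A <- cM * Sigma - diag(s, p)
      Ainv <- chol2inv(chol(A))
      g <- 1 - mu * diag(Ainv) + mu / s - mu / (1 - s)
      H <- mu * (Ainv * Ainv) + diag(mu / s^2 + mu / (1 - s)^2, p)
      d <- tryCatch(solve(H, g), error = function(e) g / diag(H))
      if (max(abs(g)) < 1e-10 + mu * 1e-4) break
      f0 <- obj(s, mu)
      t <- 1
      while (t > 1e-12 && obj(s + t * d, mu) < f0 + 1e-4 * t * sum(g * d)) {
        t <- t / 2
      }
      if (t <= 1e-12) break
      s <- s + t * d
    }
    mu <- mu / 5
  }
  pmin(pmax(s, 0), 1)
}

#' Build a per-block knockoff model
#'
#' Assembles, from a block LD matrix `Sigma`, everything needed to sample
#' knockoff Z-scores for the block:
#' the projection `P1 = I - D Sigma^{-1}` (the `pM x p` projection `P` is `M`
#' stacked copies of `P1`), and a factor of the `pM x pM` noise covariance `V`
#' with diagonal blocks `C = 2D - D Sigma^{-1} D` and off-diagonal blocks
#' `C - D`. The factorization exploits the exchangeable block structure:
#' `V = (Q kron I) blockdiag(B, D, ..., D) (Q' kron I)` with
#' `B = D + M (C - D)` and `Q` orthogonal with first column `1/sqrt(M)`,
#' so only p x p eigendecompositions are required. Eigenvalues of the blocks
#' are clipped at `psd_floor` before taking square roots; clipping beyond
#' 1e-6 (a genuinely indefinite block, usually from mismatched LD) raises a
#' warning.
#'
#' @inheritParams solve_s
#' @param s Optional precomputed decoupling vector; solved via [solve_s()]
#'   when `NULL`.
#' @param psd_floor Eigenvalue floor used when factoring the noise covariance.
#' @return An object of class `knockoff_model` with elements `variants`, `M`,
#'   `s`, `method`, `P1`, `C`, `F1` (factor of `B`), `sqrt_s`, `Q`, `p`,
#'   `lambda_min`, `shrinkage`.
#' @seealso [sample_knockoff_z()], [knockoff_P()], [knockoff_V()]
#' @export
knockoff_model <- function(Sigma, M = 5, method = c("equi", "sdp"), s = NULL,
                           psd_floor = 1e-10) {
  method <- match.arg(method)
  variants <- attr(Sigma, "variants") %||% colnames(Sigma) %||%
    paste0("v", seq_len(nrow(Sigma)))
  Sig <- unclass(Sigma)
  p <- nrow(Sig)
  if (is.null(s)) s <- solve_s(Sigma, M = M, method = method)
  if (length(s) != p || any(s < 0)) abort("`s` must be nonnegative, length p.")
  lmin <- lambda_min(Sig)
  if (lmin <= 0 && lmin > -1e-8) {
    # repaired-but-singular LD: ridge keeps the solve well defined
    Sinv <- solve_ridge(Sig)
  } else if (lmin <= -1e-8) {
    abort("`Sigma` is not PSD; run psd_repair() (or increase shrinkage).")
  } else {
    Sinv <- solve_ridge(Sig)
  }
  DSinv <- s * Sinv                     # D Sigma^{-1}
  P1 <- diag(p) - DSinv
  C <- diag(2 * s, p) - DSinv %*% diag(s, p)   # 2D - D Sigma^{-1} D
  C <- (C + t(C)) / 2
  B <- diag(s, p) + M * (C - diag(s, p))
  ev <- eigen(B, symmetric = TRUE)
  clip <- -min(ev$values, 0)
  if (clip > 1e-6) {
    warn(sprintf(
      "noise covariance clipped by %.2g (> 1e-6); check LD repair/shrinkage",
      clip
    ))
  }
  F1 <- ev$vectors %*% diag(sqrt(pmax(ev$values, psd_floor)), p)
  # Orthogonal Q with first column 1/sqrt(M) * 1
  H <- diag(M)
  H[, 1] <- 1
  Q <- qr.Q(qr(H))
  if (Q[1, 1] < 0) Q[, 1] <- -Q[, 1]
  structure(
    list(
      variants = variants, M = as.integer(M), s = s, method = method,
      P1 = P1, C = C, F1 = F1, sqrt_s = sqrt(pmax(s, 0)), Q = Q, p = p,
      lambda_min = lmin, psd_floor = psd_floor,
      shrinkage = attr(Sigma, "shrinkage") %||% NA_real_
    ),
    class = "knockoff_model"
  )
}

#' @export
print.knockoff_model <- function(x, ...) {
  cat(sprintf(
    "<knockoff_model> p = %d, M = %d, method = %s, mean(s) = %.3f\n",
    x$p, x$M, x$method, mean(x$s)
  ))
  invisible(x)
}

#' @rdname knockoff_model
#' @param x A `knockoff_model`.
#' @param ... Unused.
#' @export
tidy.knockoff_model <- function(x, ...) {
  tibble(variant = x$variants, s = x$s)
}

#' @rdname knockoff_model
#' @export
glance.knockoff_model <- function(x, ...) {
  tibble(
    p = x$p, M = x$M, method = x$method,
    mean_s = mean(x$s), lambda_min = x$lambda_min,
    shrinkage = x$shrinkage
  )
}

#' Full projection and noise covariance matrices
#'
#' Materialize the `pM x p` projection `P` (stacked copies of
#' `I - D Sigma^{-1}`) and the dense `pM x pM` noise covariance `V` implied by
#' a knockoff model. Mostly useful for checking the model invariants; sampling
#' uses the structured factor instead.
#'
#' @param model A [knockoff_model()].
#' @return A matrix.
#' @export
knockoff_P <- function(model) {
  do.call(rbind, replicate(model$M, model$P1, simplify = FALSE))
}

#' @rdname knockoff_P
#' @export
knockoff_V <- function(model) {
  p <- model$p
  M <- model$M
  D <- diag(model$s, p)
  V <- matrix(0, p * M, p * M)
  for (a in seq_len(M)) {
    for (b in seq_len(M)) {
      blk <- if (a == b) model$C else model$C - D
      V[(a - 1) * p + seq_len(p), (b - 1) * p + seq_len(p)] <- blk
    }
  }
  V
}

#' Sample knockoff Z-scores for one block
#'
#' Draws `z_knock = P1 z + gamma * E` for each of the `M` knockoff copies,
#' where the noise `E` has covariance `V` (exchangeable block structure) and
#' `gamma >= 1` is the meta-analysis dependency factor (1 for a single study
#' or independent studies). Sampling is fully determined by `seed`.
#'
#' @param model A [knockoff_model()].
#' @param z Numeric vector of original Z-scores, length `p`.
#' @param gamma Dependency factor, `>= 1`.
#' @param seed Integer seed; identical seed and inputs reproduce the draw
#'   bit for bit.
#' @return An object of class `knockoff_z`: list with `z` (length p),
#'   `z_knock` (p x M matrix) and `seed`.
#' @export
sample_knockoff_z <- function(model, z, gamma = 1, seed) {
  if (length(z) != model$p) abort("length(z) must equal the model's p.")
  if (any(!is.finite(z))) abort("`z` must be finite.")
  if (gamma < 1) abort("`gamma` must be >= 1 (dependency factor cannot shrink noise).")
  if (missing(seed)) abort("`seed` is required for reproducible sampling.")
  E <- withr::with_seed(as.integer(seed), draw_noise(model))
  z_knock <- matrix(drop(model$P1 %*% z), model$p, model$M) + gamma * E
  structure(
    list(z = z, z_knock = z_knock, seed = as.integer(seed)),
    class = "knockoff_z"
  )
}

# One draw of the pM noise with covariance V, returned as a p x M matrix
# (columns are knockoff copies). Uses the structured factor.
draw_noise <- function(model) {
  p <- model$p
  M <- model$M
  eps <- matrix(rnorm(p * M), p, M)
  E0 <- matrix(0, p, M)
  E0[, 1] <- model$F1 %*% eps[, 1]
  if (M > 1) E0[, -1] <- model$sqrt_s * eps[, -1, drop = FALSE]
  E0 %*% t(model$Q)
}

#' @export
print.knockoff_z <- function(x, ...) {
  cat(sprintf(
    "<knockoff_z> p = %d, M = %d, seed = %d\n",
    length(x$z), ncol(x$z_knock), x$seed
  ))
  invisible(x)
}

#' Write / read a knockoff model cache
#'
#' One serialized container per block, keyed by block id, holding the fields
#' needed to regenerate knockoff Z-scores (`variants`, `s`, projection, noise
#' factor, `M`, method, shrinkage). Round-trips are bit-exact.
#'
#' @param models Named list of [knockoff_model()] objects (names = block ids).
#' @param dir Cache directory (created if needed).
#' @return `write_model_cache()` returns the file paths invisibly;
#'   `read_model_cache()` returns the named list of models.
#' @export
write_model_cache <- function(models, dir) {
  if (is.null(names(models)) || any(names(models) == "")) {
    abort("`models` must be a named list keyed by block id.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(models), function(id) {
    path <- file.path(dir, paste0(id, ".knockoff.rds"))
    saveRDS(models[[id]], path)
    path
  }, character(1))
  invisible(paths)
}

#' @rdname write_model_cache
#' @export
read_model_cache <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.knockoff\\.rds$", full.names = TRUE))
  if (length(files) == 0) abort(sprintf("no cached models under '%s'", dir))
  models <- lapply(files, readRDS)
  names(models) <- sub("\\.knockoff\\.rds$", "", basename(files))
  models
}
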