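#' Aligned multi-study Z-score panel
#'
#' Bundles K studies' aligned Z-scores on a common variant set, their sample
#' sizes, observation masks (for study-specific variants) and optional LD
#' group labels (for ancestry-heterogeneous meta-analysis). Variants observed
#' in no study are dropped with a warning.
#'
#' @param Z p x K numeric matrix of Z-scores (NA = unobserved).
#' @param n Length-K sample sizes (positive).
#' @param mask Optional p x K 0/1 observation indicator; defaults to
#'   `!is.na(Z)`.
#' @param variants Optional variant ids (default rownames of `Z`).
#' @param group Optional length-K labels mapping studies to LD groups;
#'   default a single group `"g1"`.
#' @param n_case,n_control Optional length-K case/control counts; when given,
#'   the effective per-study size `4 / (1/n_case + 1/n_control)` is available
#'   to the weight solver.
#' @param drop_unobserved Drop variants observed in no study (default TRUE);
#'   set FALSE to keep them coded as zero, e.g. when rows must stay aligned
#'   to a per-block knockoff model.
#' @return An object of class `study_panel`.
#' @export
study_panel <- function(Z, n, mask = NULL, variants = NULL, group = NULL,
                        n_case = NULL, n_control = NULL,
                        drop_unobserved = TRUE) {
  if (!is.matrix(Z)) Z <- as.matrix(Z)
  K <- ncol(Z)
  if (length(n) != K || any(n <= 0)) abort("`n` must be positive, one per study.")
  if (is.null(mask)) mask <- 1 * !is.na(Z)
  if (!all(dim(mask) == dim(Z))) abort("`mask` must match dim(Z).")
  if (any(!is.finite(Z[mask == 1]))) abort("Z must be finite where mask = 1.")
  variants <- variants %||% rownames(Z) %||% paste0("v", seq_len(nrow(Z)))
  group <- group %||% rep("g1", K)
  if (length(group) != K) abort("`group` needs one label per study.")
  keep <- rowSums(mask) > 0
  if (!all(keep) && drop_unobserved) {
    warn(sprintf("dropping %d variant(s) observed in no study", sum(!keep)))
    Z <- Z[keep, , drop = FALSE]
    mask <- mask[keep, , drop = FALSE]
    variants <- variants[keep]
  }
  Z[mask == 0] <- 0   # unobserved coded 0 so studies contribute nothing
  structure(
    list(
      Z = Z, n = as.numeric(n), mask = mask, variants = variants,
      group = as.character(group), K = K,
      n_case = n_case, n_control = n_control
    ),
    class = "study_panel"
  )
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf(
    "<study_panel> %d studies, %d variants, groups: %s\n",
    x$K, nrow(x$Z), paste(unique(x$group), collapse = ", ")
  ))
  invisible(x)
}

#' Estimate the study-correlation matrix from null Z-scores
#'
#' Sample overlap between studies induces correlation between their Z-scores
#' at null variants. The estimator decorrelates LD first: for each study the
#' residual `z - P1 z = D Sigma^{-1} z` is computed per block, and pairs of
#' studies are correlated over variants observed in both with `|z| <= z_cap`
#' in both (the cap removes polygenic signal; default 1.96). The raw pairwise
#' matrix is forced to unit diagonal and PSD-repaired.
#'
#' @param panel A [study_panel()].
#' @param models A [knockoff_model()], or a list of them (one per block, in
#'   variant order matching the panel).
#' @param z_cap Null cap on |Z|; default 1.96.
#' @param min_shared Minimum jointly observed null variants per pair.
#' @return K x K correlation matrix.
#' @export
estimate_study_correlation <- function(panel, models, z_cap = 1.96,
                                       min_shared = 100) {
  if (inherits(models, "knockoff_model")) models <- list(models)
  p_tot <- sum(vapply(models, function(m) m$p, numeric(1)))
  if (p_tot != nrow(panel$Z)) {
    abort("models cover a different number of variants than the panel.")
  }
  K <- panel$K
  resid <- matrix(0, nrow(panel$Z), K)
  off <- 0
  for (m in models) {
    idx <- off + seq_len(m$p)
    # D Sigma^{-1} z: expected gap between original and knockoff Z
    resid[idx, ] <- panel$Z[idx, , drop = FALSE] -
      m$P1 %*% panel$Z[idx, , drop = FALSE]
    off <- off + m$p
  }
  nullish <- (panel$mask == 1) & (abs(panel$Z) <= z_cap)
  corS <- diag(1, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      use <- nullish[, i] & nullish[, j]
      if (sum(use) < min_shared) {
        abort(sprintf(
          "studies %d and %d share only %d null variants (< %d)",
          i, j, sum(use), min_shared
        ))
      }
      corS[i, j] <- corS[j, i] <- cor(resid[use, i], resid[use, j])
    }
  }
  R <- psd_repair(corS, variants = paste0("study", seq_len(K)))
  out <- unclass(R)[seq_len(K), seq_len(K)]
  dimnames(out) <- NULL
  diag(out) <- 1
  out
}

#' Optimal study weights under sample overlap
#'
#' Solves `minimize sum_ij w_i w_j corS_ij` subject to
#' `sum_k w_k sqrt(n_k) = 1`, `w_k >= 0` — the overlap-aware analogue of
#' Lin–Sullivan weights with a nonnegativity constraint. Up-weights studies
#' carrying independent information, down-weights studies that largely
#' overlap others. Solved with a dual-method QP solver; when `corS` is
#' singular (e.g. duplicated studies) a vanishing ridge selects the
#' minimum-norm optimum, so duplicated studies get equal weights.
#'
#' @param corS K x K PSD study-correlation matrix.
#' @param n Length-K sample sizes.
#' @param n_case,n_control Optional case/control counts; when both are given
#'   `n` is replaced by `4 / (1/n_case + 1/n_control)` to account for
#'   case-control imbalance.
#' @return Numeric weight vector with attribute `kkt_residual`.
#' @export
optimal_weights <- function(corS, n, n_case = NULL, n_control = NULL) {
  K <- length(n)
  check_symmetric(corS, arg = "corS")
  if (lambda_min(corS) < -1e-8) abort("`corS` must be PSD (repair it first).")
  n <- effective_study_n(n, n_case, n_control)
  b <- sqrt(n)
  ridge <- 0
  w <- NULL
  for (attempt in 1:6) {
    Dmat <- 2 * (corS + ridge * diag(K))
    sol <- tryCatch(
      quadprog::solve.QP(
        Dmat = Dmat, dvec = rep(0, K),
        Amat = cbind(b, diag(K)), bvec = c(1, rep(0, K)), meq = 1
      ),
      error = function(e) NULL
    )
    if (!is.null(sol)) {
      w <- pmax(sol$solution, 0)
      w <- w / sum(w * b)
      break
    }
    ridge <- max(ridge * 10, 1e-10)
  }
  if (is.null(w)) abort("optimal weight QP failed to solve.")
  # KKT residual of the original (ridge-free) problem
  g <- 2 * drop(corS %*% w)
  lam <- sum(w * g) / sum(w * b)   # from complementary slackness on active set
  mu <- g - lam * b
  kkt <- max(0, -min(mu), max(abs(mu[w > 1e-10])), abs(sum(w * b) - 1))
  structure(w, kkt_residual = kkt)
}

effective_study_n <- function(n, n_case = NULL, n_control = NULL) {
  if (!is.null(n_case) && !is.null(n_control)) {
    4 / (1 / n_case + 1 / n_control)
  } else {
    n
  }
}

#' Effective sample size and dependency factor
#'
#' The dependency factor `gamma = sqrt(1 + N / N_eff - N_eff / N)` inflates
#' the knockoff noise of each study so that overlapping samples do not make
#' knockoffs too similar across studies. With sample-size weights,
#' `N_eff / N = N / sum_ij sqrt(n_i n_j) corS_ij`; with optimal weights,
#' `N_eff / N = sum_k w_k^2 / sum_ij w_i w_j corS_ij`. Independent studies
#' (`corS = I`) give `N_eff = N` and `gamma = 1` exactly; K identical studies
#' give `N_eff = N / K`. Estimation noise can push `N_eff` slightly above
#' `N`; it is clipped to `N` with a warning.
#'
#' @inheritParams optimal_weights
#' @param w Weights (required for `scheme = "optimal"`).
#' @param scheme `"size"` (weights `sqrt(n_k / N)`) or `"optimal"`.
#' @return List with `N_eff` and `gamma`.
#' @export
effective_size_and_gamma <- function(corS, n, w = NULL,
                                     scheme = c("size", "optimal")) {
  scheme <- match.arg(scheme)
  N <- sum(n)
  ratio <- if (scheme == "size") {
    N / sum(sqrt(outer(n, n)) * corS)
  } else {
    if (is.null(w)) abort("`w` is required for scheme = 'optimal'.")
    sum(w^2) / sum(outer(w, w) * corS)
  }
  if (ratio > 1 + 1e-8) {
    warn(sprintf("estimated N_eff/N = %.3f > 1; clipping to 1", ratio))
  }
  ratio <- min(ratio, 1)
  list(N_eff = ratio * N, gamma = sqrt(1 + 1 / ratio - ratio))
}

#' Full meta-analysis weight bundle
#'
#' Convenience wrapper producing the study-correlation-aware weight set used
#' by [meta_z()] / [meta_knockoff_z()]: weights `w`, effective sample size
#' `N_eff`, and dependency factor `gamma`.
#'
#' @inheritParams optimal_weights
#' @param scheme `"size"` for conventional `sqrt(n_k / N)` weights or
#'   `"optimal"` for the overlap-aware QP weights.
#' @return Object of class `meta_weights`: list with `corS`, `w`, `N_eff`,
#'   `gamma`, `scheme`, `n`.
#' @export
meta_weights <- function(corS, n, scheme = c("size", "optimal"),
                         n_case = NULL, n_control = NULL) {
  scheme <- match.arg(scheme)
  n_use <- effective_study_n(n, n_case, n_control)
  w <- if (scheme == "size") {
    sqrt(n_use / sum(n_use))
  } else {
    as.numeric(optimal_weights(corS, n_use))
  }
  eg <- effective_size_and_gamma(corS, n_use, w = w, scheme = scheme)
  structure(
    list(corS = corS, w = w, N_eff = eg$N_eff, gamma = eg$gamma,
         scheme = scheme, n = n_use),
    class = "meta_weights"
  )
}

#' @export
print.meta_weights <- function(x, ...) {
  cat(sprintf(
    "<meta_weights> K = %d, scheme = %s, N_eff = %.1f, gamma = %.4f\n",
    length(x$w), x$scheme, x$N_eff, x$gamma
  ))
  invisible(x)
}

#' @rdname meta_weights
#' @param x A `meta_weights`.
#' @param ... Unused.
#' @export
glance.meta_weights <- function(x, ...) {
  tibble(
    K = length(x$w), scheme = x$scheme, N = sum(x$n),
    N_eff = x$N_eff, gamma = x$gamma
  )
}

#' Meta-analysis Z-scores
#'
#' `Z_meta = sum_k w_k C_k Z_k`, where the diagonal mask `C_k` zeroes
#' variants unobserved in study k (which therefore contribute nothing). No
#' rescaling for missingness is applied: knockoff inference is scale-free,
#' selection depends only on the contrast between `Z_meta` and its knockoffs.
#'
#' @param panel A [study_panel()].
#' @param weights A [meta_weights()] (or bare weight vector).
#' @return Numeric vector of meta Z-scores, named by variant.
#' @export
meta_z <- function(panel, weights) {
  w <- if (inherits(weights, "meta_weights")) weights$w else weights
  if (length(w) != panel$K) abort("one weight per study required.")
  z <- drop((panel$Z * panel$mask) %*% w)
  names(z) <- panel$variants
  z
}

#' Meta-analysis knockoff Z-scores
#'
#' Homogeneous-LD case (single group): `Z_knock = sum_k w_k C_k (P1 Z_k +
#' gamma E_k)` with `E_k ~ N(0, V)` drawn independently per study and
#' `gamma` the dependency factor. Heterogeneous case (several LD groups):
#' knockoffs are generated per group with that group's model and `gamma_l`,
#' then combined with fixed `sqrt(n_l / N)` weights across groups.
#'
#' @param panel A [study_panel()].
#' @param weights A [meta_weights()] for the single-group case, or a named
#'   list of `meta_weights` keyed by group label.
#' @param models A [knockoff_model()] for the single-group case, or a named
#'   list keyed by group label.
#' @param seed Integer seed (per-study noise seeds are derived from it).
#' @return p x M matrix of meta knockoff Z-scores.
#' @export
meta_knockoff_z <- function(panel, weights, models, seed) {
  if (missing(seed)) abort("`seed` is required.")
  groups <- unique(panel$group)
  if (length(groups) == 1) {
    model <- if (inherits(models, "knockoff_model")) models else models[[groups]]
    if (is.null(model)) abort(sprintf("no knockoff model for group '%s'", groups))
    wts <- if (inherits(weights, "meta_weights")) weights else weights[[groups]]
    return(meta_knockoff_group(panel, seq_len(panel$K), wts, model, seed))
  }
  N <- sum(panel$n)
  out <- NULL
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ks <- which(panel$group == g)
    model <- models[[g]]
    if (is.null(model)) abort(sprintf("no knockoff model for group '%s'", g))
    wts <- weights[[g]]
    if (is.null(wts)) abort(sprintf("no weights for group '%s'", g))
    zk_g <- meta_knockoff_group(panel, ks, wts, model, derive_seed(seed, gi))
    n_l <- sum(panel$n[ks])
    contrib <- sqrt(n_l / N) * zk_g
    out <- if (is.null(out)) contrib else out + contrib
  }
  out
}

# Within-group combination: sum_k w_k C_k (P1 z_k + gamma E_k).
meta_knockoff_group <- function(panel, ks, weights, model, seed) {
  w <- if (inherits(weights, "meta_weights")) weights$w else weights
  gamma <- if (inherits(weights, "meta_weights")) weights$gamma else 1
  if (length(w) != length(ks)) abort("one weight per study in the group.")
  p <- model$p
  if (p != nrow(panel$Z)) abort("model and panel disagree on variant count.")
  out <- matrix(0, p, model$M)
  for (i in seq_along(ks)) {
    k <- ks[i]
    zk <- sample_knockoff_z(model, panel$Z[, k] * panel$mask[, k],
                            gamma = max(gamma, 1),
                            seed = derive_seed(seed, k))
    out <- out + w[i] * (zk$z_knock * panel$mask[, k])
  }
  rownames(out) <- panel$variants
  out
}

#' Group-combined meta Z-scores for heterogeneous LD
#'
#' For L LD groups, combines within-group weighted Z-scores with fixed
#' `sqrt(n_l / N)` weights: `Z = (1/sqrt(N)) sum_l sqrt(n_l) Z_l` where
#' `Z_l = sum_k w_lk Z_lk`. Reduces to [meta_z()] for a single group.
#'
#' @inheritParams meta_knockoff_z
#' @return Numeric vector of meta Z-scores.
#' @export
meta_z_grouped <- function(panel, weights) {
  groups <- unique(panel$group)
  if (length(groups) == 1) {
    wts <- if (inherits(weights, "meta_weights")) weights else weights[[groups]]
    return(meta_z(panel, wts))
  }
  N <- sum(panel$n)
  z <- rep(0, nrow(panel$Z))
  for (g in groups) {
    ks <- which(panel$group == g)
    wts <- weights[[g]]
    w <- if (inherits(wts, "meta_weights")) wts$w else wts
    zg <- drop((panel$Z[, ks, drop = FALSE] *
                  panel$mask[, ks, drop = FALSE]) %*% w)
    z <- z + sqrt(sum(panel$n[ks]) / N) * zg
  }
  names(z) <- panel$variants
  z
}
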