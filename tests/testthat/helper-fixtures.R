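# Shared fixtures and independent oracles used across test files.

# Random PSD correlation matrix of size p.
random_corr <- function(p, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(p * (p + 2)), p + 2, p)
    cov2cor(crossprod(A))
  })
}

# Exhaustive oracle for the knockoff filter: scan every candidate threshold.
oracle_threshold <- function(kappa, tau, q, M) {
  cand <- sort(unique(tau[tau > 0]))
  best <- Inf
  for (t in cand) {
    num <- 1 / M + sum(kappa >= 1 & tau >= t) / M
    den <- sum(kappa == 0 & tau >= t)
    if (den > 0 && num / den <= q) {
      best <- min(best, t)
    }
  }
  best
}

# Exhaustive oracle for q-values: minimize the estimate over all t <= tau_j.
oracle_qvalues <- function(kappa, tau, M) {
  cand <- sort(unique(tau[tau > 0]))
  vapply(seq_along(kappa), function(j) {
    if (kappa[j] != 0 || tau[j] <= 0) return(1)
    ratios <- vapply(cand[cand <= tau[j]], function(t) {
      num <- 1 / M + sum(kappa >= 1 & tau >= t) / M
      den <- sum(kappa == 0 & tau >= t)
      if (den == 0) Inf else num / den
    }, numeric(1))
    min(c(ratios, 1))
  }, numeric(1))
}

# Small aligned two-study panel on independent variants, for meta tests.
toy_panel <- function(p = 200, K = 2, seed = 7) {
  withr::with_seed(seed, {
    Z <- matrix(rnorm(p * K), p, K)
    study_panel(Z, n = rep(1000, K))
  })
}
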