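# Knockoff model construction and Z-score sampling.

test_that("psd_repair fixes indefinite input and is idempotent", {
  R <- matrix(c(1, 1.2, 1.2, 1), 2)
  fixed <- psd_repair(R)
  expect_true(attr(fixed, "repaired"))
  expect_gte(min(eigen(unclass(fixed))$values), 0)
  expect_equal(diag(unclass(fixed)), c(v1 = 1, v2 = 1))
  expect_true(fixed[1, 2] > 0 && fixed[1, 2] <= 1)

  again <- psd_repair(unclass(fixed))
  expect_false(attr(again, "repaired"))
  expect_equal(unclass(again), unclass(fixed), ignore_attr = TRUE)

  I3 <- psd_repair(diag(3))
  expect_false(attr(I3, "repaired"))
  expect_equal(unclass(I3), diag(3), ignore_attr = TRUE)

  expect_error(psd_repair(matrix(1:6, 2)), "square")
  expect_error(psd_repair(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("solve_s equi matches the closed form", {
  expect_equal(solve_s(psd_repair(diag(3)), M = 1), rep(1, 3))
  S <- psd_repair(matrix(c(1, .8, .8, 1), 2))
  expect_equal(solve_s(S, M = 1, "equi"), c(0.4, 0.4), tolerance = 1e-10)
  expect_equal(solve_s(S, M = 5, "equi"), c(0.24, 0.24), tolerance = 1e-10)
})

test_that("sdp solver agrees with equi on equicorrelated blocks and beats it elsewhere", {
  for (rho in c(0.3, 0.8)) {
    S <- psd_repair(matrix(c(1, rho, rho, 1), 2))
    expect_equal(solve_s(S, M = 1, "sdp"), solve_s(S, M = 1, "equi"),
                 tolerance = 1e-4)
    expect_equal(solve_s(S, M = 5, "sdp"), solve_s(S, M = 5, "equi"),
                 tolerance = 1e-4)
  }
  # generic matrices: sdp stays feasible and never loses to equi
  for (seed in 1:5) {
    S <- psd_repair(random_corr(6, seed))
    for (M in c(1, 5)) {
      s_sdp <- solve_s(S, M = M, "sdp")
      s_equi <- solve_s(S, M = M, "equi")
      expect_gte(min(eigen((M + 1) / M * unclass(S) - diag(s_sdp))$values),
                 -1e-8)
      expect_gte(sum(s_sdp), sum(s_equi) - 1e-6)
      expect_true(all(s_sdp >= 0 & s_sdp <= 1 + 1e-8))
    }
  }
})

test_that("solve_s rejects non-PSD input", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(solve_s(bad, M = 1), "psd_repair")
})

test_that("knockoff model matches hand-derived P and V", {
  # independent variants: projection vanishes, noise is white
  m <- knockoff_model(psd_repair(diag(2)), M = 1)
  expect_equal(m$P1, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_equal(knockoff_V(m), diag(2), tolerance = 1e-12)

  # hand inversion for rho = 0.5 with s = (1, 1)
  S <- psd_repair(matrix(c(1, .5, .5, 1), 2))
  m <- knockoff_model(S, M = 1, s = c(1, 1))
  expect_equal(m$P1, matrix(c(-1, 2, 2, -1) / 3, 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(knockoff_V(m), matrix(2 / 3, 2, 2), tolerance = 1e-9)
  expect_equal(sort(eigen(knockoff_V(m))$values), c(0, 4 / 3),
               tolerance = 1e-9)

  # multiple knockoffs of independent variants: V is the pM identity
  m3 <- knockoff_model(psd_repair(diag(2)), M = 3)
  expect_equal(knockoff_V(m3), diag(6), tolerance = 1e-12)
})

test_that("structured noise factor reproduces V and the feasibility constraints hold", {
  for (seed in c(2, 9)) {
    for (M in c(1, 3, 5)) {
      S <- psd_repair(random_corr(8, seed))
      m <- knockoff_model(S, M = M)
      V <- knockoff_V(m)
      # factor x factor' == V via the structured (Q kron I) blockdiag form
      p <- m$p
      blk <- matrix(0, p * M, p * M)
      blk[seq_len(p), seq_len(p)] <- tcrossprod(m$F1)
      if (M > 1) {
        for (a in 2:M) {
          idx <- (a - 1) * p + seq_len(p)
          blk[idx, idx] <- diag(m$s, p)
        }
      }
      QI <- kronecker(m$Q, diag(p))
      expect_equal(QI %*% blk %*% t(QI), V, tolerance = 1e-8)
      # spec constraints
      expect_gte(min(eigen((M + 1) / M * unclass(S) - diag(m$s))$values), -1e-8)
      expect_gte(min(eigen(V, symmetric = TRUE, only.values = TRUE)$values),
                 -1e-8)
      expect_equal(knockoff_P(m),
                   do.call(rbind, replicate(M, m$P1, simplify = FALSE)))
    }
  }
})

test_that("knockoff sampling is seed-deterministic and respects gamma bounds", {
  S <- psd_repair(random_corr(5, 3))
  m <- knockoff_model(S, M = 5)
  z <- rnorm(5)
  a <- sample_knockoff_z(m, z, seed = 11)
  b <- sample_knockoff_z(m, z, seed = 11)
  expect_identical(a$z_knock, b$z_knock)
  c_ <- sample_knockoff_z(m, z, seed = 12)
  expect_false(identical(a$z_knock, c_$z_knock))
  expect_error(sample_knockoff_z(m, z, gamma = 0.5, seed = 1), "gamma")
  expect_error(sample_knockoff_z(m, z[1:3], seed = 1), "length")
})

test_that("knockoff Z-scores of independent variants are independent white noise", {
  m <- knockoff_model(psd_repair(diag(2)), M = 1)
  z <- c(3, -2)
  draws <- vapply(1:50000, function(i) {
    sample_knockoff_z(m, z, seed = i)$z_knock[, 1]
  }, numeric(2))
  expect_equal(rowMeans(draws), c(0, 0), tolerance = 0.02)
  expect_equal(cov(t(draws)), diag(2), tolerance = 0.03)
})

test_that("joint (z, knockoffs) covariance is exchangeable under the null", {
  # pooled Monte-Carlo second moments must match Sigma on the diagonal
  # blocks and Sigma - D everywhere off-diagonal
  p <- 6
  M <- 3
  S <- psd_repair(random_corr(p, 5))
  m <- knockoff_model(S, M = M)
  n_draws <- 10000
  L <- chol(unclass(S))
  X <- withr::with_seed(99, matrix(rnorm(n_draws * p), n_draws, p) %*% L)
  big <- matrix(0, n_draws, p * (M + 1))
  for (i in seq_len(n_draws)) {
    zk <- sample_knockoff_z(m, X[i, ], seed = i)
    big[i, ] <- c(X[i, ], as.vector(zk$z_knock))
  }
  emp <- cov(big)
  theo <- matrix(0, p * (M + 1), p * (M + 1))
  for (a in 0:M) {
    for (b in 0:M) {
      blk <- if (a == b) unclass(S) else unclass(S) - diag(m$s)
      theo[a * p + seq_len(p), b * p + seq_len(p)] <- blk
    }
  }
  # 3 x Monte-Carlo SE for a covariance entry at these draws
  se <- 3 * sqrt(2 / n_draws)
  expect_lt(max(abs(emp - theo)), se + 0.02)
})

test_that("model cache round-trips bit-exactly", {
  S <- psd_repair(random_corr(4, 8))
  models <- list(blockA = knockoff_model(S, M = 2),
                 blockB = knockoff_model(psd_repair(diag(3)), M = 2))
  dir <- withr::local_tempdir()
  write_model_cache(models, dir)
  back <- read_model_cache(dir)
  expect_identical(back[order(names(back))], models[order(names(models))])
  expect_error(read_model_cache(file.path(dir, "nope")), "no cached models")
  expect_error(write_model_cache(unname(models), dir), "named")
})

test_that("downstream selection is invariant to joint rescaling of the scores", {
  S <- psd_repair(random_corr(10, 4))
  m <- knockoff_model(S, M = 5)
  z <- withr::with_seed(21, drop(chol(unclass(S)) %*% rnorm(10)) + c(rep(4, 2), rep(0, 8)))
  zk <- sample_knockoff_z(m, z, seed = 5)
  s1 <- feature_stats(z, zk$z_knock, tie_seed = 3)
  s2 <- feature_stats(3.7 * z, 3.7 * zk$z_knock, tie_seed = 3)
  expect_equal(s1$kappa, s2$kappa)
  sel1 <- knockoff_select(s1, 0.2)
  sel2 <- knockoff_select(s2, 0.2)
  expect_equal(sel1$selected, sel2$selected)
})
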