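# Study correlations, optimal weights, dependency factor, meta knockoffs.

test_that("gamma is exactly 1 for independent studies and >= 1 always", {
  eg <- effective_size_and_gamma(diag(2), c(4000, 1000), scheme = "size")
  expect_identical(eg$gamma, 1)
  expect_equal(eg$N_eff, 5000)

  # two identical studies: N_eff = N/2 and gamma = sqrt(2.5)
  eg2 <- effective_size_and_gamma(matrix(1, 2, 2), c(1000, 1000),
                                  scheme = "size")
  expect_equal(eg2$N_eff, 1000)
  expect_equal(eg2$gamma, sqrt(1 + 2 - 0.5), tolerance = 1e-12)

  withr::with_seed(5, {
    for (i in 1:10) {
      K <- sample(2:5, 1)
      corS <- unclass(psd_repair(random_corr(K, i)))
      diag(corS) <- 1
      n <- runif(K, 500, 5000)
      eg <- effective_size_and_gamma(abs(corS), n, scheme = "size")
      expect_gte(eg$gamma, 1)
    }
  })
})

test_that("case-control effective size matches 4/(1/n1+1/n0)", {
  expect_equal(zknock:::effective_study_n(1, n_case = 5000, n_control = 5000),
               10000)
  w <- meta_weights(diag(1), n = 1, scheme = "size",
                    n_case = 1000, n_control = 9000)
  expect_equal(w$n, 4 / (1 / 1000 + 1 / 9000))
})

test_that("optimal weights solve the constrained QP", {
  # two independent equal studies: closed form w = 1/(2 sqrt(n))
  w <- optimal_weights(diag(2), c(400, 400))
  expect_equal(as.numeric(w), rep(1 / (2 * 20), 2), tolerance = 1e-8)
  expect_lt(attr(w, "kkt_residual"), 1e-6)

  # single study: constraint alone fixes w = 1/sqrt(n)
  w1 <- optimal_weights(matrix(1, 1, 1), 2500)
  expect_equal(as.numeric(w1), 1 / 50, tolerance = 1e-10)

  # duplicated studies: degenerate QP, symmetric minimum-norm optimum
  wd <- optimal_weights(matrix(1, 2, 2), c(900, 900))
  expect_equal(wd[1], wd[2], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(sum(as.numeric(wd) * sqrt(c(900, 900))), 1, tolerance = 1e-8)

  # random PSD problems: constraint + nonnegativity + KKT residual
  withr::with_seed(11, {
    for (i in 1:10) {
      K <- sample(2:6, 1)
      corS <- unclass(psd_repair(abs(random_corr(K, i * 17))))
      diag(corS) <- 1
      n <- runif(K, 500, 5000)
      w <- optimal_weights(corS, n)
      expect_true(all(w >= -1e-10))
      expect_equal(sum(as.numeric(w) * sqrt(n)), 1, tolerance = 1e-8)
      expect_lt(attr(w, "kkt_residual"), 1e-6)
      # never worse than projected size weights
      ws <- sqrt(n) / sum(n)
      obj <- function(v) sum(outer(v, v) * corS)
      expect_lte(obj(as.numeric(w)), obj(ws) + 1e-8)
    }
  })
})

test_that("study correlation recovers identity, duplication and overlap", {
  p <- 400
  S <- psd_repair(diag(p))
  m <- knockoff_model(S, M = 5)

  # byte-identical studies -> correlation 1
  z <- withr::with_seed(2, rnorm(p))
  panel <- study_panel(cbind(z, z), n = c(1000, 1000))
  corS <- estimate_study_correlation(panel, m)
  expect_equal(corS[1, 2], 1, tolerance = 1e-8)

  # independent null studies -> correlation near 0 (3 SE at ~p variants)
  z2 <- withr::with_seed(3, rnorm(p))
  corS0 <- estimate_study_correlation(study_panel(cbind(z, z2),
                                                  n = c(1000, 1000)), m)
  expect_lt(abs(corS0[1, 2]), 3 / sqrt(p) + 0.02)

  expect_error(
    estimate_study_correlation(study_panel(cbind(z, z2), n = c(1, 1)),
                               m, min_shared = 1e6),
    "null variants"
  )
})

test_that("study correlation under 50% sample overlap is near 0.5", {
  # simulate overlapping score statistics directly: z_k = G_k' y_k / sqrt(n)
  p <- 300
  n <- 400
  S <- psd_repair(diag(p))
  m <- knockoff_model(S, M = 5)
  cors <- withr::with_seed(8, {
    vapply(1:5, function(r) {
      pool_y <- rnorm(2 * n)
      G <- matrix(rbinom(2 * n * p, 2, 0.3), 2 * n, p)
      idx <- make_overlapping_studies(2 * n, n, 0.5, seed = r)
      z1 <- compute_zscores(G[idx$study1, ], pool_y[idx$study1])
      z2 <- compute_zscores(G[idx$study2, ], pool_y[idx$study2])
      c(estimate_study_correlation(study_panel(cbind(z1, z2), n = c(n, n)),
                                   m, z_cap = Inf)[1, 2],
        estimate_study_correlation(study_panel(cbind(z1, z2), n = c(n, n)),
                                   m)[1, 2])
    }, numeric(2))
  })
  # uncapped estimate matches the overlap theory cor = n_shared / sqrt(n1 n2)
  expect_equal(mean(cors[1, ]), 0.5,
               tolerance = 3 * sd(cors[1, ]) / sqrt(5) + 0.05)
  # the default |Z| <= 1.96 null cap truncates the bivariate normal and
  # attenuates the estimate towards zero, but keeps the ordering
  expect_lt(mean(cors[2, ]), mean(cors[1, ]))
  expect_gt(mean(cors[2, ]), 0.25)
})

test_that("meta Z-scores follow the masked weighted sum", {
  Z <- cbind(c(1, 2, NA), c(2, NA, 3))
  panel <- study_panel(Z, n = c(100, 400))
  wts <- meta_weights(diag(2), c(100, 400), scheme = "size")
  z <- meta_z(panel, wts)
  w <- sqrt(c(100, 400) / 500)
  expect_equal(unname(z), c(w[1] * 1 + w[2] * 2, w[1] * 2, w[2] * 3))

  # masking only affects the masked variant's row
  Z2 <- Z; Z2[1, 2] <- NA
  z2 <- meta_z(study_panel(Z2, n = c(100, 400)), wts)
  expect_equal(unname(z2[-1]), unname(z[-1]))
  expect_equal(unname(z2[1]), w[1] * 1)
})

test_that("meta knockoffs reduce to single-study sampling when K = 1", {
  S <- psd_repair(random_corr(12, 6))
  m <- knockoff_model(S, M = 5)
  z <- withr::with_seed(4, rnorm(12))
  panel <- study_panel(matrix(z, ncol = 1), n = 900)
  wts <- meta_weights(diag(1), 900, scheme = "size")
  expect_equal(wts$gamma, 1)
  zk_meta <- meta_knockoff_z(panel, wts, m, seed = 77)
  direct <- sample_knockoff_z(m, z, gamma = 1,
                              seed = zknock:::derive_seed(77, 1))
  # w = 1 for a single study, so the draws must coincide exactly
  expect_equal(unname(zk_meta), unname(direct$z_knock))
})

test_that("meta of two independent studies has the exchangeable null covariance", {
  # pooled (z_meta, z_knock) second moments must match the single-study
  # exchangeable form because gamma = 1 and sum w_k^2 = 1
  p <- 5
  M <- 3
  S <- psd_repair(random_corr(p, 13))
  m <- knockoff_model(S, M = M)
  L <- chol(unclass(S))
  n_draws <- 6000
  wts <- meta_weights(diag(2), c(700, 700), scheme = "size")
  big <- withr::with_seed(14, {
    t(vapply(seq_len(n_draws), function(i) {
      Z <- t(L) %*% matrix(rnorm(2 * p), p, 2) # two independent null studies
      panel <- study_panel(Z, n = c(700, 700))
      zm <- meta_z(panel, wts)
      zk <- meta_knockoff_z(panel, wts, m, seed = i)
      c(zm, as.vector(zk))
    }, numeric(p * (M + 1))))
  })
  emp <- cov(big)
  theo <- matrix(0, p * (M + 1), p * (M + 1))
  for (a in 0:M) {
    for (b in 0:M) {
      blk <- if (a == b) unclass(S) else unclass(S) - diag(m$s)
      theo[a * p + seq_len(p), b * p + seq_len(p)] <- blk
    }
  }
  expect_lt(max(abs(emp - theo)), 3 * sqrt(2 / n_draws) + 0.03)
})

test_that("heterogeneous-LD groups combine with sqrt(n_l/N) weights", {
  p <- 6
  S1 <- psd_repair(random_corr(p, 1))
  S2 <- psd_repair(random_corr(p, 2))
  models <- list(eur = knockoff_model(S1, M = 2),
                 afr = knockoff_model(S2, M = 2))
  Z <- withr::with_seed(9, matrix(rnorm(p * 2), p, 2))
  panel <- study_panel(Z, n = c(300, 100), group = c("eur", "afr"))
  wlist <- list(eur = meta_weights(diag(1), 300, scheme = "size"),
                afr = meta_weights(diag(1), 100, scheme = "size"))
  zm <- meta_z_grouped(panel, wlist)
  expect_equal(unname(zm),
               sqrt(300 / 400) * Z[, 1] + sqrt(100 / 400) * Z[, 2])
  zk <- meta_knockoff_z(panel, wlist, models, seed = 3)
  expect_equal(dim(zk), c(p, 2))
  # deterministic given the seed
  expect_equal(zk, meta_knockoff_z(panel, wlist, models, seed = 3))
  expect_error(meta_knockoff_z(panel, wlist, list(eur = models$eur), seed = 1),
               "no knockoff model")
})
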