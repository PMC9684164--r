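#' Simulation configuration
#'
#' Collects the settings of the synthetic two-study power/FDR experiment:
#' a genotype pool with block-AR(1) latent LD, 10 causal variants carrying
#' total causal variance 1, quantitative or dichotomous traits (10%
#' prevalence), and configurable sample overlap between the two studies.
#' Defaults are the desk-scale profile (1000 samples/study, 300 variants,
#' 100 replicates); the full-scale design (2500/2000/1000) is one config
#' change away.
#'
#' @param n_study Samples per study.
#' @param p Number of variants in the region (pre-filter).
#' @param overlap Fraction of each study's samples shared with the other
#'   (`0 <= overlap < 1`; the experiments use 0, 0.25, 0.5).
#' @param n_causal Number of causal variants.
#' @param trait `"quantitative"` or `"dichotomous"`.
#' @param prevalence Marginal case prevalence for the dichotomous trait.
#' @param total_causal_variance Total phenotypic variance attributed to the
#'   causal variants.
#' @param ld_spec List describing the latent LD: `rho` (AR(1) coefficient
#'   within a block) and `block_size`.
#' @param maf_range Range the per-variant MAFs are drawn from (uniform).
#' @param mac_min Minor-allele-count filter (strict >) applied to the pool.
#' @param M Knockoff copies per variant.
#' @param targets Target-FDR grid for the filter.
#' @param weights Weight scheme for the two-study meta-analysis.
#' @param shrinkage LD shrinkage used when estimating the model LD from the
#'   pool (in-sample panel, so only a small stabilizing value is needed).
#' @param prune_threshold Tight-LD pruning correlation; default 0.75.
#' @param unobserved_frac Fraction of variants randomly set to unobserved in
#'   each study (study-specific coverage gaps, e.g. platform differences);
#'   masked variants contribute zero to the meta Z-score and its knockoffs.
#' @param replicates Number of replicates.
#' @param seed Master seed; all per-replicate seeds derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_study = 1000, p = 300, overlap = 0.25,
                       n_causal = 10, trait = c("quantitative", "dichotomous"),
                       prevalence = 0.10, total_causal_variance = 1,
                       ld_spec = list(rho = 0.5, block_size = 10),
                       maf_range = c(0.05, 0.5), mac_min = 25L,
                       M = 5L, targets = c(0.05, 0.1, 0.15, 0.2),
                       weights = c("size", "optimal"), shrinkage = 0.01,
                       prune_threshold = 0.75, unobserved_frac = 0,
                       replicates = 100L, seed = 2024L) {
  trait <- match.arg(trait)
  weights <- match.arg(weights)
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  if (n_causal > p) abort("`n_causal` must be <= p.")
  if (unobserved_frac < 0 || unobserved_frac >= 1) {
    abort("`unobserved_frac` must be in [0, 1).")
  }
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0,1).")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate genotype dosages with block LD
#'
#' Latent-Gaussian model: for each of two independent haplotypes per sample,
#' a latent vector with block-AR(1) correlation is thresholded at the
#' MAF-matched normal quantile to give a 0/1 allele; the dosage is the sum.
#' The realized dosage correlation is an attenuated, deterministic function
#' of the latent one; downstream knockoff models are always built from the
#' realized correlations, never the latent ones.
#'
#' @param n Number of samples.
#' @param p Number of variants.
#' @param ld_spec List with `rho` and `block_size` (see [sim_config()]).
#' @param maf Length-p vector of minor allele frequencies in `(0, 0.5]`, or a
#'   length-2 range to draw them from uniformly.
#' @param seed Integer seed.
#' @return List with `G` (n x p dosage matrix), `maf` (target MAFs),
#'   `maf_hat` (realized), `mac` (realized minor allele counts).
#' @export
simulate_genotypes <- function(n, p, ld_spec = list(rho = 0.5, block_size = 10),
                               maf = c(0.05, 0.5), seed) {
  if (missing(seed)) abort("`seed` is required.")
  withr::with_seed(as.integer(seed), {
    if (length(maf) == 2 && p != 2) maf <- runif(p, maf[1], maf[2])
    if (length(maf) != p) abort("`maf` must be a range or length p.")
    if (any(maf <= 0 | maf >= 0.5)) abort("MAFs must be strictly inside (0, 0.5).")
    rho <- ld_spec$rho %||% 0.5
    bs <- ld_spec$block_size %||% 10
    thr <- qnorm(maf)
    hap <- function() {
      Z <- matrix(0, n, p)
      start <- 1
      while (start <= p) {
        end <- min(start + bs - 1, p)
        m <- end - start + 1
        S <- rho^abs(outer(seq_len(m), seq_len(m), "-"))
        Z[, start:end] <- matrix(rnorm(n * m), n, m) %*% chol(S)
        start <- end + 1
      }
      sweep(Z, 2, thr, "<") * 1
    }
    G <- hap() + hap()
    mac <- pmin(colSums(G), 2 * n - colSums(G))
    list(G = G, maf = maf, maf_hat = colMeans(G) / 2, mac = mac)
  })
}

#' Draw two study index sets with controlled overlap
#'
#' `round(overlap * n_study)` samples appear in both studies; the remaining
#' members are disjoint draws from the pool.
#'
#' @param n_pool Pool size.
#' @param n_study Samples per study.
#' @param overlap Shared fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with integer index vectors `study1`, `study2`, `shared`.
#' @export
make_overlapping_studies <- function(n_pool, n_study, overlap, seed) {
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  n_shared <- round(overlap * n_study)
  n_unique <- 2 * n_study - n_shared
  if (n_unique > n_pool) {
    abort(sprintf("pool too small: need %d unique samples, have %d",
                  n_unique, n_pool))
  }
  withr::with_seed(as.integer(seed), {
    picks <- sample.int(n_pool, n_unique)
    shared <- picks[seq_len(n_shared)]
    rest <- if (n_shared > 0) picks[-seq_len(n_shared)] else picks
    only1 <- rest[seq_len(n_study - n_shared)]
    only2 <- rest[(n_study - n_shared) + seq_len(n_study - n_shared)]
    list(study1 = sort(c(shared, only1)), study2 = sort(c(shared, only2)),
         shared = sort(shared))
  })
}

#' Simulate a phenotype with 10 causal variants
#'
#' Quantitative: `Y = X1 + sum_j beta_j G_j + eps`, `eps ~ N(0, 3)`.
#' Dichotomous: `logit(mu) = beta0 + X1 + X2 + sum_j beta_j G_j`, with
#' `beta0` calibrated so the marginal prevalence matches. In both cases
#' `beta_j = a / sqrt(2 m_j (1 - m_j))` with `a` chosen so that the variance
#' from the causal variants equals `total_var`. `X2` and `eps` play the role
#' of unobserved covariates: only `X1` is adjusted for in the analysis,
#' matching the misspecification-robustness setup.
#'
#' @param G Dosage matrix (n x p).
#' @param causal_idx Indices of the causal variants.
#' @param maf Model MAFs of all p variants (used for effect sizes).
#' @param trait `"quantitative"` or `"dichotomous"`.
#' @param prevalence Target marginal prevalence (dichotomous only).
#' @param total_var Total causal variance; default 1.
#' @param seed Integer seed.
#' @return List with `y`, `X1`, `beta` (length p, zero off the causal set),
#'   `causal_idx`, and for the dichotomous trait `beta0` and `mu`.
#' @export
simulate_phenotype <- function(G, causal_idx, maf,
                               trait = c("quantitative", "dichotomous"),
                               prevalence = 0.10, total_var = 1, seed) {
  trait <- match.arg(trait)
  if (missing(seed)) abort("`seed` is required.")
  n <- nrow(G)
  m <- maf[causal_idx]
  if (any(m <= 0 | m > 0.5)) abort("causal MAFs must be in (0, 0.5].")
  a <- sqrt(total_var / length(causal_idx))
  beta <- rep(0, ncol(G))
  beta[causal_idx] <- a / sqrt(2 * m * (1 - m))
  withr::with_seed(as.integer(seed), {
    X1 <- rnorm(n)
    gshift <- drop(G[, causal_idx, drop = FALSE] %*% beta[causal_idx])
    if (trait == "quantitative") {
      y <- X1 + gshift + rnorm(n, sd = sqrt(3))
      list(y = y, X1 = X1, beta = beta, causal_idx = causal_idx)
    } else {
      X2 <- rnorm(n)
      eta <- X1 + X2 + gshift
      f <- function(b0) mean(plogis(b0 + eta)) - prevalence
      if (f(-50) > 0 || f(50) < 0) abort("prevalence calibration failed to bracket.")
      b0 <- uniroot(f, c(-50, 50), tol = 1e-10)$root
      mu <- plogis(b0 + eta)
      y <- rbinom(n, 1, mu)
      list(y = y, X1 = X1, beta = beta, causal_idx = causal_idx,
           beta0 = b0, mu = mu)
    }
  })
}

#' Score-test Z-scores from genotypes and phenotype
#'
#' `Z = G' Y / sqrt(n)` after residualizing `Y` on the observed covariates
#' and standardizing both `Y` and each genotype column to mean 0, variance 1.
#'
#' @param G Dosage matrix (n x p).
#' @param y Phenotype vector.
#' @param X Optional covariate matrix to residualize `y` on (intercept always
#'   included).
#' @return Numeric vector of Z-scores.
#' @export
compute_zscores <- function(G, y, X = NULL) {
  n <- length(y)
  Xmat <- cbind(rep(1, n), X)
  y <- y - drop(Xmat %*% qr.coef(qr(Xmat), y))
  if (sd(y) == 0) abort("phenotype has zero variance after adjustment.")
  y <- y / sd(y)
  sds <- apply(G, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("zero-variance genotype column(s): ",
                 paste(head(which(sds == 0), 5), collapse = ", ")))
  }
  Gs <- scale(G)
  drop(crossprod(Gs, y)) / sqrt(n)
}

#' Power and false discovery proportion of a selection
#'
#' `power = |selected ∩ causal| / |causal|`;
#' `fdp = |selected \ causal| / max(|selected|, 1)` (empty selection counts
#' as FDP 0).
#'
#' @param selected Integer indices (or logical vector) of selected variants.
#' @param causal Integer indices of causal variants (nonempty).
#' @return List with `power` and `fdp`.
#' @export
evaluate_power_fdr <- function(selected, causal) {
  if (length(causal) == 0) abort("`causal` must be nonempty.")
  if (is.logical(selected)) selected <- which(selected)
  power <- length(intersect(selected, causal)) / length(causal)
  fdp <- length(setdiff(selected, causal)) / max(length(selected), 1)
  list(power = power, fdp = fdp)
}

#' Stability of the W statistic under knockoff resampling
#'
#' Holds the data (`z`) fixed, redraws the knockoffs `n_draws` times,
#' recomputes W each time, and returns the per-variant standard deviation of
#' W. Multiple knockoffs (larger M) give visibly smaller sampling noise than
#' a single knockoff.
#'
#' @param z Fixed vector of original Z-scores.
#' @param model A [knockoff_model()].
#' @param gamma Dependency factor; default 1.
#' @param n_draws Number of knockoff redraws (>= 2).
#' @param seed Integer seed.
#' @return Numeric vector (length p) of per-variant SDs of W.
#' @export
stability_sd <- function(z, model, gamma = 1, n_draws = 100, seed = 1L) {
  if (n_draws < 2) abort("`n_draws` must be >= 2 to compute an SD.")
  Ws <- vapply(seq_len(n_draws), function(d) {
    zk <- sample_knockoff_z(model, z, gamma = gamma,
                            seed = derive_seed(seed, d))
    feature_stats(zk, tie_seed = derive_seed(seed, d))$W
  }, numeric(model$p))
  apply(Ws, 1, sd)
}

#' Run the two-study overlap power/FDR experiment
#'
#' Full pipeline per replicate: simulate a genotype pool, apply the MAC
#' filter and tight-LD pruning, pick causal variants among the
#' representatives, simulate the phenotype, split the pool into two
#' overlapping studies, compute per-study score Z-scores, build the knockoff
#' model from the realized pool LD, estimate the study correlation, form
#' overlap-aware meta Z-scores and their knockoffs, and run the filter over
#' the target-FDR grid. Power and FDP are evaluated against the causal truth.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_result`: list with `replicates` (tibble of
#'   per-replicate, per-target power/FDP) and `summary` (tibble with
#'   `target_fdr`, `mean_power`, `mean_fdp`, `se_power`, `se_fdp`,
#'   `n_replicates`), plus the config.
#' @export
run_overlap_experiment <- function(config = sim_config()) {
  reps <- purrr::map_dfr(seq_len(config$replicates), function(r) {
    res <- run_overlap_replicate(config, derive_seed(config$seed, r))
    dplyr::mutate(res, replicate = r)
  })
  summary <- reps |>
    dplyr::group_by(.data$target_fdr) |>
    dplyr::summarise(
      mean_power = mean(.data$power), mean_fdp = mean(.data$fdp),
      se_power = sd(.data$power) / sqrt(dplyr::n()),
      se_fdp = sd(.data$fdp) / sqrt(dplyr::n()),
      n_replicates = dplyr::n(), .groups = "drop"
    )
  structure(list(replicates = reps, summary = summary, config = config),
            class = "sim_result")
}

# One replicate of the experiment; returns a tibble over the target grid.
run_overlap_replicate <- function(config, seed) {
  n_pool <- 2 * config$n_study
  geno <- simulate_genotypes(n_pool, config$p, config$ld_spec,
                             maf = config$maf_range, seed = derive_seed(seed, 1))
  keep <- which(geno$mac > config$mac_min)
  G <- geno$G[, keep, drop = FALSE]
  maf <- geno$maf[keep]
  # prune tight LD among the retained variants; analyze representatives only
  R_pool <- estimate_ld(G, shrinkage = config$shrinkage)
  cmap <- prune_clusters(R_pool, threshold = config$prune_threshold,
                         seed = derive_seed(seed, 2))
  rep_idx <- which(cmap$representative)
  G <- G[, rep_idx, drop = FALSE]
  maf <- maf[rep_idx]
  p <- ncol(G)
  causal <- withr::with_seed(derive_seed(seed, 3),
                             sort(sample.int(p, config$n_causal)))
  pheno <- simulate_phenotype(G, causal, maf, trait = config$trait,
                              prevalence = config$prevalence,
                              total_var = config$total_causal_variance,
                              seed = derive_seed(seed, 4))
  split <- make_overlapping_studies(n_pool, config$n_study, config$overlap,
                                    seed = derive_seed(seed, 5))
  z1 <- compute_zscores(G[split$study1, ], pheno$y[split$study1],
                        X = pheno$X1[split$study1])
  z2 <- compute_zscores(G[split$study2, ], pheno$y[split$study2],
                        X = pheno$X1[split$study2])
  Sigma <- estimate_ld(G, shrinkage = config$shrinkage)
  model <- knockoff_model(Sigma, M = config$M)
  mask <- matrix(1, p, 2)
  if (config$unobserved_frac > 0) {
    # study-specific coverage gaps: mask a random subset per study
    mask <- withr::with_seed(derive_seed(seed, 8), {
      n_hide <- round(config$unobserved_frac * p)
      m <- matrix(1, p, 2)
      m[sample.int(p, n_hide), 1] <- 0
      m[sample.int(p, n_hide), 2] <- 0
      m
    })
  }
  panel <- study_panel(cbind(z1, z2), n = rep(config$n_study, 2),
                       mask = mask, drop_unobserved = FALSE)
  corS <- estimate_study_correlation(panel, model,
                                     min_shared = min(100, floor(p / 2)))
  wts <- meta_weights(corS, panel$n, scheme = config$weights)
  z_meta <- meta_z(panel, wts)
  zk_meta <- meta_knockoff_z(panel, wts, model, seed = derive_seed(seed, 6))
  stats <- feature_stats(z_meta, zk_meta, tie_seed = derive_seed(seed, 7))
  purrr::map_dfr(config$targets, function(q) {
    sel <- knockoff_select(stats, target_fdr = q)
    pf <- evaluate_power_fdr(which(sel$selected), causal)
    tibble(target_fdr = q, power = pf$power, fdp = pf$fdp,
           n_selected = sum(sel$selected), gamma = wts$gamma,
           cor12 = corS[1, 2])
  })
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> trait = %s, overlap = %.0f%%, %d replicates\n",
    x$config$trait, 100 * x$config$overlap,
    max(x$replicates$replicate)
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname run_overlap_experiment
#' @param x,object A `sim_result`.
#' @param ... Unused.
#' @export
tidy.sim_result <- function(x, ...) x$summary

#' @rdname run_overlap_experiment
#' @export
autoplot.sim_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$summary,
                            c("mean_power", "mean_fdp"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_fdr, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "target FDR", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
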