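---
title: "Knockoff inference from GWAS summary statistics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockoff inference from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Conventional GWAS tests each variant marginally and controls the family-wise
error rate, which confounds causal variants with their linkage-disequilibrium
(LD) neighbours. Knockoff inference replaces the marginal test with a
conditional one: each variant is paired with synthetic "knockoff" copies that
preserve the LD second moments but are conditionally independent of the
phenotype, and a variant is reported only when its association signal beats
its own negative controls, with finite-sample false discovery rate (FDR)
control.

Classically, knockoffs are generated per sample and per variant, which
requires individual-level genotypes. This package works directly on the
score-test Z-scores `Z = G'Y / sqrt(n)` of a standard GWAS: for Gaussian
model-X knockoffs of the genotypes, the implied knockoff Z-scores have an
explicit distribution and can be sampled without ever touching genotypes,

```
Z_knock = P Z + E,   E ~ N(0, V),
```

where both `P` and `V` are functions of the LD matrix `Sigma` alone and can
be precomputed from a reference panel.

## Knockoff model per LD block

For `M` knockoff copies per variant, with `D = diag(s)`:

* `P` is `M` stacked copies of `I - D Sigma^{-1}`;
* `V` has diagonal blocks `C = 2D - D Sigma^{-1} D` and off-diagonal blocks
  `C - D`;
* `s >= 0` solves `minimize sum_j |1 - s_j|` subject to
  `((M + 1) / M) Sigma - D` positive semidefinite.

Under the null `z ~ N(0, Sigma)`, the joint covariance of `(z, z_knock)` is
the exchangeable block matrix with `Sigma` on the diagonal blocks and
`Sigma - D` everywhere else — the defining second-order exchangeability.
The larger `s`, the more the knockoffs decouple from the originals and the
more power the contrast carries.

Two solvers for `s` are provided. `equi` is the closed-form equicorrelated
solution `s_j = min(1, ((M + 1) / M) lambda_min(Sigma))`, the scalable
default. `sdp` solves the full convex program by a log-barrier interior-point
Newton method (the barrier gradient and Hessian of `log det` are
`-diag(A^{-1})` and `-(A^{-1} \circ A^{-1})`, so each step is a `p x p`
solve); on equicorrelated blocks the two coincide, elsewhere `sdp` dominates
in `sum(s)` at `O(p^3)` per Newton step. Both are exposed because the choice
is a genuine trade-off between power and compute, and neither is canonical.

### Numerical choices

* **PSD repair.** Reference-panel LD is noisy and often slightly indefinite.
  `psd_repair()` floors eigenvalues at `1e-10` and rescales to unit diagonal;
  inputs already PSD within tolerance pass through untouched, making the
  repair idempotent.
* **Inverse of Sigma.** Computed once per block with a `1e-10` ridge whenever
  the condition number exceeds `1e12`, since external-panel LD is routinely
  near-singular.
* **Factorizing V.** `V` is `pM x pM` but has exchangeable block structure:
  `V = (Q kron I) blockdiag(B, D, ..., D) (Q' kron I)` with
  `B = D + M(C - D)` and `Q` any orthogonal matrix whose first column is
  `1/sqrt(M)`. The factor therefore needs one `p x p` eigendecomposition
  instead of a `(pM)^3` one. Eigenvalues of the blocks are clipped at
  `1e-10` before the square root — rank-deficient `V` arises legitimately
  (e.g. `p = 2`, `s = 1`, `rho = 0.5` has eigenvalues `4/3` and `0`) — and a
  clip beyond `1e-6` raises a warning because it signals genuinely
  inconsistent LD rather than roundoff.
* **Seeds.** Every sampling function takes an explicit seed; run-level seeds
  derive per-block and per-study sub-seeds deterministically, so block order
  and study order cannot change results, and identical seeds reproduce
  outputs bit for bit.

## The filter

Feature importance is the squared Z-score, `T = z^2`, with knockoff
counterparts `T^m`. Per variant, `kappa` is the index of the largest of the
`M + 1` scores (0 = original), and `tau` is the largest score minus the
median of the remaining `M`. The reported statistic is
`W = tau * 1{kappa = 0}`. The selection threshold is the smallest `t` among
the observed positive `tau` with

```
(1/M + #{kappa >= 1, tau >= t} / M) / #{kappa = 0, tau >= t} <= q,
```

and per-variant q-values minimize the same ratio over `t <= tau_j`
(`q = 1` whenever a knockoff wins). Selection at level `alpha` equals
`q <= alpha` exactly; the suite verifies both against an exhaustive scan.

Three small conventions are deliberate:

* **Ties in kappa** are broken uniformly at random under a seed. On
  quantized scores, deterministically favouring the original would bias the
  false discovery proportion upward; the random break preserves the null
  exchangeability of `kappa`.
* **Median of an even count** uses the midpoint convention.
* **Boundary of the threshold.** The counting in the threshold definition
  includes equality (`tau >= t`), so a variant whose `tau` equals the
  threshold is selected; this is also the unique reading under which
  threshold selection and q-value selection coincide for every target.

The filter is always applied once, globally, to the statistics pooled over
all blocks; per-block thresholds would not control the genome-wide FDR.

## Meta-analysis with sample overlap

The meta Z-score is the weighted sum `sum_k w_k Z_k` over studies. Overlap
between studies makes their score statistics correlated; the package
estimates the `K x K` study correlation from the LD-decorrelated residuals
`z - P1 z = D Sigma^{-1} z` over variants with `|Z| <= 1.96` in both studies
of a pair (the cap strips polygenic signal). Two properties are worth
knowing:

* For true overlap fraction `f` (equal sizes), the score-statistic
  correlation is `f` — but the cap truncates the bivariate normal, so the
  estimate is attenuated towards zero (about 0.39 for `f = 0.5`). The
  attenuation direction makes the dependency factor smaller, hence slightly
  anti-conservative; empirically the FDR experiments below stay controlled.
* The pairwise estimates need not be jointly PSD; the matrix is
  eigenvalue-clipped and rescaled before any optimization.

Study weights are either conventional size weights `sqrt(n_k / N)` or the
overlap-aware solution of `minimize w' corS w` subject to
`sum_k w_k sqrt(n_k) = 1, w >= 0` (a quadratic program, solved with
`quadprog`; a vanishing ridge handles the degenerate duplicated-study case
and returns the minimum-norm symmetric optimum). For case-control studies,
`n_k` may be replaced by `4 / (1/n_case + 1/n_control)`.

Knockoff noise must be inflated when samples are shared: each study's draw
uses `P Z_k + gamma E_k` with the dependency factor

```
gamma = sqrt(1 + N / N_eff - N_eff / N),
```

where `N_eff / N` is `N / sum_ij sqrt(n_i n_j) corS_ij` under size weights
and `sum_k w_k^2 / sum_ij w_i w_j corS_ij` under optimal weights (the latter
is an approximation — the exact form for reweighted studies is intractable —
and is used exactly as stated). Independent studies give `gamma = 1`
identically; `K` identical studies give `N_eff = N / K`. Estimation noise
can push `N_eff` above `N`; it is clipped with a warning.

Variants missing from a study are coded 0 in both the Z-score and its
knockoff (the study simply contributes nothing); no rescaling is applied
because the filter is scale-free. For ancestry-heterogeneous panels, groups
of studies sharing an LD structure get their own `P_l`, `V_l`, `gamma_l`,
and group-level Z-scores combine with fixed `sqrt(n_l / N)` weights —
optimal weighting *across* LD groups is not defined by the theory and is not
invented here.

## Preprocessing conventions

* **p-to-Z.** Literally, `sign x qnorm(p / 2)` is negative for `p < 1`, so
  the implementation uses the evident intent
  `direction * |qnorm(p / 2)|`. `p = 0` is rejected unless the caller
  supplies a floor (`1e-300` suggested).
* **Tight-LD pruning.** Complete-linkage hierarchical clustering on
  `1 - |r|`, cut at `1 - threshold` (default 0.75): complete linkage is the
  one standard linkage whose cut guarantees the within-cluster pairwise
  `|r| >= threshold` property. One representative per cluster is drawn
  uniformly under a seed.
* **Blocks.** Contiguous blocks of at most 1000 variants / 1 Mb by default;
  when a cluster map is supplied, boundaries move so clusters are never
  split, which makes the representative set independent of the blocking.
* **Allele harmonization.** Match on (chr, pos); flip the Z sign when
  ref/alt are swapped; drop strand-ambiguous A/T and C/G variants.
* **Filters.** MAF and MAC thresholds are strict (`> 0.01`, `> 25`).

## The synthetic cohort simulator

Restricted sequencing data cannot ship with a package, so the experiment
harness generates genotypes from a latent-Gaussian model: per sample, two
independent haplotype vectors with block-AR(1) latent correlation
(`rho = 0.5`, blocks of 10 by default) are thresholded at the MAF-matched
normal quantile and summed to a 0/1/2 dosage. Thresholding attenuates the
latent correlation; the knockoff model is always built from the *realized*
dosage correlations, never the latent ones, so no attenuation formula is
assumed anywhere.

Phenotypes follow the two-covariate designs: quantitative
`Y = X1 + sum_j beta_j G_j + eps` with `eps ~ N(0, 3)`, and dichotomous
`logit(mu) = beta0 + X1 + X2 + sum_j beta_j G_j` with `beta0` calibrated by
root-finding on the sample mean of `mu` so the marginal prevalence is 10%
(tolerance well under 0.002 at the default sizes). Ten causal variants carry
effects `beta_j = a / sqrt(2 m_j (1 - m_j))` with `a` fixed so the causal
variance totals 1. Only `X1` is adjusted in the analysis; `X2` and `eps`
deliberately act as unobserved covariates, so the experiments also probe
robustness to model misspecification. Two studies of `n_study` samples are
drawn from a pool with a configurable shared fraction (0, 25, 50%).

The default profile is desk-scale — 1000 samples/study, 300 variants, 100
replicates — chosen so the full grid of experiments runs on a single CPU in
minutes; the published-scale profile (2500 / 2000 / 1000) is one
`sim_config()` call away. Because the harness's LD panel is the in-sample
pool itself (`n_pool >> p`), it passes `shrinkage = 0.01` to
`estimate_ld()` rather than the 0.1 default that suits external panels of a
few hundred samples: only a numerical-stability ridge is warranted when LD
is estimated from thousands of in-sample genotypes.

What the simulator does *not* emulate: real LD is longer-ranged and blockier
than AR(1); rare variants, population structure and imputation error are
absent. Study-specific coverage gaps can be injected with
`sim_config(unobserved_frac = ...)`, which masks a random subset of variants
per study (their Z-scores and knockoffs are coded zero, never rescaled).
Passing FDR/power tests on this generator therefore demonstrates the
statistical machinery under a matched LD panel, not robustness to the
panel-mismatch failure mode, which is the method's documented weakness.

```{r example}
library(zknock)
cfg <- sim_config(overlap = 0.25, trait = "quantitative",
                  replicates = 100, seed = 2024)
res <- run_overlap_experiment(cfg)
tidy(res)        # mean power / FDP per target level
autoplot(res)    # power and FDP against the target grid
```

## Known limitations

* Inter-block LD is not modelled; long-range LD can leak confounding across
  block boundaries.
* FDR control degrades when the LD panel mismatches the study cohort; the
  per-block `lambda_min` and shrinkage diagnostics in the model objects are
  there to be monitored.
* The study-correlation cap attenuates overlap estimates (see above); with
  genome-wide input the estimate is precise but remains biased towards
  independence.
* Group knockoffs (exchangeability at the cluster level) are out of scope;
  tight-LD clusters are represented by a single pruned representative, so
  power is lost when the causal variant is not the representative.
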