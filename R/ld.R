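#' LD matrix container
#'
#' Wraps a p x p genotype correlation matrix for one genomic block, together
#' with its variant identifiers, the shrinkage applied during estimation and a
#' flag recording whether a positive-semidefinite (PSD) repair was needed.
#' Downstream knockoff model construction requires an `ld_matrix`.
#'
#' @param R Symmetric numeric matrix of pairwise genotype correlations with
#'   unit diagonal. Entries must lie in `[-1, 1]`.
#' @param variants Character vector of variant identifiers (defaults to the
#'   column names of `R`, or `v1..vp`).
#' @param shrinkage Shrinkage weight in `[0, 1)` that was applied towards the
#'   identity during estimation (0 if none).
#' @param repaired Logical; whether [psd_repair()] modified the matrix.
#'
#' @return An object of class `ld_matrix`: the matrix with attributes
#'   `variants`, `shrinkage`, `repaired`.
#' @seealso [estimate_ld()], [psd_repair()]
#' @export
ld_matrix <- function(R, variants = NULL, shrinkage = 0, repaired = FALSE) {
  check_symmetric(R, arg = "R")
  p <- nrow(R)
  if (is.null(variants)) variants <- colnames(R) %||% paste0("v", seq_len(p))
  if (length(variants) != p) abort("`variants` must have one id per row of `R`.")
  if (max(abs(diag(R) - 1)) > 1e-8) abort("`R` must have unit diagonal.")
  if (max(abs(R)) > 1 + 1e-8) abort("correlations must lie in [-1, 1].")
  structure(R,
    variants = as.character(variants),
    shrinkage = shrinkage, repaired = repaired,
    dimnames = list(variants, variants),
    class = c("ld_matrix", "matrix", "array")
  )
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf(
    "<ld_matrix> %d variants, shrinkage %.3g, repaired: %s\n",
    nrow(x), attr(x, "shrinkage"), attr(x, "repaired")
  ))
  invisible(x)
}

#' Repair an indefinite correlation matrix
#'
#' LD estimated from an external reference panel is noisy and often slightly
#' indefinite. The repair floors the eigenvalues at `floor`, reconstructs the
#' matrix and rescales it back to unit diagonal. Already-PSD input is returned
#' unchanged (`repaired = FALSE`), so the operation is idempotent.
#'
#' @param R Symmetric square matrix (correlation scale).
#' @param floor Eigenvalue floor; default `1e-10`.
#' @inheritParams ld_matrix
#' @return An [ld_matrix()].
#' @export
psd_repair <- function(R, floor = 1e-10, variants = NULL, shrinkage = 0) {
  check_symmetric(R, arg = "R")
  R <- unclass((R + t(R)) / 2)
  ev <- eigen(R, symmetric = TRUE)
  # treat PSD-within-tolerance input as already repaired (idempotence:
  # rescaling after an eigenvalue clip can leave lambda_min a hair under
  # the floor, which is harmless)
  if (min(ev$values) >= min(floor, 0) - 1e-9) {
    return(ld_matrix(R, variants = variants, shrinkage = shrinkage,
                     repaired = FALSE))
  }
  vals <- pmax(ev$values, floor)
  A <- ev$vectors %*% (vals * t(ev$vectors))
  A <- (A + t(A)) / 2
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  diag(A) <- 1
  A <- pmin(pmax(A, -1), 1)
  ld_matrix(A, variants = variants, shrinkage = shrinkage, repaired = TRUE)
}

#' Estimate an LD matrix from a genotype panel
#'
#' Computes the shrinkage correlation matrix
#' `R = (1 - lambda) * cor(G) + lambda * I` from a block of reference-panel
#' dosages, after centering and standardizing each variant, then PSD-repairs
#' the result. Missing dosages must be imputed beforehand (see
#' [read_panel_vcf()] / [read_panel_plink()], which mean-impute).
#'
#' @param G Numeric matrix of dosages (samples x variants), values 0/1/2 or
#'   imputed in between.
#' @param shrinkage Shrinkage weight `lambda` in `[0, 1)`; default 0.1, chosen
#'   for external panels of a few hundred samples.
#' @param variants Optional variant identifiers (defaults to column names).
#' @return An [ld_matrix()].
#' @export
estimate_ld <- function(G, shrinkage = 0.1, variants = NULL) {
  if (!is.matrix(G)) G <- as.matrix(G)
  if (nrow(G) < 2) abort("LD estimation needs at least 2 samples.")
  if (shrinkage < 0 || shrinkage >= 1) abort("`shrinkage` must be in [0, 1).")
  mono <- which(apply(G, 2, function(x) var(x) == 0 || !is.finite(var(x))))
  if (length(mono) > 0) {
    ids <- (variants %||% colnames(G) %||% as.character(seq_len(ncol(G))))[mono]
    abort(paste0(
      "monomorphic variant(s) in panel, filter them first: ",
      paste(head(ids, 5), collapse = ", ")
    ))
  }
  R <- (1 - shrinkage) * cor(G) + shrinkage * diag(ncol(G))
  psd_repair(R, variants = variants %||% colnames(G), shrinkage = shrinkage)
}
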