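#' Read a GWAS summary-statistics file
#'
#' Tab-separated with a header; required columns `CHR`, `POS`, `REF`, `ALT`
#' and either `Z` or the pair `P`, `DIR` (two-sided p-value and direction of
#' effect, converted via [z_from_pvalue()]). Optional: `N`, `N_CASE`,
#' `N_CONTROL`. Gzip input is transparent. Duplicate
#' (chr, pos, ref, alt) keys are rejected.
#'
#' @param path File path (possibly `.gz`).
#' @param p_floor Floor applied to p-values of 0 (default `1e-300`).
#' @return Tibble with columns `chr`, `pos`, `ref`, `alt`, `z`, `variant`
#'   (chr:pos:ref:alt), plus `n`/`n_case`/`n_control` when present.
#' @export
read_sumstats <- function(path, p_floor = 1e-300) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(df) <- toupper(names(df))
  need <- c("CHR", "POS", "REF", "ALT")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"Z" %in% names(df)) {
    if (!all(c("P", "DIR") %in% names(df))) {
      abort("need either a Z column or both P and DIR columns.")
    }
    bad <- which(!is.finite(df$P) | df$P > 1 | df$P < 0 | df$DIR == 0)
    if (length(bad) > 0) {
      abort(paste0("unparseable P/DIR at line(s): ",
                   paste(head(bad + 1, 5), collapse = ", ")))
    }
    df$Z <- z_from_pvalue(df$P, df$DIR, p_floor = p_floor)
  }
  bad <- which(!is.finite(df$Z))
  if (length(bad) > 0) {
    abort(paste0("non-finite Z at line(s): ",
                 paste(head(bad + 1, 5), collapse = ", ")))
  }
  out <- tibble(
    chr = as.character(df$CHR), pos = as.integer(df$POS),
    ref = as.character(df$REF), alt = as.character(df$ALT),
    z = as.numeric(df$Z)
  )
  out$variant <- paste(out$chr, out$pos, out$ref, out$alt, sep = ":")
  if (anyDuplicated(out$variant)) {
    dup <- out$variant[duplicated(out$variant)]
    abort(paste0("duplicated variant key(s): ", paste(head(dup, 3), collapse = ", ")))
  }
  if ("N" %in% names(df)) out$n <- as.numeric(df$N)
  if ("N_CASE" %in% names(df)) out$n_case <- as.numeric(df$N_CASE)
  if ("N_CONTROL" %in% names(df)) out$n_control <- as.numeric(df$N_CONTROL)
  dplyr::arrange(out, .data$chr, .data$pos)
}

#' Read a reference genotype panel
#'
#' `read_panel_vcf()` reads a (optionally bgzipped) VCF via the vcfR package
#' and converts GT fields to 0/1/2 dosages; `read_panel_plink()` reads PLINK
#' bed/bim/fam (SNP-major bed format). Missing genotypes are mean-imputed
#' per variant, as required before LD estimation.
#'
#' @param path Path to the `.vcf`/`.vcf.gz` file, or the PLINK prefix (or
#'   `.bed` path).
#' @return List with `G` (samples x variants dosage matrix) and `variants`
#'   (tibble: `chr`, `pos`, `ref`, `alt`, `variant`).
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF panels requires the vcfR package.")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | x %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/"), function(a) {
             sum(a == "1")
           }, numeric(1)))
  }
  G <- t(apply(gt, 1, count_alt))
  G <- t(G)  # samples x variants
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  variants <- tibble(
    chr = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  variants$variant <- paste(variants$chr, variants$pos, variants$ref,
                            variants$alt, sep = ":")
  colnames(G) <- variants$variant
  list(G = G, variants = variants)
}

#' @rdname read_panel_vcf
#' @export
read_panel_plink <- function(path) {
  prefix <- sub("\\.bed$", "", path)
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) abort(sprintf("missing PLINK file: %s", f))
  }
  bim_df <- readr::read_table(bim, col_names = c("chr", "id", "cm", "pos",
                                                 "alt", "ref"),
                              show_col_types = FALSE, progress = FALSE)
  n_var <- nrow(bim_df)
  n_sam <- length(readLines(fam))
  raw <- readBin(bed, "raw", n = file.size(bed))
  if (!identical(as.integer(raw[1:3]), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a SNP-major PLINK bed file.")
  }
  bytes_per_var <- ceiling(n_sam / 4)
  body <- raw[-(1:3)]
  if (length(body) != bytes_per_var * n_var) {
    abort("bed file size inconsistent with bim/fam.")
  }
  # 2-bit codes: 00 hom alt1(=2 copies), 01 missing, 10 het, 11 hom alt2(=0)
  lut <- c(`0` = 2, `1` = NA, `2` = 1, `3` = 0)
  G <- matrix(NA_real_, n_sam, n_var)
  for (j in seq_len(n_var)) {
    vb <- as.integer(body[(j - 1) * bytes_per_var + seq_len(bytes_per_var)])
    codes <- c(
      bitwAnd(vb, 3L), bitwAnd(bitwShiftR(vb, 2L), 3L),
      bitwAnd(bitwShiftR(vb, 4L), 3L), bitwAnd(bitwShiftR(vb, 6L), 3L)
    )
    ord <- as.vector(t(matrix(codes, ncol = 4)))
    G[, j] <- lut[as.character(ord[seq_len(n_sam)])]
  }
  G <- apply(G, 2, function(g) {
    g[is.na(g)] <- mean(g, na.rm = TRUE)
    g
  })
  variants <- tibble(
    chr = as.character(bim_df$chr), pos = as.integer(bim_df$pos),
    ref = bim_df$ref, alt = bim_df$alt
  )
  variants$variant <- paste(variants$chr, variants$pos, variants$ref,
                            variants$alt, sep = ":")
  colnames(G) <- variants$variant
  list(G = G, variants = variants)
}

#' Single- or multi-study knockoff analysis from aligned inputs
#'
#' End-to-end analysis of one or more studies on one set of genomic blocks:
#' per block, build (or reuse) the knockoff model, form meta Z-scores and
#' their knockoffs (a single study reduces to plain knockoff sampling with
#' `gamma = 1`), pool the feature statistics over all blocks, and run the
#' knockoff filter once, globally. Per-block thresholds are never used.
#'
#' @param Z p x K matrix (or vector for one study) of aligned Z-scores;
#'   NA = unobserved.
#' @param models Named list of [knockoff_model()]s in block order; their
#'   variant counts must tile the rows of `Z`.
#' @param n Length-K study sample sizes.
#' @param M Knockoff copies (must match the models).
#' @param target_fdr Target FDR for the filter.
#' @param weights `"size"` or `"optimal"`.
#' @param seed Integer seed; per-block seeds are derived from it so block
#'   order cannot change results.
#' @param variants Optional variant ids for the pooled rows.
#' @param min_shared Minimum jointly observed null variants per study pair
#'   for the study-correlation estimate (see
#'   [estimate_study_correlation()]).
#' @return A list of class `ghost_result`: `selection` (a
#'   [knockoff_select()] tibble), `weights` (a [meta_weights()] or NULL for
#'   K = 1), `corS`, and `manifest` (run parameters).
#' @export
ghost_analyze <- function(Z, models, n, M = 5, target_fdr = 0.1,
                          weights = c("size", "optimal"), seed = 1L,
                          variants = NULL, min_shared = 100) {
  weights <- match.arg(weights)
  if (inherits(models, "knockoff_model")) models <- list(block1 = models)
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1)
  p_blocks <- vapply(models, function(m) m$p, numeric(1))
  if (sum(p_blocks) != nrow(Z)) {
    abort(sprintf(
      "model cache covers %d variants but sumstats have %d rows",
      sum(p_blocks), nrow(Z)
    ))
  }
  K <- ncol(Z)
  panel <- study_panel(Z, n = n, variants = variants,
                       drop_unobserved = FALSE)
  if (any(rowSums(panel$mask) == 0)) {
    warn(sprintf("%d variant(s) observed in no study; they are carried as 0",
                 sum(rowSums(panel$mask) == 0)))
  }
  if (K > 1) {
    corS <- estimate_study_correlation(panel, unname(models),
                                       min_shared = min_shared)
    wts <- meta_weights(corS, n, scheme = weights)
  } else {
    corS <- matrix(1, 1, 1)
    wts <- meta_weights(corS, n, scheme = "size")
  }
  stats_blocks <- list()
  off <- 0
  for (bi in seq_along(models)) {
    m <- models[[bi]]
    idx <- off + seq_len(m$p)
    sub <- study_panel(panel$Z[idx, , drop = FALSE], n = n,
                       mask = panel$mask[idx, , drop = FALSE],
                       variants = panel$variants[idx],
                       drop_unobserved = FALSE)
    z_meta <- meta_z(sub, wts)
    zk <- meta_knockoff_z(sub, wts, m, seed = derive_seed(seed, bi))
    stats_blocks[[bi]] <- feature_stats(z_meta, zk,
                                        tie_seed = derive_seed(seed, 10000 + bi),
                                        variants = sub$variants)
    off <- off + m$p
  }
  M_used <- attr(stats_blocks[[1]], "M")
  stats <- dplyr::bind_rows(lapply(stats_blocks, as_tibble))
  stats <- structure(stats, M = M_used,
                     class = c("feature_stats", class(stats)))
  sel <- knockoff_select(stats, target_fdr = target_fdr)
  manifest <- list(
    K = K, M = M_used, target_fdr = target_fdr, weights = weights,
    seed = as.integer(seed), n = n, gamma = wts$gamma, N_eff = wts$N_eff,
    corS = corS, w = wts$w,
    blocks = length(models), p = nrow(Z),
    # LD mismatch is the main failure mode; keep per-block diagnostics
    block_diagnostics = data.frame(
      block = names(models) %||% as.character(seq_along(models)),
      p = vapply(models, function(m) m$p, numeric(1)),
      lambda_min = vapply(models, function(m) m$lambda_min, numeric(1)),
      shrinkage = vapply(models, function(m) m$shrinkage, numeric(1)),
      row.names = NULL
    )
  )
  structure(list(selection = sel, weights = wts, corS = corS,
                 manifest = manifest),
            class = "ghost_result")
}

#' @export
print.ghost_result <- function(x, ...) {
  g <- glance(x$selection)
  cat(sprintf(
    "<ghost_result> %d studies, %d variants, %d selected at FDR %.2f (gamma %.3f)\n",
    x$manifest$K, g$n_variants, g$n_selected, g$target_fdr, x$manifest$gamma
  ))
  invisible(x)
}

#' Run the file-based analysis pipeline
#'
#' Thin orchestration over the package functions: read one or more
#' summary-statistics files, align them on shared variants, read a cached
#' knockoff model directory (see [write_model_cache()]), run
#' [ghost_analyze()], and write the results table plus a JSON run manifest
#' (seeds, weights, gamma, study correlations). Reruns with an identical
#' config and seed are bitwise identical.
#'
#' @param sumstats Character vector of summary-statistics paths.
#' @param model_dir Directory holding the cached knockoff models.
#' @param out_dir Output directory.
#' @param n Study sample sizes (taken from the files' `N` column when
#'   omitted).
#' @param target_fdr,weights,seed Passed to [ghost_analyze()].
#' @return The [ghost_analyze()] result, invisibly.
#' @export
run_pipeline <- function(sumstats, model_dir, out_dir, n = NULL,
                         target_fdr = 0.1, weights = "size", seed = 1L) {
  studies <- lapply(sumstats, read_sumstats)
  models <- read_model_cache(model_dir)
  model_variants <- unlist(lapply(models, function(m) m$variants),
                           use.names = FALSE)
  Z <- matrix(NA_real_, length(model_variants), length(studies))
  rownames(Z) <- model_variants
  for (k in seq_along(studies)) {
    idx <- match(studies[[k]]$variant, model_variants)
    hit <- !is.na(idx)
    if (sum(hit) == 0) {
      abort(sprintf(
        "study %d: none of %d variants match the %d model-cache variants",
        k, nrow(studies[[k]]), length(model_variants)
      ))
    }
    Z[idx[hit], k] <- studies[[k]]$z[hit]
  }
  if (is.null(n)) {
    n <- vapply(studies, function(s) {
      if (!"n" %in% names(s)) abort("supply `n`: no N column in sumstats.")
      stats::median(s$n, na.rm = TRUE)
    }, numeric(1))
  }
  res <- ghost_analyze(Z, models, n = n, target_fdr = target_fdr,
                       weights = weights, seed = seed,
                       variants = model_variants)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  info <- dplyr::bind_rows(lapply(studies, function(s) {
    dplyr::select(s, "variant", "chr", "pos", "ref", "alt")
  }))
  info <- dplyr::distinct(info, .data$variant, .keep_all = TRUE)
  write_results(res$selection, file.path(out_dir, "results.tsv"),
                variant_info = info)
  jsonlite::write_json(
    res$manifest[c("K", "M", "target_fdr", "weights", "seed", "n",
                   "gamma", "N_eff", "w", "blocks", "p",
                   "block_diagnostics")],
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(res)
}
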