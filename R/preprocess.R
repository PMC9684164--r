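#' Z-score from a p-value and effect direction
#'
#' Inverse-normal transformation of a two-sided p-value, signed by the
#' direction of effect: `direction * |qnorm(p / 2)|`. `p = 1` maps to 0.
#' A p-value of exactly 0 is rejected unless a floor is supplied
#' (`p_floor = 1e-300` is a sensible choice near the double limit).
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param direction Sign(s) of the effect (any nonzero number; only the sign
#'   is used).
#' @param p_floor Optional lower floor applied to `p` before transforming.
#' @return Numeric Z-score(s).
#' @export
z_from_pvalue <- function(p, direction, p_floor = NULL) {
  if (length(direction) == 1) direction <- rep(direction, length(p))
  if (any(direction == 0)) abort("`direction` must be nonzero.")
  if (!is.null(p_floor)) p <- pmax(p, p_floor)
  if (any(p <= 0)) {
    abort("p-value of 0; supply `p_floor` (e.g. 1e-300) to cap it.")
  }
  if (any(p > 1)) abort("p-values must be in (0, 1].")
  sign(direction) * abs(qnorm(p / 2))
}

#' Filter variants on MAF and MAC
#'
#' Removes rows failing the strict thresholds `maf > maf_min` or
#' `mac > mac_min` (both strict, matching the usual ">1% MAF" and
#' "minor allele count > 25" conventions). A column absent from the table is
#' not filtered on.
#'
#' @param table Tibble with per-variant rows; columns `maf` and/or `mac`.
#' @param maf_min Minor allele frequency threshold (strict >); default 0.01.
#' @param mac_min Minor allele count threshold (strict >); default 0.
#' @return The filtered tibble.
#' @export
filter_variants <- function(table, maf_min = 0.01, mac_min = 0L) {
  n0 <- nrow(table)
  if ("maf" %in% names(table)) {
    table <- dplyr::filter(table, .data$maf > maf_min)
  }
  if ("mac" %in% names(table)) {
    table <- dplyr::filter(table, .data$mac > mac_min)
  }
  if (nrow(table) == 0) abort("no variants left after MAF/MAC filtering.")
  if (nrow(table) < n0) {
    rlang::inform(sprintf("filter_variants: kept %d of %d variants",
                          nrow(table), n0))
  }
  table
}

#' Prune tightly linked variants by hierarchical clustering
#'
#' Complete-linkage hierarchical clustering on distance `1 - |r|`, cut at
#' height `1 - threshold`, so that every pair inside a cluster has
#' `|r| >= threshold`. One representative per cluster is drawn uniformly at
#' random under `seed`; only representatives enter the knockoff analysis,
#' ensuring every variant has a highly correlated proxy in the analysis.
#'
#' @param Sigma An [ld_matrix()] or correlation matrix.
#' @param threshold Within-cluster correlation floor; default 0.75.
#' @param seed Integer seed for the representative draw.
#' @return Object of class `cluster_map`: tibble with columns `variant`,
#'   `cluster`, `representative` (logical), plus attribute `threshold`.
#' @export
prune_clusters <- function(Sigma, threshold = 0.75, seed = 1L) {
  R <- unclass(Sigma)
  variants <- attr(Sigma, "variants") %||% colnames(R) %||%
    paste0("v", seq_len(nrow(R)))
  p <- nrow(R)
  if (p == 1) {
    cl <- 1L
  } else {
    d <- as.dist(1 - abs(R))
    hc <- hclust(d, method = "complete")
    cl <- cutree(hc, h = 1 - threshold)
  }
  reps <- withr::with_seed(as.integer(seed), {
    vapply(split(seq_len(p), cl), function(idx) {
      if (length(idx) == 1) idx else idx[sample.int(length(idx), 1)]
    }, numeric(1))
  })
  out <- tibble(
    variant = variants,
    cluster = as.integer(cl),
    representative = seq_len(p) %in% reps
  )
  structure(out, threshold = threshold,
            class = c("cluster_map", class(out)))
}

#' Partition sorted variants into contiguous analysis blocks
#'
#' Greedy partition of a sorted variant table into contiguous, non-overlapping
#' blocks of at most `block_max` variants spanning at most `block_span` bp.
#' When a [prune_clusters()] map is supplied, boundaries are moved so that no
#' cluster is split across blocks (a cluster larger than `block_max` stays in
#' one block).
#'
#' @param table Tibble sorted by (`chr`, `pos`) with those columns.
#' @param block_span Maximum block span in bp; default 1e6.
#' @param block_max Maximum variants per block; default 1000.
#' @param cluster_map Optional [prune_clusters()] result aligned to `table`
#'   rows (same order).
#' @return The input tibble with an added integer `block` column.
#' @export
partition_blocks <- function(table, block_span = 1e6, block_max = 1000,
                             cluster_map = NULL) {
  ord <- order(table$chr, table$pos)
  if (any(diff(ord) < 0)) abort("`table` must be sorted by (chr, pos).")
  p <- nrow(table)
  # atomic units: contiguous runs that must stay in one block
  unit_key <- if (is.null(cluster_map)) {
    seq_len(p)
  } else {
    cumsum(c(TRUE, paste(table$chr, cluster_map$cluster)[-1] !=
                     paste(table$chr, cluster_map$cluster)[-p]))
  }
  runs <- rle(paste(table$chr, unit_key))$lengths
  ends <- cumsum(runs)
  starts <- ends - runs + 1L
  block <- integer(p)
  b <- 1L
  blk_start <- starts[1]
  for (u in seq_along(runs)) {
    open_new <- FALSE
    if (starts[u] > blk_start) {
      same_chr <- table$chr[starts[u]] == table$chr[blk_start]
      n_if_added <- ends[u] - blk_start + 1L
      span_if_added <- table$pos[ends[u]] - table$pos[blk_start]
      open_new <- !same_chr || n_if_added > block_max ||
        span_if_added > block_span
    }
    if (open_new) {
      b <- b + 1L
      blk_start <- starts[u]
    }
    block[starts[u]:ends[u]] <- b
  }
  dplyr::mutate(table, block = block)
}

#' Harmonize study alleles against a reference variant table
#'
#' Matches study rows to the reference on (`chr`, `pos`); Z-scores whose
#' ref/alt are swapped relative to the reference are sign-flipped;
#' strand-ambiguous A/T and C/G variants are dropped with a warning, as are
#' rows whose alleles match neither orientation.
#'
#' @param study Tibble with columns `chr`, `pos`, `ref`, `alt`, `z`.
#' @param reference Tibble with columns `chr`, `pos`, `ref`, `alt`.
#' @return The harmonized study tibble, aligned to reference orientation.
#' @export
harmonize_alleles <- function(study, reference) {
  ambiguous <- function(a, b) {
    (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "C" & b == "G") | (a == "G" & b == "C")
  }
  amb <- ambiguous(toupper(study$ref), toupper(study$alt))
  if (any(amb)) {
    warn(sprintf("dropping %d strand-ambiguous (A/T, C/G) variant(s)", sum(amb)))
    study <- study[!amb, , drop = FALSE]
  }
  merged <- dplyr::inner_join(
    study,
    dplyr::select(reference, "chr", "pos", ref_panel = "ref", alt_panel = "alt"),
    by = c("chr", "pos")
  )
  same <- merged$ref == merged$ref_panel & merged$alt == merged$alt_panel
  flip <- merged$ref == merged$alt_panel & merged$alt == merged$ref_panel
  bad <- !same & !flip
  if (any(bad)) {
    warn(sprintf("dropping %d variant(s) with mismatched alleles", sum(bad)))
  }
  merged <- merged[!bad, , drop = FALSE]
  flip <- merged$ref == merged$alt_panel & merged$alt == merged$ref_panel
  merged$z[flip] <- -merged$z[flip]
  merged$ref[flip] <- merged$ref_panel[flip]
  merged$alt[flip] <- merged$alt_panel[flip]
  dplyr::select(merged, -"ref_panel", -"alt_panel")
}
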