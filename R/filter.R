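#' Feature statistics for the multiple-knockoff filter
#'
#' Converts original and knockoff Z-scores into the per-variant statistics the
#' filter operates on. The importance score is the squared Z-score,
#' `T = z^2`, with knockoff counterparts `T^m = z_knock[, m]^2`. Then, per
#' variant:
#'
#' * `kappa`: index (0 = original, 1..M = knockoff copy) of the largest of the
#'   `M + 1` scores; exact ties are broken uniformly at random under
#'   `tie_seed`, which preserves the null exchangeability of `kappa`.
#' * `tau`: largest score minus the median of the remaining `M` ordered
#'   scores (midpoint convention for even counts).
#' * `W`: `(T - median_m T^m) * 1{T >= max_m T^m}`, identically
#'   `tau * 1{kappa == 0}`; positive `W` is evidence of a direct effect.
#'
#' @param z Numeric vector of original Z-scores (length p).
#' @param z_knock p x M matrix of knockoff Z-scores (or a `knockoff_z`
#'   object, in which case `z` is taken from it).
#' @param tie_seed Integer seed for random tie breaking.
#' @param variants Optional variant identifiers.
#' @return An object of class `feature_stats`: tibble with columns `variant`,
#'   `z`, `T`, `kappa`, `tau`, `W`, plus attribute `M`.
#' @export
feature_stats <- function(z, z_knock = NULL, tie_seed = 1L,
                          variants = NULL) {
  if (inherits(z, "knockoff_z")) {
    z_knock <- z$z_knock
    z <- z$z
  }
  if (!is.matrix(z_knock)) z_knock <- as.matrix(z_knock)
  p <- length(z)
  M <- ncol(z_knock)
  if (nrow(z_knock) != p) abort("`z_knock` must have one row per entry of `z`.")
  if (M < 1) abort("at least one knockoff copy is required (M >= 1).")
  bad <- which(!is.finite(z) | rowSums(!is.finite(z_knock)) > 0)
  if (length(bad) > 0) {
    abort(paste0(
      "non-finite Z-scores for variant(s): ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  variants <- variants %||% names(z) %||% paste0("v", seq_len(p))
  T0 <- z^2
  Tk <- z_knock^2
  scores <- cbind(T0, Tk)
  kappa <- withr::with_seed(as.integer(tie_seed), {
    apply(scores, 1, function(x) {
      idx <- which(x == max(x))
      if (length(idx) > 1) idx <- sample(idx, 1)
      idx - 1L
    })
  })
  tau <- apply(scores, 1, function(x) {
    ord <- sort(x, decreasing = TRUE)
    ord[1] - median(ord[-1])
  })
  med_k <- apply(Tk, 1, median)
  W <- (T0 - med_k) * as.numeric(T0 >= apply(Tk, 1, max))
  out <- tibble(
    variant = variants, z = as.numeric(z), T = T0,
    kappa = as.integer(kappa), tau = tau, W = W
  )
  structure(out, M = M, class = c("feature_stats", class(out)))
}

#' Data-dependent selection threshold of the knockoff filter
#'
#' Scans the observed positive `tau` values (the criterion is piecewise
#' constant between them) for the smallest `t` with
#' `(1/M + (1/M) * #\{kappa_j >= 1, tau_j >= t\}) / #\{kappa_j = 0, tau_j >= t\}
#' <= target_fdr`. Returns `Inf` when no `t` qualifies (nothing selected).
#'
#' @param kappa Integer vector in `0..M`.
#' @param tau Nonnegative numeric vector.
#' @param target_fdr Target FDR `q` in `(0, 1)`.
#' @param M Number of knockoff copies.
#' @return The threshold (a `tau` value, or `Inf`).
#' @export
knockoff_threshold <- function(kappa, tau, target_fdr, M) {
  if (length(kappa) == 0) abort("empty input.")
  if (target_fdr <= 0 || target_fdr >= 1) abort("`target_fdr` must be in (0, 1).")
  cand <- sort(unique(tau[tau > 0]))
  if (length(cand) == 0) return(Inf)
  ratios <- filter_ratio(cand, kappa, tau, M)
  ok <- which(ratios <= target_fdr)
  if (length(ok) == 0) Inf else cand[min(ok)]
}

# Knockoff FDR estimate at each candidate threshold t.
filter_ratio <- function(t_grid, kappa, tau, M) {
  vapply(t_grid, function(t) {
    num <- 1 / M + sum(kappa >= 1 & tau >= t) / M
    den <- sum(kappa == 0 & tau >= t)
    if (den == 0) Inf else num / den
  }, numeric(1))
}

#' Per-variant q-values for the knockoff filter
#'
#' `q_j = min over t <= tau_j` of the knockoff FDR estimate, capped at 1, for
#' variants whose original score beats all knockoffs (`kappa = 0`); variants
#' with `kappa != 0` get `q = 1` and are never selected. Selecting
#' `q_j <= alpha` is equivalent to thresholding at
#' [knockoff_threshold()] with `target_fdr = alpha`.
#'
#' @inheritParams knockoff_threshold
#' @return Numeric vector of q-values in `(0, 1]`.
#' @export
q_values <- function(kappa, tau, M) {
  if (length(kappa) == 0) abort("empty input.")
  q <- rep(1, length(kappa))
  cand <- sort(unique(tau[tau > 0]))
  if (length(cand) == 0) return(q)
  ratios <- pmin(cummin(filter_ratio(cand, kappa, tau, M)), 1)
  idx <- which(kappa == 0 & tau > 0)
  pos <- findInterval(tau[idx], cand)
  q[idx] <- ratios[pos]
  q
}

#' Select variants at a target FDR
#'
#' Applies the knockoff filter to pooled feature statistics (the filter is a
#' global function of the pooled `kappa`/`tau`, so per-block statistics are
#' simply concatenated first). A variant is selected when `kappa = 0` and
#' `tau >= threshold`, equivalently when `q <= target_fdr`.
#'
#' @param stats A [feature_stats()] tibble (possibly row-bound over blocks).
#' @param target_fdr Target FDR in `(0, 1)`.
#' @return An object of class `knockoff_selection`: the `stats` tibble with
#'   added columns `qvalue` and `selected`, plus attributes `threshold`,
#'   `target_fdr`, `M`.
#' @export
knockoff_select <- function(stats, target_fdr = 0.1) {
  M <- attr(stats, "M")
  if (is.null(M)) abort("`stats` must come from feature_stats().")
  thr <- knockoff_threshold(stats$kappa, stats$tau, target_fdr, M)
  q <- q_values(stats$kappa, stats$tau, M)
  out <- dplyr::mutate(
    as_tibble(stats),
    qvalue = q,
    selected = .data$kappa == 0L & .data$tau >= thr
  )
  structure(out,
    threshold = thr, target_fdr = target_fdr, M = M,
    class = c("knockoff_selection", class(out))
  )
}

#' @rdname knockoff_select
#' @param x A `knockoff_selection`.
#' @param ... Unused.
#' @export
glance.knockoff_selection <- function(x, ...) {
  tibble(
    n_variants = nrow(x), n_selected = sum(x$selected),
    threshold = attr(x, "threshold"), target_fdr = attr(x, "target_fdr"),
    M = attr(x, "M")
  )
}

#' Plot W statistics of a selection
#'
#' Manhattan-style plot of the W statistic per variant, colored by selection
#' status, with the filter threshold drawn as a dashed line.
#'
#' @param object A `knockoff_selection`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knockoff_selection <- function(object, ...) {
  df <- as_tibble(object)
  df$index <- seq_len(nrow(df))
  thr <- attr(object, "threshold")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$W,
                                        colour = .data$selected)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "variant index", y = "W statistic",
                  colour = "selected") +
    ggplot2::theme_minimal()
  if (is.finite(thr)) {
    p <- p + ggplot2::geom_hline(yintercept = thr, linetype = "dashed")
  }
  p
}

#' Write a per-variant results table
#'
#' Tab-separated output with one row per analyzed representative variant:
#' CHR, POS, REF, ALT, Z, W, KAPPA, TAU, QVALUE, SELECTED (0/1). Variant
#' coordinates are taken from `variant_info` (matched by variant id) when
#' given, otherwise left NA.
#'
#' @param selection A [knockoff_select()] result.
#' @param path Output file.
#' @param variant_info Optional tibble with columns `variant`, `chr`, `pos`,
#'   `ref`, `alt`.
#' @return The written tibble, invisibly.
#' @export
write_results <- function(selection, path, variant_info = NULL) {
  df <- as_tibble(selection)
  if (!is.null(variant_info)) {
    df <- dplyr::left_join(df, variant_info, by = "variant")
  } else {
    df$chr <- NA_character_; df$pos <- NA_integer_
    df$ref <- NA_character_; df$alt <- NA_character_
  }
  out <- tibble(
    CHR = df$chr, POS = df$pos, REF = df$ref, ALT = df$alt,
    Z = df$z, W = df$W, KAPPA = df$kappa, TAU = df$tau,
    QVALUE = df$qvalue, SELECTED = as.integer(df$selected)
  )
  readr::write_tsv(out, path)
  invisible(out)
}
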