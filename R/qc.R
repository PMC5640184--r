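#' Relative log expression summary per sample
#'
#' RLE deviates each value from its feature's median across samples:
#' `expr[i, j] - median_j(expr[i, ])`. Well-behaved arrays have RLE
#' distributions centred on zero with comparable spread; a shifted median or
#' inflated IQR marks a suspect sample.
#'
#' @param expr An [expr_set()] with at least two samples.
#' @return Tibble with one row per sample: `sample_id`, `rle_median`,
#'   `rle_iqr`.
#' @export
compute_rle <- function(expr) {
  stopifnot(inherits(expr, "expr_set"))
  if (ncol(expr$values) < 2) {
    abort("RLE needs at least two samples (the feature medians are the reference).")
  }
  dev <- expr$values - apply(expr$values, 1, median)
  tibble::tibble(
    sample_id = colnames(expr$values),
    rle_median = unname(apply(dev, 2, median)),
    rle_iqr = unname(apply(dev, 2, stats::IQR))
  )
}

#' PCA outlier screen over samples
#'
#' Samples are scored on the first two principal components of the
#' feature-centred matrix; a sample is flagged when its robust z-score
#' `|score - median| / (1.4826 * MAD)` exceeds `z_cut` on either component.
#' This is a numeric stand-in for the visual PCA inspection usually done on
#' array QC plots.
#'
#' @param expr An [expr_set()] with at least three samples.
#' @param z_cut Robust z-score threshold (default 3).
#' @param groups Optional grouping vector (length = samples): robust
#'   z-scores are then computed within group, so that a genuine group
#'   separation along PC1 (e.g. the pre/post intervention effect) is not
#'   mistaken for outlyingness. Groups with fewer than 3 samples are never
#'   flagged.
#' @return Tibble per sample: `sample_id`, `pc1`, `pc2`, `outlier_flag`.
#' @export
pca_outlier_screen <- function(expr, z_cut = 3.0, groups = NULL) {
  stopifnot(inherits(expr, "expr_set"))
  if (ncol(expr$values) < 3) abort("PCA screening needs at least three samples.")
  centered <- expr$values - rowMeans(expr$values)
  if (all(abs(centered) < .Machine$double.eps^0.5)) {
    warn("Zero-variance matrix: no PCA outliers can be flagged.")
    return(tibble::tibble(sample_id = colnames(expr$values),
                          pc1 = 0, pc2 = 0, outlier_flag = FALSE))
  }
  sv <- svd(t(centered), nu = 2, nv = 0)
  scores <- sv$u %*% diag(sv$d[1:2], 2, 2)
  # a PC carrying no real variance (e.g. a rank-1 matrix) cannot flag anyone
  informative <- sv$d[1:2] > sv$d[1] * 1e-8
  robust_z <- function(x) {
    if (length(x) < 3) return(rep(0, length(x)))
    dev <- abs(x - median(x))
    s <- mad(x)
    if (s < .Machine$double.eps) {
      # degenerate spread (e.g. most samples identical): any real deviation is extreme
      tol <- 1e-8 * (1 + max(abs(x)))
      return(ifelse(dev > tol, Inf, 0))
    }
    dev / s
  }
  grouped_z <- function(x) {
    if (is.null(groups)) return(robust_z(x))
    stats::ave(x, groups, FUN = robust_z)
  }
  z1 <- if (informative[1]) grouped_z(scores[, 1]) else rep(0, nrow(scores))
  z2 <- if (informative[2]) grouped_z(scores[, 2]) else rep(0, nrow(scores))
  tibble::tibble(
    sample_id = colnames(expr$values),
    pc1 = scores[, 1], pc2 = scores[, 2],
    outlier_flag = z1 > z_cut | z2 > z_cut
  )
}

#' Sample-level QC report
#'
#' Combines [compute_rle()] and [pca_outlier_screen()] and records the grand
#' mean of all log2 values (used by the low-expression filter).
#'
#' @inheritParams pca_outlier_screen
#' @return A `qc_report` tibble (one row per sample) with attribute
#'   `overall_mean`.
#' @export
qc_screen <- function(expr, z_cut = 3.0, groups = NULL) {
  report <- dplyr::left_join(compute_rle(expr), pca_outlier_screen(expr, z_cut, groups),
                             by = "sample_id")
  structure(report, overall_mean = mean(expr$values),
            class = c("qc_report", class(report)))
}

#' Drop QC-flagged samples
#'
#' @param expr An [expr_set()].
#' @param report A `qc_report` from [qc_screen()].
#' @return `expr` restricted to unflagged samples, with `included` updated.
#' @export
apply_qc <- function(expr, report) {
  keep <- report$sample_id[!report$outlier_flag]
  out <- expr_subset(expr, samples = keep)
  out$samples$included <- TRUE
  out
}

#' Non-supervised low-expression filter
#'
#' Keeps feature i iff its expression exceeds the overall intensity mean
#' (the grand mean over every cell of the input matrix) on strictly more
#' than `min_samples` samples. Both inequalities are strict. The filter is
#' applied once, after QC exclusion, since the grand mean is recomputed from
#' its input.
#'
#' @param expr An [expr_set()].
#' @param min_samples Count threshold; features need
#'   `> min_samples` samples above the grand mean. The default scales the
#'   reference choice of 12 arrays out of 28 to the current sample count.
#' @return Filtered `expr_set` (feature order preserved, samples unchanged).
#' @export
filter_low_expressed <- function(expr, min_samples = floor(ncol(expr$values) * 12 / 28)) {
  stopifnot(inherits(expr, "expr_set"))
  overall_mean <- mean(expr$values)
  n_above <- rowSums(expr$values > overall_mean)
  keep <- n_above > min_samples
  if (!any(keep)) {
    abort(sprintf(
      "Low-expression filter removed all %d features (grand mean %.3f, min_samples %d); lower `min_samples`.",
      nrow(expr$values), overall_mean, min_samples
    ))
  }
  expr_subset(expr, features = which(keep))
}
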