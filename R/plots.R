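#' Plot a QC report
#'
#' RLE medians with IQR whiskers per sample; PCA-flagged outliers in red.
#'
#' @param object A `qc_report` from [qc_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$sample_id, y = .data$rle_median,
    ymin = .data$rle_median - .data$rle_iqr / 2,
    ymax = .data$rle_median + .data$rle_iqr / 2,
    colour = .data$outlier_flag
  )) +
    ggplot2::geom_pointrange() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30", `TRUE` = "red")) +
    ggplot2::labs(x = NULL, y = "RLE median (+/- IQR/2)", colour = "PCA outlier") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Plot PCA sample scores
#'
#' @param object A `pca_model`.
#' @param colour Optional vector (length = samples) mapped to colour, e.g.
#'   the timepoint.
#' @param ... Unused.
#' @return A ggplot object of PC1 vs PC2 scores with variance fractions in
#'   the axis labels.
#' @method autoplot pca_model
#' @export
autoplot.pca_model <- function(object, colour = NULL, ...) {
  df <- tibble::tibble(sample_id = rownames(object$scores),
                       pc1 = object$scores[, 1],
                       pc2 = if (ncol(object$scores) >= 2) object$scores[, 2] else 0)
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_point(if (is.null(colour)) NULL else ggplot2::aes(colour = .data$colour),
                        size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = if (ncol(object$scores) >= 2) {
        sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])
      } else {
        "PC2"
      },
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Volcano plot of a moderated fit
#'
#' @param object A moderated `moderated_fit`.
#' @param coefficient `"distance"` (default) or `"gender"`.
#' @param alpha FDR threshold used to colour significant features.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot moderated_fit
#' @export
autoplot.moderated_fit <- function(object, coefficient = "distance", alpha = 0.05, ...) {
  if (is.null(object$adj_p)) abort("Run ebayes_moderate() before plotting.")
  df <- tibble::tibble(
    beta = object$coefficients[, coefficient],
    neg_log10_p = -log10(pmax(object$p_value[, coefficient], 1e-300)),
    significant = object$adj_p[, coefficient] < alpha
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$beta, .data$neg_log10_p,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = sprintf("%s coefficient (log2 units)", coefficient),
                  y = "-log10 p", colour = sprintf("FDR < %g", alpha)) +
    ggplot2::theme_minimal()
}

#' Bar chart of top enrichment terms
#'
#' @param rows An `enrichment_result`.
#' @param top_n Number of terms shown (by adjusted p).
#' @return A ggplot object: -log10 adjusted p per term, filled by the
#'   percentage of up-regulated overlap genes when available.
#' @export
plot_enrichment <- function(rows, top_n = 20) {
  df <- head(rows, top_n)
  df$term <- factor(df$term_id, levels = rev(df$term_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(pmax(.data$adj_p, 1e-300)), y = .data$term
  ))
  p <- if (all(is.na(df$up_regulated_pct))) {
    p + ggplot2::geom_col(fill = "steelblue")
  } else {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$up_regulated_pct)) +
      ggplot2::scale_fill_gradient2(low = "darkgreen", mid = "grey80",
                                    high = "firebrick", midpoint = 50,
                                    name = "Up-reg [%]")
  }
  p + ggplot2::geom_vline(xintercept = -log10(attr(rows, "alpha") %||% 0.05),
                          linetype = "dashed") +
    ggplot2::labs(x = "-log10 adjusted p", y = NULL) +
    ggplot2::theme_minimal()
}
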