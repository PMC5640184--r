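#' Tidy a moderated fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Long tibble: one row per feature x tested coefficient with
#'   `feature_id`, `term`, `estimate`, `sigma2`, and when moderated
#'   `s2_post`, `statistic` (moderated t), `p.value`, `adj.p.value`.
#' @method tidy moderated_fit
#' @export
tidy.moderated_fit <- function(x, ...) {
  terms <- c("gender", "distance")
  out <- tidyr::expand_grid(feature_id = x$feature_ids, term = terms)
  idx <- match(out$feature_id, x$feature_ids)
  out$estimate <- x$coefficients[cbind(idx, match(out$term, colnames(x$coefficients)))]
  out$sigma2 <- x$sigma2[idx]
  if (!is.null(x$t_mod)) {
    pos <- cbind(idx, match(out$term, colnames(x$t_mod)))
    out$s2_post <- x$s2_post[idx]
    out$statistic <- x$t_mod[pos]
    out$p.value <- x$p_value[pos]
    out$adj.p.value <- x$adj_p[pos]
  }
  out
}

#' One-row summary of a moderated fit
#'
#' @param x A `moderated_fit`.
#' @param ... Unused.
#' @return Tibble with `n_features`, `df_residual`, `d0`, `s0_squared`,
#'   `df_total`.
#' @method glance moderated_fit
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_ids), df_residual = x$df_residual,
    d0 = x$d0 %||% NA_real_, s0_squared = x$s0_squared %||% NA_real_,
    df_total = (x$d0 %||% NA_real_) + x$df_residual
  )
}

#' Tidy a PCA model
#'
#' @param x A `pca_model`.
#' @param matrix `"scores"` (default), `"loadings"` or `"eigenvalues"`.
#' @param ... Unused.
#' @return Long tibble of the requested quantity.
#' @method tidy pca_model
#' @export
tidy.pca_model <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(component = colnames(x$scores),
                          eigenvalue = x$eigenvalues,
                          variance_fraction = x$variance_fraction))
  }
  m <- x[[matrix]]
  tibble::as_tibble(m, rownames = if (matrix == "scores") "sample_id" else "feature_id") |>
    tidyr::pivot_longer(-1, names_to = "component", values_to = "value")
}

#' Tidy an ICA model
#'
#' @param x An `ica_model`.
#' @param matrix `"mixing"` (gene weights, default) or `"sources"`.
#' @param ... Unused.
#' @return Long tibble with `component` and either `gene_id`/`weight` or
#'   `sample_id`/`activation`.
#' @method tidy ica_model
#' @export
tidy.ica_model <- function(x, matrix = c("mixing", "sources"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "mixing") {
    tibble::as_tibble(t(x$A), rownames = "gene_id") |>
      tidyr::pivot_longer(-1, names_to = "component", values_to = "weight")
  } else {
    tibble::as_tibble(x$S, rownames = "sample_id") |>
      tidyr::pivot_longer(-1, names_to = "component", values_to = "activation")
  }
}

#' One-row summary of an ICA model
#'
#' @param x An `ica_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `converged`, `iterations`, `tolerance`,
#'   `alpha1`, `whitened_variance`, `seed`.
#' @method glance ica_model
#' @export
glance.ica_model <- function(x, ...) {
  tibble::tibble(k = x$k, converged = x$converged, iterations = x$iterations,
                 tolerance = x$tolerance, alpha1 = x$alpha1,
                 whitened_variance = x$whitened_variance, seed = x$seed)
}
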