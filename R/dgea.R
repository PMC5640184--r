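#' Build the design matrix for the paired-exposure model
#'
#' Per-feature model: `expr = beta0 + beta1 * gender + beta2 * distance + e`,
#' with gender coded 0 = female / 1 = male and distance the completed km
#' (0 for pre-race samples under the default encoding).
#'
#' @param samples Sample tibble (see [expr_set()]).
#' @return Numeric matrix with columns `intercept`, `gender`, `distance`,
#'   rows in sample order.
#' @export
build_design <- function(samples) {
  samples <- validate_sample_sheet(samples)
  if (nrow(samples) < 4) abort("Need at least 4 samples to fit the 3-coefficient model.")
  design <- cbind(
    intercept = 1,
    gender = as.numeric(samples$gender == "male"),
    distance = samples$distance_km
  )
  rownames(design) <- samples$sample_id
  for (col in c("gender", "distance")) {
    if (var(design[, col]) == 0) {
      abort(sprintf("Covariate '%s' is constant: the design is rank deficient.", col))
    }
  }
  if (qr(design)$rank < ncol(design)) abort("Design matrix is rank deficient.")
  design
}

#' Fit per-feature ordinary least squares models
#'
#' One linear model per feature against a shared design. Residual variance
#' is RSS / df with df = m - p; the unscaled coefficient variances are the
#' diagonal of the design cross-product inverse.
#'
#' @param expr An [expr_set()] (or features x samples matrix).
#' @param design Design matrix from [build_design()].
#' @return A `moderated_fit` (pre-moderation fields): list with
#'   `coefficients` (features x 3), `sigma2`, `df_residual`,
#'   `unscaled_var` (per-coefficient diagonal of `(X'X)^{-1}`),
#'   `feature_ids`.
#' @export
fit_linear_models <- function(expr, design) {
  values <- if (inherits(expr, "expr_set")) expr$values else expr
  if (ncol(values) != nrow(design)) abort("Design rows must match samples.")
  p <- ncol(design)
  df_residual <- ncol(values) - p
  if (df_residual < 1) abort("Residual degrees of freedom must be >= 1.")
  qr_x <- qr(design)
  if (qr_x$rank < p) abort("Design matrix is rank deficient.")
  # all features share the design: solve once through the QR factorisation
  coefs <- t(qr.coef(qr_x, t(values)))
  fitted <- coefs %*% t(design)
  rss <- rowSums((values - fitted)^2)
  xtx_inv <- chol2inv(qr.R(qr_x))
  fit <- list(
    feature_ids = rownames(values),
    coefficients = `colnames<-`(coefs, colnames(design)),
    sigma2 = rss / df_residual,
    df_residual = df_residual,
    unscaled_var = setNames(diag(xtx_inv), colnames(design)),
    design = design
  )
  class(fit) <- "moderated_fit"
  fit
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x`; used by the moment estimator
#' of the variance prior.
#'
#' @param x Positive values.
#' @param tol Relative convergence tolerance.
#' @return `y` with `trigamma(y) = x`; `Inf` maps to 0 and values below
#'   machine resolution map to `Inf`.
#' @export
trigamma_inverse <- function(x, tol = 1e-8) {
  vapply(x, function(xi) {
    if (!is.finite(xi) || xi <= 0) return(NaN)
    if (xi > 1e7) return(1 / sqrt(xi))
    if (xi < 1e-6) return(1 / xi)
    y <- 0.5 + 1 / xi
    for (iter in 1:50) {
      tri <- trigamma(y)
      dif <- tri * (1 - tri / xi) / psigamma(y, deriv = 2)
      y <- y + dif
      if (abs(dif / y) < tol) break
    }
    y
  }, numeric(1))
}

#' Empirical-Bayes moderation of per-feature variances
#'
#' Residual variances are modelled as draws from a scaled inverse
#' chi-square prior with `d0` degrees of freedom and scale `s0_squared`.
#' The prior is estimated by matching the first two moments of
#' `log(sigma2)` to the log F / log chi-square model (digamma/trigamma
#' inversion, Newton iteration); posterior variances
#' `s2_post = (d0 * s0^2 + df * sigma2) / (d0 + df)` then give moderated
#' t-statistics on `d0 + df` degrees of freedom for the gender and distance
#' coefficients, with two-sided p-values and BH adjustment per coefficient.
#'
#' @param fit A `moderated_fit` from [fit_linear_models()].
#' @param d0,s0_squared Optional prior overrides (e.g. `d0 = 0` reproduces
#'   ordinary t-statistics; `d0 = Inf` shrinks every variance to
#'   `s0_squared`). When `NULL` both are estimated.
#' @return The fit with fields `d0`, `s0_squared`, `s2_post`, and
#'   per-coefficient matrices `t_mod`, `p_value`, `adj_p` (columns `gender`,
#'   `distance`).
#' @export
ebayes_moderate <- function(fit, d0 = NULL, s0_squared = NULL) {
  stopifnot(inherits(fit, "moderated_fit"))
  df <- fit$df_residual
  s2 <- fit$sigma2
  if (is.null(d0) || is.null(s0_squared)) {
    ok <- s2 > 0
    if (sum(ok) < 10) abort("Need >= 10 features with positive residual variance.")
    z <- log(s2[ok])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e)
    target <- evar - trigamma(df / 2)
    if (is.finite(target) && target > 0) {
      half_d0 <- trigamma_inverse(target)
      if (!is.finite(half_d0) || is.nan(half_d0)) {
        warn("Trigamma inversion failed; falling back to d0 = Inf.")
        half_d0 <- Inf
      }
    } else {
      half_d0 <- Inf
    }
    est_d0 <- 2 * half_d0
    est_s0 <- if (is.finite(half_d0)) {
      exp(mean(e) + digamma(half_d0) - log(half_d0))
    } else {
      exp(mean(e))
    }
    if (is.null(d0)) d0 <- est_d0
    if (is.null(s0_squared)) s0_squared <- est_s0
  }
  s2_post <- if (!is.finite(d0)) {
    rep(s0_squared, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * s0_squared + df * s2) / (d0 + df)
  }
  df_total <- d0 + df
  tested <- c("gender", "distance")
  t_mod <- sapply(tested, function(cf) {
    fit$coefficients[, cf] / sqrt(s2_post * fit$unscaled_var[cf])
  })
  p_value <- 2 * pt(-abs(t_mod), df = df_total)
  fit$d0 <- d0
  fit$s0_squared <- s0_squared
  fit$s2_post <- s2_post
  fit$t_mod <- t_mod
  fit$p_value <- p_value
  fit$adj_p <- apply(p_value, 2, bh_adjust)
  fit
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone, capped at 1, input order preserved).
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d features, df = %d", length(x$feature_ids), x$df_residual))
  if (!is.null(x$d0)) {
    cat(sprintf(", prior: d0 = %.3g, s0^2 = %.4g", x$d0, x$s0_squared))
  }
  cat("\n")
  invisible(x)
}

#' Select differential features at a given FDR
#'
#' Features with BH-adjusted p below `alpha` for the chosen coefficient.
#' The gene-level list keeps unambiguously annotated features only;
#' multi-annotated and unannotated features are counted but excluded from
#' gene-level analyses.
#'
#' @param fit A moderated `moderated_fit`.
#' @param coefficient `"distance"` (exposure response) or `"gender"`.
#' @param alpha FDR threshold (default 0.05).
#' @param annotation Optional annotation tibble (`feature_id`, `gene_id`);
#'   without it the gene column is NA and every feature is retained.
#' @return A `differential_list` tibble: `feature_id`, `gene_id`, `beta`,
#'   `t_mod`, `p_value`, `adj_p`, `direction` (`up`/`down` by the sign of
#'   beta), sorted by `adj_p`. Attribute `counts` reports features,
#'   single-annotation features, distinct genes and the up/down split
#'   percentages; attribute `coefficient` records the tested coefficient.
#' @export
select_differential <- function(fit, coefficient = c("distance", "gender"),
                                alpha = 0.05, annotation = NULL) {
  coefficient <- match.arg(coefficient)
  if (is.null(fit$adj_p)) abort("Run ebayes_moderate() before selecting.")
  sel <- which(fit$adj_p[, coefficient] < alpha)
  out <- tibble::tibble(
    feature_id = fit$feature_ids[sel],
    gene_id = NA_character_,
    beta = fit$coefficients[sel, coefficient],
    t_mod = fit$t_mod[sel, coefficient],
    p_value = fit$p_value[sel, coefficient],
    adj_p = fit$adj_p[sel, coefficient],
    direction = ifelse(fit$coefficients[sel, coefficient] < 0, "down", "up")
  )
  counts <- list(n_features = nrow(out))
  if (!is.null(annotation) && nrow(out)) {
    parts <- map_features_to_genes(out$feature_id, annotation)
    out$gene_id <- parts$unambiguous$gene_id[match(out$feature_id, parts$unambiguous$feature_id)]
    counts$n_single_annotation <- nrow(parts$unambiguous)
    counts$n_multi_annotation <- length(parts$ambiguous)
    counts$n_unannotated <- length(parts$unannotated)
    counts$n_distinct_genes <- parts$n_distinct_genes
  }
  counts$pct_down <- if (nrow(out)) 100 * mean(out$direction == "down") else NA_real_
  counts$pct_up <- if (nrow(out)) 100 * mean(out$direction == "up") else NA_real_
  out <- out[order(out$adj_p, out$p_value, out$feature_id), ]
  structure(out, counts = counts, coefficient = coefficient, alpha = alpha,
            class = c("differential_list", class(out)))
}

#' Strong-effect selection for heatmap display
#'
#' Keeps differential features with `|beta| > mu + 2 * sigma`. Under the
#' default `"signed"` convention mu and sigma are the mean and SD of the
#' signed beta values over the differential set (literal reading of the
#' rule); `"absolute"` uses the moments of `|beta|` instead.
#'
#' @param diff A `differential_list`.
#' @param convention `"signed"` (default) or `"absolute"`.
#' @return Character vector of selected feature ids (possibly empty), with
#'   attribute `threshold`.
#' @export
select_strong_effects <- function(diff, convention = c("signed", "absolute")) {
  convention <- match.arg(convention)
  if (nrow(diff) < 2) abort("Strong-effect selection needs >= 2 differential features.")
  b <- if (convention == "signed") diff$beta else abs(diff$beta)
  if (sd(b) == 0) {
    warn("Zero variance of effect sizes: no strong effects selected.")
    return(structure(character(0), threshold = NA_real_))
  }
  thr <- mean(b) + 2 * sd(b)
  structure(diff$feature_id[abs(diff$beta) > thr], threshold = thr)
}

#' Dendrogram leaf ordering for heatmap display
#'
#' Complete-linkage agglomerative clustering with Euclidean distances on
#' (optionally row-standardized) expression values; returns leaf orders for
#' features and samples.
#'
#' @param expr An [expr_set()].
#' @param features Feature ids to cluster (>= 2).
#' @param standardize_rows Centre/scale each feature before clustering
#'   (default TRUE).
#' @return List with `features` and `samples`: ids in dendrogram leaf order.
#' @export
hierarchical_order <- function(expr, features, standardize_rows = TRUE) {
  stopifnot(inherits(expr, "expr_set"))
  if (length(features) < 2) abort("Need >= 2 features to cluster.")
  m <- expr$values[features, , drop = FALSE]
  if (standardize_rows) {
    mu <- rowMeans(m)
    s <- apply(m, 1, sd)
    s[s == 0] <- 1
    m <- (m - mu) / s
  }
  hc_rows <- hclust(dist(m), method = "complete")
  hc_cols <- hclust(dist(t(m)), method = "complete")
  list(features = rownames(m)[hc_rows$order],
       samples = colnames(m)[hc_cols$order])
}
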