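#' Principal component analysis of an expression matrix
#'
#' SVD-based PCA of the feature-centred matrix. Samples get scores, features
#' get loadings (orthonormal columns); eigenvalues are the sample variances
#' of the score columns.
#'
#' @param x An [expr_set()] or a features x samples numeric matrix.
#' @param K Number of components (at most `min(n_features - 1,
#'   n_samples - 1)`).
#' @return A `pca_model`: list with `scores` (samples x K), `loadings`
#'   (features x K), `eigenvalues`, `variance_fraction`, `center`
#'   (per-feature means), `total_variance`, plus id vectors.
#' @export
fit_pca <- function(x, K = NULL) {
  values <- if (inherits(x, "expr_set")) x$values else x
  n <- nrow(values)
  m <- ncol(values)
  k_cap <- min(n - 1, m - 1)
  if (is.null(K)) K <- k_cap
  if (K < 1 || K > k_cap) {
    abort(sprintf("K must lie in 1..%d for a %d x %d matrix.", k_cap, n, m))
  }
  center <- rowMeans(values)
  xt_c <- t(values - center) # samples x features, feature-centred
  sv <- svd(xt_c)
  denom <- m - 1
  eig <- sv$d^2 / denom
  model <- list(
    scores = sv$u[, 1:K, drop = FALSE] %*% diag(sv$d[1:K], K, K),
    loadings = sv$v[, 1:K, drop = FALSE],
    eigenvalues = eig[1:K],
    variance_fraction = (eig / sum(eig))[1:K],
    center = center,
    total_variance = sum(eig),
    feature_ids = rownames(values),
    sample_ids = colnames(values)
  )
  dimnames(model$scores) <- list(model$sample_ids, paste0("PC", 1:K))
  dimnames(model$loadings) <- list(model$feature_ids, paste0("PC", 1:K))
  class(model) <- "pca_model"
  model
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components; variance fractions: %s\n",
              ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * head(x$variance_fraction, 5)), collapse = ", ")))
  invisible(x)
}

#' Estimate the number of principal components
#'
#' `"gcv"` minimises the generalized cross-validation criterion
#' `GCV(k) = n * m * RSS_k / (n * m - df_k)^2` over `k = 0..K_max`, where
#' `RSS_k` is the squared Frobenius residual of the rank-k reconstruction of
#' the centred matrix and `df_k = m + n * k + m * k - k^2 - k` counts the
#' parameters of a k-component bilinear fit with centring. `"smooth"` is an
#' eigen-gap heuristic: it smooths the eigenvalue drops with a 3-point
#' moving average and returns the k with the largest ratio of successive
#' smoothed drops.
#'
#' @param x An [expr_set()] or features x samples matrix.
#' @param method `"gcv"` (default) or `"smooth"`.
#' @param K_max Largest k considered. The default caps the search at half
#'   the matrix rank: at full rank the residual vanishes identically and
#'   the GCV criterion degenerates to zero, so the approximation is only
#'   informative for k well below `min(n, m) - 1`.
#' @return List with `k` (the estimate) and `curve` (tibble `k`,
#'   `criterion`).
#' @export
estimate_ncp <- function(x, method = c("gcv", "smooth"), K_max = NULL) {
  method <- match.arg(method)
  values <- if (inherits(x, "expr_set")) x$values else x
  n <- nrow(values)
  m <- ncol(values)
  k_cap <- min(n - 1, m - 1)
  if (is.null(K_max)) K_max <- max(1, floor(k_cap / 2))
  if (K_max > k_cap) abort(sprintf("K_max must be <= %d.", k_cap))
  centered <- values - rowMeans(values)
  d2 <- svd(t(centered), nu = 0, nv = 0)$d^2
  total <- sum(d2)
  ks <- 0:K_max
  if (method == "gcv") {
    rss <- total - c(0, cumsum(d2))[ks + 1]
    df_k <- m + n * ks + m * ks - ks^2 - ks
    crit <- (n * m * rss) / (n * m - df_k)^2
    if (any(!is.finite(crit))) abort("Non-finite GCV criterion.")
    curve <- tibble::tibble(k = ks, criterion = crit)
    list(k = ks[which.min(crit)], curve = curve, method = method)
  } else {
    lambda <- c(d2, 0, 0)
    drop <- lambda[1:(K_max + 1)] - lambda[2:(K_max + 2)]
    # 3-point moving average of the drops, then ratio of successive drops
    sm <- stats::filter(drop, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- drop[is.na(sm)]
    ratio <- as.numeric(sm[1:K_max] / pmax(sm[2:(K_max + 1)], .Machine$double.eps))
    if (any(!is.finite(ratio))) abort("Non-finite smoothing criterion.")
    curve <- tibble::tibble(k = 1:K_max, criterion = ratio)
    list(k = which.max(ratio), curve = curve, method = method)
  }
}

#' Rank-1 deflation of the first expression mode
#'
#' Subtracts the PC1 rank-1 reconstruction `Y^T = z_1 (x) phi_1` (outer
#' product of the first score and loading vectors) from the expression
#' matrix, removing the dominant mode so later decompositions see residual
#' structure only. The deflated matrix has zero projection on `phi_1` and
#' its total variance drops by exactly the first eigenvalue.
#'
#' @param x An [expr_set()] or features x samples matrix.
#' @param pca A `pca_model` fitted on `x` with `K >= 1`.
#' @return List with `Y` (features x samples rank-1 matrix) and `x_hat`
#'   (deflated features x samples matrix, feature means preserved).
#' @export
deflate_first_component <- function(x, pca) {
  values <- if (inherits(x, "expr_set")) x$values else x
  stopifnot(inherits(pca, "pca_model"))
  if (nrow(values) != nrow(pca$loadings) || ncol(values) != nrow(pca$scores)) {
    abort("PCA model dimensions do not match the matrix.")
  }
  yt <- pca$scores[, 1] %o% pca$loadings[, 1] # samples x features
  y <- t(yt)
  dimnames(y) <- dimnames(values)
  list(Y = y, x_hat = values - y)
}

#' Symmetric FastICA of an expression matrix
#'
#' Decomposes `X^T = S A`: samples x genes data into `k` independent source
#' activations over samples (columns of `S`) and a mixing matrix `A` of gene
#' weights. Gene-wise centring, PCA whitening to `k` dimensions, then the
#' symmetric (parallel) fixed-point iteration with the log-cosh contrast
#' `g(u) = tanh(alpha1 * u)`. Components are extracted simultaneously;
#' convergence when the largest absolute change in the unmixing directions
#' drops below `tolerance`. Each component is sign-oriented so its largest
#' |weight| gene has positive weight.
#'
#' @param x An [expr_set()] or features x samples matrix (genes x samples;
#'   transposed internally).
#' @param k Number of components (`<= min(n_genes, n_samples)`).
#' @param seed Integer seed for the random orthogonal start.
#' @param tolerance Convergence tolerance on the unmixing directions.
#' @param max_iter Maximum fixed-point iterations.
#' @param alpha1 Log-cosh contrast parameter in `[1, 2]`.
#' @return An `ica_model`: list with `S` (samples x k, unit-variance
#'   sources), `A` (k x genes mixing weights), `k`, `converged`,
#'   `iterations`, `seed`, `tolerance`, `alpha1`, `whitened_variance`
#'   (fraction of variance retained by the k whitening components), plus id
#'   vectors.
#' @export
run_fastica <- function(x, k, seed = 1L, tolerance = 1e-4, max_iter = 1000L,
                        alpha1 = 1) {
  values <- if (inherits(x, "expr_set")) x$values else x
  n <- nrow(values)
  m <- ncol(values)
  if (k < 1 || k > min(n, m)) abort(sprintf("k must lie in 1..%d.", min(n, m)))
  xt_c <- t(values - rowMeans(values)) # m x n, gene-centred
  sv <- svd(xt_c)
  pos <- sum(sv$d > max(sv$d) * 1e-12)
  if (k > pos) abort(sprintf("k = %d exceeds the matrix rank (%d).", k, pos))
  z <- sv$u[, 1:k, drop = FALSE] * sqrt(m) # whitened: crossprod(z)/m = I
  whitened_variance <- sum(sv$d[1:k]^2) / sum(sv$d^2)

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  w <- matrix(rnorm(k * k), k, k)
  w <- sym_decorrelate(w)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    wz <- z %*% t(w) # m x k projections
    gwz <- tanh(alpha1 * wz)
    g_prime <- alpha1 * (1 - gwz^2)
    w_new <- crossprod(gwz, z) / m - diag(colMeans(g_prime), k, k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(1 - abs(rowSums(w_new * w))))
    w <- w_new
    if (delta < tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("FastICA did not converge in %d iterations (last change %.2e).",
                 max_iter, delta))
  }
  s <- z %*% t(w) # m x k, unit variance columns
  # map back to the data: xt_c ~ s %*% a for the rank-k subspace
  a <- w %*% (diag(sv$d[1:k] / sqrt(m), k, k) %*% t(sv$v[, 1:k, drop = FALSE]))
  # orientation: largest-|weight| gene positive per component
  flip <- vapply(seq_len(k), function(i) sign(a[i, which.max(abs(a[i, ]))]), numeric(1))
  a <- a * flip
  s <- s * rep(flip, each = m)
  dimnames(s) <- list(colnames(values), paste0("IC", 1:k))
  dimnames(a) <- list(paste0("IC", 1:k), rownames(values))
  structure(list(S = s, A = a, k = k, converged = converged,
                 iterations = iterations, seed = seed, tolerance = tolerance,
                 nonlinearity = "logcosh", alpha1 = alpha1,
                 whitened_variance = whitened_variance,
                 feature_ids = rownames(values), sample_ids = colnames(values)),
            class = "ica_model")
}

sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(w), nrow(w)) %*% t(e$vectors) %*% w
}

#' @export
print.ica_model <- function(x, ...) {
  cat(sprintf("<ica_model> k = %d, %s after %d iterations (tol %.1e, logcosh alpha1 = %g)\n",
              x$k, if (x$converged) "converged" else "NOT converged",
              x$iterations, x$tolerance, x$alpha1))
  invisible(x)
}

#' Ninth-decile contributor selection per component
#'
#' For each independent component, ranks genes by absolute mixing weight and
#' keeps the top `ceiling(n / 10)` — the genes whose |weight| falls in the
#' ninth decile. Selection is rank-based (exactly `ceiling(n / 10)` genes,
#' ties at the boundary broken by gene-id order) so the set size is
#' identical across components.
#'
#' @param ica An `ica_model` from [run_fastica()].
#' @param gene_ids Optional gene ids (defaults to the model's feature ids).
#' @return Tibble with columns `component`, `gene_id`, `weight`,
#'   `abs_weight`, `rank`; `ceiling(n / 10)` rows per component.
#' @export
select_contributors <- function(ica, gene_ids = NULL) {
  stopifnot(inherits(ica, "ica_model"))
  gene_ids <- gene_ids %||% ica$feature_ids
  n <- length(gene_ids)
  if (n < 10) abort("Contributor selection needs >= 10 genes.")
  if (n != ncol(ica$A)) abort("gene_ids length must match the mixing matrix.")
  n_keep <- ceiling(n / 10)
  purrr::map_dfr(seq_len(ica$k), function(i) {
    w <- ica$A[i, ]
    ord <- order(-abs(w), gene_ids)
    keep <- ord[seq_len(n_keep)]
    tibble::tibble(component = paste0("IC", i), gene_id = gene_ids[keep],
                   weight = unname(w[keep]), abs_weight = abs(unname(w[keep])),
                   rank = seq_len(n_keep))
  })
}

#' Pairwise overlap and uniqueness of contributor sets
#'
#' @param contributors Tibble from [select_contributors()] (>= 2
#'   components).
#' @return List with `overlap` (symmetric matrix of pairwise intersection
#'   sizes, diagonal = set sizes) and `unique_counts` (tibble: genes of each
#'   component absent from every other component's set).
#' @export
contributor_overlap <- function(contributors) {
  sets <- split(contributors$gene_id, contributors$component)
  if (length(sets) < 2) abort("Need >= 2 contributor sets.")
  ids <- names(sets)
  ov <- outer(seq_along(sets), seq_along(sets),
              Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(ov) <- list(ids, ids)
  uniq <- vapply(seq_along(sets), function(i) {
    length(setdiff(sets[[i]], unlist(sets[-i], use.names = FALSE)))
  }, integer(1))
  list(overlap = ov,
       unique_counts = tibble::tibble(component = ids, n_unique = uniq))
}
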