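test_that("PCA matches an eigen-decomposition oracle and reconstructs completely", {
  set.seed(2)
  v <- matrix(rnorm(5 * 4, 7), 5, 4,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  pca <- fit_pca(v, K = 3)
  # oracle: eigenvalues of the gene-gene covariance (samples as observations)
  ev <- eigen(stats::cov(t(v)), symmetric = TRUE)$values
  expect_equal(pca$eigenvalues, ev[1:3], tolerance = 1e-10)
  expect_equal(crossprod(pca$loadings), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pca$variance_fraction) <= 1e-12))

  # full reconstruction of the centred matrix
  centred <- v - rowMeans(v)
  expect_equal(t(pca$scores %*% t(pca$loadings)), centred, tolerance = 1e-10,
               ignore_attr = TRUE)

  # exact rank-1 input
  r1 <- outer(rnorm(6), rnorm(5))
  pca1 <- fit_pca(r1 - rowMeans(r1), K = 3)
  expect_equal(pca1$variance_fraction, c(1, 0, 0), tolerance = 1e-10)

  expect_error(fit_pca(v, K = 4), "K must lie")
})

test_that("GCV recovers a planted rank and stays low on pure noise", {
  hits <- 0
  for (s in 1:50) {
    set.seed(s)
    signal <- matrix(rnorm(200 * 3), 200, 3) %*% matrix(rnorm(3 * 30), 3, 30)
    noise <- matrix(rnorm(200 * 30, 0, 0.1 * sd(signal)), 200, 30)
    est <- estimate_ncp(signal + noise, method = "gcv", K_max = 10)
    hits <- hits + (est$k == 3)
  }
  expect_gte(hits / 50, 0.9)

  null_small <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    est <- estimate_ncp(matrix(rnorm(200 * 30), 200, 30), "gcv", K_max = 10)
    null_small <- null_small + (est$k <= 1)
  }
  expect_gt(null_small / 20, 0.5)

  # criterion curve is returned over the full grid
  est <- estimate_ncp(matrix(rnorm(50 * 10), 50, 10), "gcv", K_max = 4)
  expect_equal(est$curve$k, 0:4)
  sm <- estimate_ncp(matrix(rnorm(50 * 10), 50, 10), "smooth", K_max = 4)
  expect_true(sm$k %in% 1:4)
})

test_that("deflation removes exactly the first mode's variance and direction", {
  set.seed(14)
  v <- matrix(rnorm(30 * 10, 7), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("s", 1:10)))
  pca <- fit_pca(v, K = 5)
  defl <- deflate_first_component(v, pca)

  # rank of the removed piece
  expect_equal(sum(svd(defl$Y)$d > 1e-8), 1)
  # orthogonality to phi1
  resid_centred <- defl$x_hat - rowMeans(defl$x_hat)
  expect_lt(max(abs(t(resid_centred) %*% pca$loadings[, 1])), 1e-8)
  # variance bookkeeping: var(X) = var(Y) + var(X_hat), drop equals eigenvalue 1
  tv <- function(m) sum((m - rowMeans(m))^2) / (ncol(m) - 1)
  expect_equal(tv(v) - tv(defl$x_hat), pca$eigenvalues[1], tolerance = 1e-8)
  expect_equal((tv(v) - tv(defl$x_hat)) / tv(v), pca$variance_fraction[1],
               tolerance = 1e-8)

  # exactly rank-1 centred input deflates to zero
  r1 <- outer(rnorm(8), rnorm(6))
  r1 <- r1 - rowMeans(r1)
  pr1 <- fit_pca(r1, K = 2)
  expect_lt(max(abs(deflate_first_component(r1, pr1)$x_hat)), 1e-10)

  expect_error(deflate_first_component(v[1:5, ], pca), "dimensions")
})

test_that("FastICA recovers planted super-Gaussian sources", {
  set.seed(61)
  m <- 300
  n <- 200
  lap <- function(n) { u <- runif(n) - 0.5; -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) }
  S_true <- cbind(lap(m), lap(m))
  W_true <- matrix(rnorm(2 * n), 2, n)
  X <- t(S_true %*% W_true) + matrix(rnorm(n * m, 0, sqrt(mean((S_true %*% W_true)^2) / 10)), n, m)
  ica <- run_fastica(X, k = 2, seed = 5)
  expect_true(ica$converged)
  expect_true(all(match_sources(ica$S, S_true) >= 0.95))

  # one-component degeneracy: source proportional to the PC1 scores
  r1 <- outer(rnorm(50), rnorm(12)) + 7
  ica1 <- run_fastica(r1, k = 1, seed = 2)
  pc1 <- fit_pca(r1, K = 1)$scores[, 1]
  expect_gte(abs(stats::cor(ica1$S[, 1], pc1)), 0.999)

  # orientation: the largest-|weight| gene carries a positive weight
  for (i in 1:2) {
    expect_gt(ica$A[i, which.max(abs(ica$A[i, ]))], 0)
  }
})

test_that("FastICA is stable across seeds and reconstructs within the whitening bound", {
  set.seed(62)
  m <- 40
  n <- 150
  lap <- function(n) { u <- runif(n) - 0.5; -sign(u) * log(1 - 2 * abs(u)) / sqrt(2) }
  S_true <- cbind(lap(m), lap(m), lap(m))
  X <- t(S_true %*% matrix(rnorm(3 * n), 3, n)) +
    matrix(rnorm(n * m, 0, 0.05), n, m)

  ica_a <- run_fastica(X, k = 3, seed = 1)
  ica_b <- run_fastica(X, k = 3, seed = 99)
  qa <- qr.Q(qr(ica_a$S))
  qb <- qr.Q(qr(ica_b$S))
  principal_angles <- acos(pmin(1, svd(crossprod(qa, qb))$d))
  expect_lt(max(principal_angles), 1e-3)

  xt_c <- t(X - rowMeans(X))
  for (ica in list(ica_a, run_fastica(X, k = 2, seed = 3))) {
    resid <- sum((xt_c - ica$S %*% ica$A)^2) / sum(xt_c^2)
    expect_lte(resid, 1 - ica$whitened_variance + 1e-6)
  }

  expect_error(run_fastica(X, k = 200), "k must lie")
})

test_that("the ninth-decile rule keeps exactly ceil(n/10) genes per component", {
  set.seed(71)
  for (n in c(10, 25, 5084)) {
    v <- matrix(rnorm(n * 12, 7), n, 12,
                dimnames = list(sprintf("g%05d", 1:n), sprintf("s%02d", 1:12)))
    ica <- suppressWarnings(run_fastica(v, k = 2, seed = 4))
    contrib <- select_contributors(ica)
    expect_equal(unname(table(contrib$component)), rep(ceiling(n / 10), 2),
                 ignore_attr = TRUE)
    # members dominate non-members in |weight|
    for (cc in c("IC1", "IC2")) {
      inset <- contrib$gene_id[contrib$component == cc]
      w <- abs(ica$A[cc, ])
      expect_gte(min(w[inset]), max(w[setdiff(names(w), inset)]) - 1e-12)
    }
  }
  v <- matrix(rnorm(9 * 12), 9, 12, dimnames = list(paste0("g", 1:9), paste0("s", 1:12)))
  ica_small <- suppressWarnings(run_fastica(v, k = 2, seed = 4))
  expect_error(select_contributors(ica_small), ">= 10")
})

test_that("contributor overlap matches brute-force set algebra", {
  mk <- function(sets) {
    tibble::tibble(component = rep(names(sets), lengths(sets)),
                   gene_id = unlist(sets, use.names = FALSE))
  }
  disjoint <- mk(list(IC1 = paste0("a", 1:509), IC2 = paste0("b", 1:509)))
  ov <- contributor_overlap(disjoint)
  expect_equal(unname(ov$overlap), rbind(c(509, 0), c(0, 509)))
  expect_equal(ov$unique_counts$n_unique, c(509, 509))

  same <- mk(list(IC1 = paste0("x", 1:40), IC2 = paste0("x", 1:40)))
  ov2 <- contributor_overlap(same)
  expect_equal(unname(ov2$overlap), matrix(40, 2, 2))
  expect_equal(ov2$unique_counts$n_unique, c(0, 0))

  set.seed(81)
  pool <- sprintf("g%03d", 1:200)
  sets <- list(IC1 = sample(pool, 60), IC2 = sample(pool, 60), IC3 = sample(pool, 60))
  ov3 <- contributor_overlap(mk(sets))
  for (i in 1:3) for (j in 1:3) {
    expect_equal(ov3$overlap[i, j], length(intersect(sets[[i]], sets[[j]])))
  }
  for (i in 1:3) {
    expect_equal(ov3$unique_counts$n_unique[i],
                 length(setdiff(sets[[i]], unlist(sets[-i]))))
  }
})

test_that("deflation unmasks minor modes dominated by a strong first mode", {
  recov <- function(deflate, seed) {
    sim <- simulate_dataset(simulation_config(
      pi_diff = 0, pi_gender = 0, k_modes = 3, dominant_mode_scale = 10,
      n_genes = 600, seed = seed
    ))
    X <- sim$expr$values
    k <- 3
    input <- if (deflate) deflate_first_component(X, fit_pca(X, K = 2))$x_hat else X
    ica <- suppressWarnings(run_fastica(input, k = if (deflate) k - 1 else k, seed = 11))
    minor <- sim$truth$mode_activations[, 2:3]
    mean(match_sources(ica$S, minor))
  }
  seeds <- 101:105
  with_defl <- vapply(seeds, function(s) recov(TRUE, s), numeric(1))
  without <- vapply(seeds, function(s) recov(FALSE, s), numeric(1))
  expect_gt(mean(with_defl), mean(without))
  expect_gte(mean(with_defl), 0.9)
})
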