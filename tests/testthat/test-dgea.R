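test_that("design construction encodes covariates and rejects rank deficiency", {
  sheet <- make_sheet(4, distances = c(50, 50))
  d <- build_design(sheet)
  expect_equal(dim(d), c(4, 3))
  expect_equal(unname(d[, "intercept"]), rep(1, 4))
  expect_setequal(unique(d[, "gender"]), c(0, 1))
  expect_equal(unname(d[, "distance"]), sheet$distance_km)
  expect_equal(qr(d)$rank, 3)

  all_male <- dplyr::mutate(sheet, gender = "male")
  expect_error(build_design(all_male), "gender")

  perm <- sample(nrow(sheet))
  expect_equal(unname(build_design(sheet[perm, ])), unname(d[perm, ]))
})

test_that("per-feature OLS matches the normal-equations oracle", {
  sheet <- make_sheet(6, distances = c(20, 50, 80))
  design <- build_design(sheet)

  # exact fit: expression = 2 * distance
  v <- rbind(2 * sheet$distance_km, rnorm(6, 7))
  es <- make_expr(v)
  fit <- fit_linear_models(es, design)
  expect_equal(unname(fit$coefficients[1, "distance"]), 2, tolerance = 1e-12)
  expect_lt(fit$sigma2[1], 1e-20)

  # random features against solve(X'X) X'y
  set.seed(21)
  es2 <- make_expr(n = 30, m = 6, seed = 21)
  fit2 <- fit_linear_models(es2, design)
  beta_oracle <- t(solve(crossprod(design), crossprod(design, t(es2$values))))
  expect_equal(unname(fit2$coefficients), unname(beta_oracle), tolerance = 1e-10)
  rss <- rowSums((es2$values - fit2$coefficients %*% t(design))^2)
  expect_equal(fit2$sigma2, rss / (6 - 3), tolerance = 1e-10)
  expect_equal(unname(fit2$unscaled_var),
               unname(diag(solve(crossprod(design)))), tolerance = 1e-10)

  # adding a constant changes only the intercept
  es3 <- es2
  es3$values[3, ] <- es3$values[3, ] + 5
  fit3 <- fit_linear_models(es3, design)
  expect_equal(fit3$coefficients[3, "intercept"],
               fit2$coefficients[3, "intercept"] + 5, tolerance = 1e-10)
  expect_equal(fit3$coefficients[3, c("gender", "distance")],
               fit2$coefficients[3, c("gender", "distance")], tolerance = 1e-10)
})

test_that("moderated t reduces to ordinary t at d0 = 0 and respects a common variance", {
  set.seed(4)
  sheet <- make_sheet(10)
  design <- build_design(sheet)
  es <- make_expr(n = 40, m = 10, seed = 4)
  fit <- fit_linear_models(es, design)

  plain <- ebayes_moderate(fit, d0 = 0, s0_squared = 1)
  t_ols <- fit$coefficients[, "distance"] /
    sqrt(fit$sigma2 * fit$unscaled_var["distance"])
  expect_equal(unname(plain$t_mod[, "distance"]), unname(t_ols), tolerance = 1e-12)

  # identical residual variances stay fixed for any d0 when s0^2 equals them
  common <- fit
  common$sigma2 <- rep(0.3, length(fit$sigma2))
  for (d0 in c(1, 4, 100)) {
    mod <- ebayes_moderate(common, d0 = d0, s0_squared = 0.3)
    expect_equal(mod$s2_post, rep(0.3, 40), ignore_attr = TRUE)
  }

  # d0 = Inf shrinks every variance to the prior
  inf_fit <- ebayes_moderate(fit, d0 = Inf, s0_squared = 0.2)
  expect_equal(inf_fit$s2_post, rep(0.2, 40), ignore_attr = TRUE)
})

test_that("the variance prior is recovered from its own sampling model", {
  sheet <- make_sheet(28, distances = c(82, 50, 50, 25, 42, 50, 82, 25, 33, 50, 50, 14, 60, 70))
  design <- build_design(sheet)
  df <- 28 - 3
  set.seed(17)
  n <- 5000
  sigma2_true <- 0.05 * 4 / rchisq(n, 4) # d0 = 4, s0^2 = 0.05
  s2_obs <- sigma2_true * rchisq(n, df) / df
  fit <- structure(list(
    feature_ids = sprintf("f%04d", 1:n),
    coefficients = matrix(0, n, 3, dimnames = list(NULL, c("intercept", "gender", "distance"))),
    sigma2 = s2_obs, df_residual = df,
    unscaled_var = c(intercept = 1, gender = 1, distance = 1),
    design = design
  ), class = "moderated_fit")
  mod <- ebayes_moderate(fit)
  expect_lt(abs(mod$d0 - 4) / 4, 0.20)
  expect_lt(abs(mod$s0_squared - 0.05) / 0.05, 0.10)
})

test_that("moderation agrees with an established empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(12)
  sheet <- make_sheet(12)
  design <- build_design(sheet)
  es <- make_expr(n = 200, m = 12, seed = 12)
  mod <- ebayes_moderate(fit_linear_models(es, design))
  lfit <- limma::eBayes(limma::lmFit(es$values, design))
  expect_equal(mod$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$s0_squared, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(unname(mod$t_mod[, "distance"]), unname(lfit$t[, "distance"]),
               tolerance = 1e-8)
  expect_equal(unname(mod$p_value[, "gender"]), unname(lfit$p.value[, "gender"]),
               tolerance = 1e-8)
})

test_that("BH adjustment matches the step-up definition and its basic properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(31)
  for (rep in 1:1000) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    expect_true(all(adj >= p))
  }
})

test_that("differential selection controls the null and assigns directions", {
  # pure-null simulation: rejections are rare at 5% FDR
  sim <- simulate_dataset(simulation_config(pi_diff = 0, pi_gender = 0,
                                            k_modes = 0, seed = 23))
  design <- build_design(sim$expr$samples)
  mod <- ebayes_moderate(fit_linear_models(sim$expr, design))
  frac <- mean(mod$adj_p[, "distance"] < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(sim$expr$values))
  expect_lte(frac, 0.05 + 3 * se)

  # alpha = 0 selects nothing
  expect_equal(nrow(select_differential(mod, "distance", alpha = 0)), 0)

  # planted effects: signs recovered as directions
  sim2 <- simulate_dataset(simulation_config(seed = 29))
  design2 <- build_design(sim2$expr$samples)
  mod2 <- ebayes_moderate(fit_linear_models(sim2$expr, design2))
  dl <- select_differential(mod2, "distance", annotation = sim2$annotation)
  expect_true(all(dl$direction[dl$beta < 0] == "down"))
  expect_true(all(dl$adj_p < 0.05))
  truth_beta <- sim2$truth$beta2[sim2$truth$feature_gene[dl$feature_id]]
  hits <- dl$feature_id[truth_beta != 0]
  agree <- sign(dl$beta[match(hits, dl$feature_id)]) ==
    sign(truth_beta[truth_beta != 0])
  expect_gt(mean(agree), 0.95)
  counts <- attr(dl, "counts")
  expect_equal(counts$pct_up + counts$pct_down, 100)
})

test_that("strong-effect selection follows the mean + 2 SD rule", {
  mk <- function(beta) {
    structure(tibble::tibble(
      feature_id = sprintf("f%d", seq_along(beta)), gene_id = NA_character_,
      beta = beta, t_mod = 0, p_value = 0, adj_p = 0,
      direction = ifelse(beta < 0, "down", "up")
    ), class = c("differential_list", "tbl_df", "tbl", "data.frame"))
  }
  expect_warning(sel <- select_strong_effects(mk(c(1, 1, 1, 1))), "Zero variance")
  expect_length(sel, 0)

  # (0,0,0,0,10): mu = 2, sd = sqrt(20), threshold 10.94 -> nothing selected
  expect_length(select_strong_effects(mk(c(0, 0, 0, 0, 10))), 0)
  expect_length(select_strong_effects(mk(c(0, 0, 0, 0, 10)), "absolute"), 0)

  # a clearly separated effect is selected
  expect_equal(select_strong_effects(mk(c(rep(0, 20), 10))), "f21",
               ignore_attr = TRUE)
})

test_that("complete-linkage ordering keeps close profiles adjacent", {
  v <- rbind(c(0, 0, 0, 0), c(0, 0, 0, 0), c(9, 9, 9, 9))
  es <- make_expr(v)
  ord <- hierarchical_order(es, rownames(es$values), standardize_rows = FALSE)
  expect_setequal(ord$features, rownames(es$values))
  pos <- match(c("f001", "f002"), ord$features)
  expect_equal(abs(diff(pos)), 1)

  # three points on a line: distances 1 and 10
  v2 <- rbind(c(0, 0), c(1, 0), c(11, 0))
  es2 <- make_expr(cbind(v2, v2)) # 4 samples to satisfy the sheet builder
  ord2 <- hierarchical_order(es2, rownames(es2$values), standardize_rows = FALSE)
  pos2 <- match(c("f001", "f002"), ord2$features)
  expect_equal(abs(diff(pos2)), 1)
  expect_setequal(ord2$samples, colnames(es2$values))
})
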