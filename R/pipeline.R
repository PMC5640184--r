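#' Pipeline configuration
#'
#' Collects the tunable parameters of [run_pipeline()]; every argument has
#' a default so a minimal call only supplies the data.
#'
#' @param alpha FDR threshold used for differential selection and
#'   enrichment (in (0, 1)).
#' @param filter_fraction Low-expression filter threshold as a fraction of
#'   the sample count (default 12/28): a feature must exceed the grand mean
#'   on more than `floor(m * filter_fraction)` samples.
#' @param z_cut Robust z threshold of the PCA outlier screen.
#' @param K_max Largest component count considered by [estimate_ncp()]
#'   (default: the matrix cap).
#' @param ncp_method `"gcv"` (default) or `"smooth"`.
#' @param deflate Remove the first expression mode before ICA and extract
#'   `k - 1` components (default TRUE).
#' @param seed Seed for the ICA start.
#' @param tolerance FastICA convergence tolerance.
#' @param max_iter FastICA iteration cap.
#' @param strong_effect_convention Passed to [select_strong_effects()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(alpha = 0.05, filter_fraction = 12 / 28, z_cut = 3.0,
                            K_max = NULL, ncp_method = c("gcv", "smooth"),
                            deflate = TRUE, seed = 1L, tolerance = 1e-4,
                            max_iter = 1000L,
                            strong_effect_convention = c("signed", "absolute")) {
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (tolerance <= 0) abort("`tolerance` must be > 0.")
  structure(list(alpha = alpha, filter_fraction = filter_fraction, z_cut = z_cut,
                 K_max = K_max, ncp_method = match.arg(ncp_method),
                 deflate = deflate, seed = as.integer(seed),
                 tolerance = tolerance, max_iter = as.integer(max_iter),
                 strong_effect_convention = match.arg(strong_effect_convention)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains QC screening -> sample exclusion -> low-expression filtering ->
#' per-feature linear models with empirical-Bayes moderation -> differential
#' selection at FDR `alpha` -> gene-level matrix (unambiguous annotations;
#' features of one gene averaged) -> PCA with component-count estimation ->
#' two branches: (a) the global stage enriches the differential gene list
#' against each database universe; (b) the independent stage deflates the
#' first expression mode (optional), runs FastICA with `k - 1` components
#' (or `k` without deflation), selects ninth-decile contributors and
#' enriches each component against the differential background. Builds the
#' pathway-gene network from the significant global terms.
#'
#' @param expr An [expr_set()].
#' @param annotation Feature annotation tibble (`feature_id`, `gene_id`).
#' @param databases Named list of `gene_set_db` / `tr_target_db` objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when supplied, [write_reports()] runs
#'   and the manifest is attached to the result.
#' @return A `pipeline_run` list: `qc`, `expr_filtered`, `fit`,
#'   `differential`, `differential_gender`, `strong_effects`, `gene_expr`
#'   (genes x samples matrix), `pca`, `ncp`, `deflation`, `ica`,
#'   `contributors`, `overlap`, `enrichment` (one table per database and
#'   stage), `network`, `regulation`, `counts` (stage count log), `config`,
#'   and `manifest` when `out_dir` was given.
#' @export
run_pipeline <- function(expr, annotation, databases, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(expr, "expr_set"), inherits(config, "pipeline_config"))
  counts <- list(n_samples_in = ncol(expr$values), n_features_in = nrow(expr$values))

  qc <- qc_screen(expr, z_cut = config$z_cut, groups = expr$samples$timepoint)
  expr_kept <- apply_qc(expr, qc)
  counts$n_samples_kept <- ncol(expr_kept$values)

  min_samples <- floor(ncol(expr_kept$values) * config$filter_fraction)
  filtered <- filter_low_expressed(expr_kept, min_samples = min_samples)
  counts$n_features_filtered <- nrow(filtered$values)

  design <- build_design(filtered$samples)
  fit <- ebayes_moderate(fit_linear_models(filtered, design))
  differential <- select_differential(fit, "distance", alpha = config$alpha,
                                      annotation = annotation)
  differential_gender <- select_differential(fit, "gender", alpha = config$alpha,
                                             annotation = annotation)
  counts$n_differential_features <- nrow(differential)
  if (!nrow(differential)) abort("dgea: no differential features at the chosen FDR.")
  strong <- if (nrow(differential) >= 2) {
    select_strong_effects(differential, config$strong_effect_convention)
  } else {
    character(0)
  }
  counts$n_strong_effects <- length(strong)

  # gene-level matrix from unambiguous annotations; features sharing a gene averaged
  gene_rows <- differential[!is.na(differential$gene_id), ]
  counts$n_differential_genes <- dplyr::n_distinct(gene_rows$gene_id)
  if (counts$n_differential_genes < 12) {
    abort("decomposition: need >= 12 differential genes for ICA and the decile rule.")
  }
  gene_expr <- rowsum(filtered$values[gene_rows$feature_id, , drop = FALSE],
                      group = gene_rows$gene_id) /
    as.vector(table(gene_rows$gene_id)[sort(unique(gene_rows$gene_id))])
  regulation <- setNames(gene_rows$direction, gene_rows$gene_id)[rownames(gene_expr)]

  k_cap <- min(nrow(gene_expr) - 1, ncol(gene_expr) - 1)
  K_max <- min(config$K_max %||% max(1, floor(k_cap / 2)), k_cap)
  ncp <- estimate_ncp(gene_expr, method = config$ncp_method, K_max = K_max)
  k <- max(ncp$k, 2L)
  counts$k_estimated <- ncp$k
  pca <- fit_pca(gene_expr, K = k_cap)

  if (config$deflate) {
    deflation <- deflate_first_component(gene_expr, pca)
    ica_input <- deflation$x_hat
    k_ica <- max(k - 1L, 1L)
  } else {
    deflation <- NULL
    ica_input <- gene_expr
    k_ica <- k
  }
  counts$k_ica <- k_ica
  ica <- run_fastica(ica_input, k = k_ica, seed = config$seed,
                     tolerance = config$tolerance, max_iter = config$max_iter)
  contributors <- select_contributors(ica)
  counts$n_contributors_per_ic <- length(unique(contributors$gene_id[contributors$component == "IC1"]))
  overlap <- if (ica$k >= 2) contributor_overlap(contributors) else NULL

  diff_genes <- unique(gene_rows$gene_id)
  enrichment <- list()
  for (nm in names(databases)) {
    q <- stagewise_background(diff_genes, databases[[nm]])
    enrichment[[paste0(nm, "_global")]] <-
      run_enrichment(q$gene_list, databases[[nm]], q$background,
                     alpha = config$alpha, regulation = regulation)
    for (comp in unique(contributors$component)) {
      contrib <- contributors$gene_id[contributors$component == comp]
      qi <- stagewise_background(diff_genes, databases[[nm]], contributors = contrib)
      if (!length(qi$gene_list)) next
      enrichment[[paste0(nm, "_", comp)]] <-
        run_enrichment(qi$gene_list, databases[[nm]], qi$background,
                       alpha = config$alpha, regulation = regulation)
    }
  }
  counts$n_significant_terms <- vapply(enrichment, function(e) sum(e$significant), integer(1))
  global_names <- grep("_global$", names(enrichment), value = TRUE)
  sig_global <- dplyr::bind_rows(lapply(enrichment[global_names],
                                        function(e) e[e$significant, , drop = FALSE]))
  network <- suppressWarnings(build_network(sig_global, regulation = regulation))

  run <- structure(list(
    qc = qc, expr_filtered = filtered, fit = fit, differential = differential,
    differential_gender = differential_gender, strong_effects = strong,
    gene_expr = gene_expr, pca = pca, ncp = ncp, deflation = deflation,
    ica = ica, contributors = contributors, overlap = overlap,
    enrichment = enrichment, network = network, regulation = regulation,
    counts = counts, config = config
  ), class = "pipeline_run")
  if (!is.null(out_dir)) run$manifest <- write_reports(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf(paste0(
    "<pipeline_run>\n",
    "  samples: %d in, %d kept after QC\n",
    "  features: %d in, %d after filtering, %d differential (%d genes)\n",
    "  components: %d estimated, %d extracted by ICA\n",
    "  significant terms per stage: %s\n"),
    c0$n_samples_in, c0$n_samples_kept, c0$n_features_in, c0$n_features_filtered,
    c0$n_differential_features, c0$n_differential_genes, c0$k_estimated, c0$k_ica,
    paste(sprintf("%s=%d", names(c0$n_significant_terms), c0$n_significant_terms),
          collapse = ", ")))
  invisible(x)
}
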