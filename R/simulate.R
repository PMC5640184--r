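#' Simulation configuration
#'
#' Defines the study conditions the generator emulates: a paired pre/post
#' design with a continuous completed-distance covariate, a binary gender
#' covariate, gene-wise variances from a scaled inverse chi-square prior,
#' a sparse set of true distance effects (majority down-regulated), and
#' latent independent expression modes with Laplace (super-Gaussian)
#' activations so ICA identifiability holds. Defaults mirror a 16-subject
#' cohort of which 12 contribute a post-race sample, completed distances
#' drawn from an observed 14-82 km race record, and a 63:37 down:up split
#' of the distance effects.
#'
#' @param n_genes Number of simulated genes.
#' @param n_subjects Number of subjects (each contributes a pre sample).
#' @param post_fraction Fraction of subjects with a post sample.
#' @param distances_km Pool of completed distances sampled (with
#'   replacement) for post-race subjects.
#' @param male_fraction Probability a subject is male.
#' @param pi_diff Fraction of genes with a true distance effect.
#' @param effect_mean Mean |beta2| (log2 per km) of true effects; effects
#'   are drawn from Gamma(shape `effect_shape`, mean `effect_mean`).
#' @param effect_shape Gamma shape of the |beta2| distribution.
#' @param prop_down Fraction of true distance effects that are negative.
#' @param pi_gender Fraction of genes with a true gender effect.
#' @param gender_effect_sd SD of the gender effects (log2).
#' @param d0,s0_squared Variance-prior degrees of freedom and scale: gene
#'   variances are `s0_squared * d0 / chisq(d0)`.
#' @param k_modes Number of planted latent modes (mode 1 is the dominant,
#'   masking mode when `dominant_mode_scale > 1`).
#' @param mode_sparsity Fraction of genes loaded on each mode.
#' @param mode_scale Amplitude of the minor modes (log2 units per unit
#'   activation).
#' @param dominant_mode_scale Multiplier on mode 1's amplitude.
#' @param mode_distribution `"laplace"` (default) or `"gaussian"` (negative
#'   control: ICA cannot identify Gaussian modes).
#' @param subject_sd SD of the shared subject baseline (paired samples).
#' @param noise_sd Global multiplier on the gene noise SDs.
#' @param multi_annotation_fraction,unannotated_fraction Fractions of
#'   features mapped to two genes / to none in the simulated annotation.
#' @param seed Integer seed; all randomness flows from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 2000, n_subjects = 16,
                              post_fraction = 12 / 16,
                              distances_km = c(82, 50, 50, 25, 42, 50, 82, 25, 33, 50, 50, 14),
                              male_fraction = 12 / 17,
                              pi_diff = 0.10, effect_mean = 0.05,
                              effect_shape = 10, prop_down = 0.63,
                              pi_gender = 0.01, gender_effect_sd = 0.5,
                              d0 = 4, s0_squared = 0.05,
                              k_modes = 3, mode_sparsity = 0.10,
                              mode_scale = 0.6, dominant_mode_scale = 8,
                              mode_distribution = c("laplace", "gaussian"),
                              subject_sd = 0.15, noise_sd = 1,
                              multi_annotation_fraction = 0.08,
                              unannotated_fraction = 0.02,
                              seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_subjects = n_subjects, post_fraction = post_fraction,
    distances_km = distances_km, male_fraction = male_fraction,
    pi_diff = pi_diff, effect_mean = effect_mean, effect_shape = effect_shape,
    prop_down = prop_down, pi_gender = pi_gender,
    gender_effect_sd = gender_effect_sd, d0 = d0, s0_squared = s0_squared,
    k_modes = k_modes, mode_sparsity = mode_sparsity, mode_scale = mode_scale,
    dominant_mode_scale = dominant_mode_scale,
    mode_distribution = match.arg(mode_distribution),
    subject_sd = subject_sd, noise_sd = noise_sd,
    multi_annotation_fraction = multi_annotation_fraction,
    unannotated_fraction = unannotated_fraction, seed = as.integer(seed)
  )
  fracs <- c(post_fraction, male_fraction, pi_diff, prop_down, pi_gender,
             mode_sparsity, multi_annotation_fraction, unannotated_fraction)
  if (any(fracs < 0 | fracs > 1)) abort("All fractions must lie in [0, 1].")
  if (d0 <= 0 || s0_squared <= 0) abort("Variance prior requires d0 > 0 and s0_squared > 0.")
  if (n_subjects < 4 || n_genes < 20) abort("Simulation needs >= 4 subjects and >= 20 genes.")
  structure(cfg, class = "simulation_config")
}

rlaplace <- function(n, scale = 1 / sqrt(2)) {
  # unit variance when scale = 1/sqrt(2)
  u <- runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

#' Simulate a paired pre/post expression dataset
#'
#' Expression is built additively: gene baseline + shared subject baseline +
#' gender effect + distance effect + planted mode contributions + Gaussian
#' noise with gene-wise variances drawn from the scaled inverse chi-square
#' prior. Mode activations are residualized against the design (intercept,
#' gender, distance) and rescaled, so mode-loaded genes are exact nulls for
#' the distance coefficient and the differential ground truth stays
#' unambiguous.
#'
#' @param config A [simulation_config()].
#' @return List with `expr` (an [expr_set()]), `annotation` (tibble
#'   `feature_id`, `gene_id`; multi-annotated features carry two rows,
#'   unannotated ones an NA gene), and `truth` (list: `beta2`, `beta1`,
#'   `diff_genes`, `gender_genes`, `mode_weights` genes x modes,
#'   `mode_activations` samples x modes, `gene_sd`, `feature_gene` map).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(cfg$seed)

  n_post <- round(cfg$n_subjects * cfg$post_fraction)
  subjects <- sprintf("subj%02d", seq_len(cfg$n_subjects))
  gender <- ifelse(rbinom(cfg$n_subjects, 1, cfg$male_fraction) == 1, "male", "female")
  if (length(unique(gender)) == 1) gender[1] <- setdiff(c("male", "female"), gender[1])
  post_subjects <- subjects[seq_len(n_post)]
  dist_post <- sample(cfg$distances_km, n_post, replace = n_post > length(cfg$distances_km))
  samples <- tibble::tibble(
    sample_id = c(paste0(subjects, "_PRE"), paste0(post_subjects, "_POST")),
    subject_id = c(subjects, post_subjects),
    timepoint = rep(c("pre", "post"), c(cfg$n_subjects, n_post)),
    gender = c(gender, gender[seq_len(n_post)]),
    distance_km = c(rep(0, cfg$n_subjects), dist_post)
  )
  m <- nrow(samples)
  n <- cfg$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  g_vec <- as.numeric(samples$gender == "male")
  d_vec <- samples$distance_km

  # true effects
  n_diff <- round(n * cfg$pi_diff)
  diff_idx <- sample.int(n, n_diff)
  beta2 <- numeric(n)
  if (n_diff > 0) {
    mag <- stats::rgamma(n_diff, shape = cfg$effect_shape,
                         scale = cfg$effect_mean / cfg$effect_shape)
    sign_down <- rbinom(n_diff, 1, cfg$prop_down) == 1
    beta2[diff_idx] <- mag * ifelse(sign_down, -1, 1)
  }
  n_gender <- round(n * cfg$pi_gender)
  gender_idx <- if (n_gender > 0) sample(setdiff(seq_len(n), diff_idx), n_gender) else integer(0)
  beta1 <- numeric(n)
  beta1[gender_idx] <- rnorm(n_gender, 0, cfg$gender_effect_sd)

  # latent modes: weights sparse over genes, activations over samples
  mode_weights <- matrix(0, n, max(cfg$k_modes, 0))
  mode_activations <- matrix(0, m, max(cfg$k_modes, 0))
  if (cfg$k_modes > 0) {
    design <- cbind(1, g_vec, d_vec)
    n_loaded <- max(2, round(n * cfg$mode_sparsity))
    for (l in seq_len(cfg$k_modes)) {
      loaded <- sample.int(n, n_loaded)
      amp <- cfg$mode_scale * if (l == 1) cfg$dominant_mode_scale else 1
      mode_weights[loaded, l] <- rnorm(n_loaded, 0, 1) * amp
      act <- if (cfg$mode_distribution == "laplace") rlaplace(m) else rnorm(m)
      act <- stats::lm.fit(design, act)$residuals # orthogonal to the design
      mode_activations[, l] <- act / sd(act)
    }
  }

  gene_sd <- cfg$noise_sd * sqrt(cfg$s0_squared * cfg$d0 / rchisq(n, cfg$d0))
  baseline <- rnorm(n, 7, 1.5)
  subj_base <- matrix(rnorm(n * cfg$n_subjects, 0, cfg$subject_sd), n, cfg$n_subjects,
                      dimnames = list(genes, subjects))
  values <- baseline +
    outer(beta1, g_vec) + outer(beta2, d_vec) +
    mode_weights %*% t(mode_activations) +
    subj_base[, samples$subject_id] +
    matrix(rnorm(n * m), n, m) * gene_sd

  # feature annotation: 1:1 backbone with multi-annotated and unannotated tails
  features <- sprintf("TC%06d", seq_len(n))
  n_multi <- round(n * cfg$multi_annotation_fraction)
  n_unann <- round(n * cfg$unannotated_fraction)
  special <- sample.int(n, n_multi + n_unann)
  multi_idx <- special[seq_len(n_multi)]
  unann_idx <- special[n_multi + seq_len(n_unann)]
  annotation <- tibble::tibble(feature_id = features, gene_id = genes)
  annotation$gene_id[unann_idx] <- NA_character_
  if (n_multi > 0) {
    extra <- tibble::tibble(
      feature_id = features[multi_idx],
      gene_id = sprintf("G%05dB", multi_idx)
    )
    annotation <- dplyr::bind_rows(annotation, extra)
  }
  dimnames(values) <- list(features, samples$sample_id)

  truth <- list(
    beta2 = setNames(beta2, genes), beta1 = setNames(beta1, genes),
    diff_genes = genes[diff_idx], gender_genes = genes[gender_idx],
    mode_weights = `dimnames<-`(mode_weights,
                                list(genes, if (cfg$k_modes > 0) paste0("mode", seq_len(cfg$k_modes)))),
    mode_activations = `dimnames<-`(mode_activations,
                                    list(samples$sample_id,
                                         if (cfg$k_modes > 0) paste0("mode", seq_len(cfg$k_modes)))),
    gene_sd = setNames(gene_sd, genes),
    feature_gene = setNames(genes, features),
    config = cfg
  )
  list(expr = expr_set(values, samples), annotation = annotation, truth = truth)
}

#' Simulate annotation databases with planted enriched terms
#'
#' Builds a pathway-style gene-set database and a regulator-target database
#' over a gene universe. Background terms sample genes uniformly;
#' designated enriched terms oversample a target gene group (by default the
#' true differential genes) with the stated odds, so downstream enrichment
#' has known positives.
#'
#' @param truth Truth list from [simulate_dataset()] (or any list with a
#'   `feature_gene` universe and `diff_genes`).
#' @param n_terms Number of pathway terms.
#' @param term_size_range Integer range of term sizes.
#' @param enrichment_odds Sampling odds of a target-group gene relative to a
#'   background gene inside enriched terms (1 = no enrichment).
#' @param n_enriched Number of planted enriched terms.
#' @param target_genes Gene group the enriched terms oversample (defaults to
#'   `truth$diff_genes`).
#' @param n_regulators Number of regulators in the regulator-target
#'   database.
#' @param universe Gene universe (defaults to all simulated genes).
#' @param seed Integer seed.
#' @return List with `gene_sets` (`gene_set_db`, planted term ids in
#'   attribute `enriched_terms`), and `tr_targets` (`tr_target_db`, planted
#'   regulator ids in attribute `enriched_terms`; every universe gene is
#'   the target of at least one regulator).
#' @export
simulate_databases <- function(truth, n_terms = 100, term_size_range = c(20, 150),
                               enrichment_odds = 10, n_enriched = 3,
                               target_genes = truth$diff_genes,
                               n_regulators = 50,
                               universe = unname(truth$feature_gene),
                               seed = truth$config$seed + 1L) {
  if (enrichment_odds < 1) abort("`enrichment_odds` must be >= 1.")
  if (max(term_size_range) > length(universe)) {
    abort("Term sizes cannot exceed the universe size.")
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  weights <- rep(1, length(universe))
  weights[universe %in% target_genes] <- enrichment_odds
  draw_term <- function(size, enriched) {
    w <- if (enriched) weights else rep(1, length(universe))
    sample(universe, size, prob = w)
  }
  sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_terms, replace = TRUE)
  enriched_flag <- seq_len(n_terms) <= n_enriched
  gs <- gene_set_db(
    term_id = sprintf("T%03d", seq_len(n_terms)),
    term_name = sprintf("synthetic term %d%s", seq_len(n_terms),
                        ifelse(enriched_flag, " (planted)", "")),
    genes = purrr::map2(sizes, enriched_flag, draw_term),
    category = "synthetic"
  )
  attr(gs, "enriched_terms") <- gs$term_id[enriched_flag]
  tr_sizes <- sample(seq(term_size_range[1], term_size_range[2]), n_regulators,
                     replace = TRUE)
  tr_enriched <- seq_len(n_regulators) <= n_enriched
  tr_sets <- purrr::map2(tr_sizes, tr_enriched, draw_term)
  # guarantee the union covers the universe so the TR background is exact
  missing <- setdiff(universe, unlist(tr_sets, use.names = FALSE))
  if (length(missing)) {
    add_to <- sample.int(n_regulators, length(missing), replace = TRUE)
    for (i in seq_along(missing)) {
      tr_sets[[add_to[i]]] <- c(tr_sets[[add_to[i]]], missing[i])
    }
  }
  trs <- tr_target_db(setNames(tr_sets, sprintf("TR%03d", seq_len(n_regulators))))
  attr(trs, "enriched_terms") <- trs$tr_id[tr_enriched]
  list(gene_sets = gs, tr_targets = trs)
}
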