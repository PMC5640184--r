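#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance that a random
#' list of `n` genes drawn without replacement from a background of `N`
#' genes, of which `K` belong to the term, overlaps the term in at least `k`
#' genes. Evaluated through the log-space survival function for numerical
#' safety; the tail is inclusive ("at least as large as observed").
#'
#' @param k Observed overlap.
#' @param n Gene-list size within the background.
#' @param K Term size within the background.
#' @param N Background (universe) size.
#' @return The upper-tail probability (1 exactly when `k = 0`).
#' @export
hypergeometric_upper_tail <- function(k, n, K, N) {
  len <- max(length(k), length(n), length(K), length(N))
  if (!all(c(length(k), length(n), length(K), length(N)) %in% c(1L, len))) {
    abort("k, n, K, N must have equal lengths (or length 1).")
  }
  k <- rep_len(k, len); n <- rep_len(n, len)
  K <- rep_len(K, len); N <- rep_len(N, len)
  bad <- k < 0 | n < 0 | K < 0 | N < 0 | k > pmin(n, K) | n > N | K > N
  if (any(bad)) {
    abort(sprintf("Invalid hypergeometric counts at position %d: k=%g n=%g K=%g N=%g.",
                  which(bad)[1], k[which(bad)[1]], n[which(bad)[1]],
                  K[which(bad)[1]], N[which(bad)[1]]))
  }
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric overrepresentation analysis
#'
#' One engine serves pathway gene-set enrichment and transcriptional
#' regulator enrichment (a regulator's target set is just another gene
#' set). Every term with at least one background gene is tested with the
#' inclusive upper-tail hypergeometric probability; BH adjustment runs
#' across all tested terms of the query. When a regulation map is supplied
#' the percentage of up-regulated overlap genes is reported (genes missing
#' from the map are excluded from the denominator).
#'
#' @param gene_list Character vector of gene ids (the query list).
#' @param database A `gene_set_db` or `tr_target_db`.
#' @param background `"universe"` (all genes in the database; the global
#'   stage) or a character vector of gene ids (e.g. the differential list
#'   for the per-component stage). A custom background is intersected with
#'   the database universe; the query list is intersected with the
#'   effective background.
#' @param alpha Significance threshold on the adjusted p-value.
#' @param regulation Optional named character vector gene -> `"up"`/`"down"`.
#' @return An `enrichment_result` tibble sorted by adjusted p-value:
#'   `term_id`, `term_name`, `category`, `k` (overlap), `K` (term size in
#'   background), `n` (list size in background), `N` (background size),
#'   `gene_bg_ratio` ("k/n:K"), `p_value`, `adj_p`, `stars`, `significant`,
#'   `up_regulated_pct`, list-column `overlap_genes`. Attributes record the
#'   effective sizes and the number of query genes dropped for falling
#'   outside the background.
#' @export
run_enrichment <- function(gene_list, database, background = "universe",
                           alpha = 0.05, regulation = NULL) {
  if (inherits(database, "tr_target_db")) database <- as_gene_set_db(database)
  universe <- db_universe(database)
  bg <- if (identical(background, "universe")) universe else {
    intersect(unique(as.character(background)), universe)
  }
  n_bg <- length(bg)
  gene_list <- unique(as.character(gene_list))
  eff_list <- intersect(gene_list, bg)
  n_dropped <- length(gene_list) - length(eff_list)
  if (!length(eff_list)) {
    abort(sprintf(
      "Empty effective gene list: %d query genes, %d background genes, 0 in common.",
      length(gene_list), n_bg))
  }
  if (n_dropped > 0) {
    inform(sprintf("%d of %d query genes fall outside the background and were dropped.",
                   n_dropped, length(gene_list)))
  }
  term_bg <- lapply(database$genes, intersect, bg)
  keep <- lengths(term_bg) >= 1
  rows <- tibble::tibble(
    term_id = database$term_id[keep],
    term_name = database$term_name[keep],
    category = database$category[keep],
    overlap_genes = lapply(term_bg[keep], intersect, eff_list),
    K = lengths(term_bg[keep]),
    n = length(eff_list),
    N = n_bg
  )
  rows$k <- lengths(rows$overlap_genes)
  rows$gene_bg_ratio <- sprintf("%d/%d:%d", rows$k, rows$n, rows$K)
  rows$p_value <- hypergeometric_upper_tail(rows$k, rows$n, rows$K, rows$N)
  rows$adj_p <- bh_adjust(rows$p_value)
  rows$stars <- significance_stars(rows$adj_p)
  rows$significant <- rows$adj_p < alpha
  rows$up_regulated_pct <- if (is.null(regulation)) NA_real_ else {
    vapply(rows$overlap_genes, function(g) {
      reg <- regulation[intersect(g, names(regulation))]
      if (!length(reg)) NA_real_ else 100 * mean(reg == "up")
    }, numeric(1))
  }
  rows <- rows[order(rows$adj_p, rows$p_value, rows$term_id),
               c("term_id", "term_name", "category", "k", "K", "n", "N",
                 "gene_bg_ratio", "p_value", "adj_p", "stars", "significant",
                 "up_regulated_pct", "overlap_genes")]
  structure(rows, list_size = length(eff_list), background_size = n_bg,
            n_dropped = n_dropped, alpha = alpha,
            class = c("enrichment_result", class(rows)))
}

significance_stars <- function(adj_p) {
  cut(adj_p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "-"), right = FALSE) |> as.character()
}

#' Stage-dependent enrichment backgrounds
#'
#' The global stage tests the differential list against the whole database
#' universe; the per-component stage tests a component's contributor genes
#' against the differential genes present in the database (so component
#' enrichment asks "which terms concentrate in this mode *within* the
#' differential response").
#'
#' @param differential_genes Character vector (non-empty).
#' @param database A `gene_set_db` or `tr_target_db`.
#' @param contributors Optional character vector; supplying it selects the
#'   per-component stage.
#' @return List with `gene_list`, `background` (ready for
#'   [run_enrichment()]) and `stage` (`"global"` or `"component"`).
#' @export
stagewise_background <- function(differential_genes, database, contributors = NULL) {
  if (!length(differential_genes)) abort("`differential_genes` must be non-empty.")
  if (is.null(contributors)) {
    list(gene_list = unique(differential_genes), background = "universe",
         stage = "global")
  } else {
    if (!length(contributors)) abort("Component stage requires a non-empty contributor set.")
    universe <- db_universe(if (inherits(database, "tr_target_db")) {
      as_gene_set_db(database)
    } else {
      database
    })
    bg <- intersect(unique(differential_genes), universe)
    list(gene_list = intersect(unique(contributors), bg), background = bg,
         stage = "component")
  }
}
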