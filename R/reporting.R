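#' Pathway-gene bipartite network
#'
#' Connects significant enrichment terms to their overlap genes. Term nodes
#' carry their category and degree (the overlap size); gene nodes carry the
#' regulation direction when a regulation map is supplied.
#'
#' @param rows An `enrichment_result` (typically filtered to significant
#'   terms; rows with zero overlap are dropped).
#' @param regulation Optional named vector gene -> `"up"`/`"down"`.
#' @return An igraph graph with vertex attributes `type`
#'   (`"pathway"`/`"gene"`), `category`, `direction`; attributes
#'   `n_components` (connected components) and `n_genes` (distinct genes)
#'   are stored as graph attributes.
#' @export
build_network <- function(rows, regulation = NULL) {
  rows <- rows[lengths(rows$overlap_genes) > 0, , drop = FALSE]
  if (!nrow(rows)) {
    warn("No terms with overlap genes: returning an empty network.")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  edges <- tibble::tibble(
    pathway = rep(rows$term_id, lengths(rows$overlap_genes)),
    gene = unlist(rows$overlap_genes, use.names = FALSE)
  )
  genes <- unique(edges$gene)
  vertices <- dplyr::bind_rows(
    tibble::tibble(name = rows$term_id, type = "pathway",
                   category = rows$category, direction = NA_character_),
    tibble::tibble(name = genes, type = "gene", category = NA_character_,
                   direction = if (is.null(regulation)) NA_character_ else {
                     unname(regulation[genes])
                   })
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  g <- igraph::set_graph_attr(g, "n_components", igraph::count_components(g))
  igraph::set_graph_attr(g, "n_genes", length(genes))
}

#' Write the pipeline's artifacts and a run manifest
#'
#' Serializes every stage output (QC report, differential tables, PCA/ICA
#' matrices, contributor lists, enrichment tables, network) under
#' `out_dir` and writes `manifest.json` recording the seed, a configuration
#' hash, stage counts and the produced files.
#'
#' @param run A `pipeline_run` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_reports <- function(run, out_dir) {
  stopifnot(inherits(run, "pipeline_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  files <- character(0)
  put_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.list),
                                          ~ vapply(.x, paste, "", collapse = ";")))
    readr::write_tsv(df, path, progress = FALSE)
    files <<- c(files, name)
  }
  put_tsv(run$qc, "qc_report.tsv")
  put_tsv(run$differential, "differential_distance.tsv")
  if (!is.null(run$differential_gender)) {
    put_tsv(run$differential_gender, "differential_gender.tsv")
  }
  put_tsv(tibble::as_tibble(run$ica$S, rownames = "sample_id"), "ica_sources.tsv")
  put_tsv(tibble::as_tibble(t(run$ica$A), rownames = "gene_id"), "ica_mixing.tsv")
  put_tsv(run$contributors, "contributors.tsv")
  put_tsv(run$ncp$curve, "ncp_criterion.tsv")
  put_tsv(tibble::tibble(component = paste0("PC", seq_along(run$pca$variance_fraction)),
                         variance_fraction = run$pca$variance_fraction),
          "pca_variance.tsv")
  for (nm in names(run$enrichment)) {
    put_tsv(run$enrichment[[nm]], paste0("enrichment_", nm, ".tsv"))
  }
  if (igraph::vcount(run$network) > 0) {
    gml <- file.path(out_dir, "pathway_gene_network.graphml")
    igraph::write_graph(run$network, gml, format = "graphml")
    files <- c(files, "pathway_gene_network.graphml")
    put_tsv(tibble::as_tibble(igraph::as_data_frame(run$network, "edges")),
            "pathway_gene_edges.tsv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("icadex")),
    seed = run$config$seed,
    config_hash = rlang::hash(run$config),
    counts = run$counts,
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
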