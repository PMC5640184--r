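#' Read a feature-to-gene annotation table
#'
#' TSV with columns `feature_id` and `gene_id`; a feature annotated to
#' several genes appears on several rows, an unannotated feature on one row
#' with an empty/NA `gene_id`.
#'
#' @param path Path to the TSV (optionally `.gz`).
#' @return Annotation tibble with columns `feature_id`, `gene_id` (NA for
#'   unannotated features); duplicate (feature, gene) pairs are collapsed.
#' @export
read_feature_annotation <- function(path) {
  ann <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), gene_id = readr::col_character()
  ), progress = FALSE)
  ann$gene_id[!is.na(ann$gene_id) & !nzchar(ann$gene_id)] <- NA_character_
  dplyr::distinct(ann, .data$feature_id, .data$gene_id)
}

#' Partition features by annotation multiplicity
#'
#' Splits features into those unambiguously annotated to a single gene,
#' those with multiple gene annotations, and unannotated ones. Gene-level
#' analyses downstream use the unambiguous partition only; several features
#' may collapse onto one gene, so the distinct-gene count is reported.
#'
#' @param features Character vector of feature ids.
#' @param annotation Annotation tibble (`feature_id`, `gene_id`), as from
#'   [read_feature_annotation()]. Features absent from the table count as
#'   unannotated.
#' @return List with elements `unambiguous` (tibble `feature_id`,
#'   `gene_id`), `ambiguous` (named list feature -> gene vector),
#'   `unannotated` (character vector) and `n_distinct_genes` (genes of the
#'   unambiguous partition). The three partitions are disjoint and cover
#'   the input.
#' @export
map_features_to_genes <- function(features, annotation) {
  features <- as.character(features)
  ann <- annotation[!is.na(annotation$gene_id) & annotation$feature_id %in% features, ,
                    drop = FALSE]
  ann <- dplyr::distinct(ann, .data$feature_id, .data$gene_id)
  genes_per_feature <- split(ann$gene_id, ann$feature_id)
  n_ann <- lengths(genes_per_feature)[match(features, names(genes_per_feature))]
  n_ann[is.na(n_ann)] <- 0L
  unamb <- features[n_ann == 1L]
  out <- list(
    unambiguous = tibble::tibble(
      feature_id = unamb,
      gene_id = unname(vapply(genes_per_feature[unamb], `[[`, "", 1))
    ),
    ambiguous = genes_per_feature[features[n_ann > 1L]],
    unannotated = features[n_ann == 0L]
  )
  out$n_distinct_genes <- dplyr::n_distinct(out$unambiguous$gene_id)
  out
}
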