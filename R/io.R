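#' Read an expression matrix and its sample sheet
#'
#' The matrix carrier is TSV: a header row of sample ids, first column of
#' feature ids, numeric log2 intensities elsewhere. The sample sheet is TSV
#' with columns `sample_id`, `subject_id`, `timepoint` (pre|post), `gender`
#' (male|female), `distance_km`. Gzip-compressed files are read
#' transparently. Matrix columns are reordered to sample-sheet order.
#'
#' @param matrix_path Path to the expression TSV (optionally `.gz`).
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @return An [expr_set()].
#' @export
read_expression_matrix <- function(matrix_path, sample_sheet_path) {
  raw <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("Expression TSV needs a feature-id column plus sample columns.")
  feature_ids <- raw[[1]]
  if (anyDuplicated(feature_ids)) {
    dup <- unique(feature_ids[duplicated(feature_ids)])
    abort(sprintf("Duplicate feature id(s) in %s: %s", matrix_path,
                  paste(head(dup, 5), collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                    dimnames = list(feature_ids, colnames(cells))))
  bad <- is.na(values) & !(is.na(cells) | cells %in% c("NA", "NaN"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf("Non-numeric cell '%s' at feature '%s', sample '%s'.",
                  cells[idx[1], idx[2]], feature_ids[idx[1]], colnames(cells)[idx[2]]))
  }
  samples <- read_sample_sheet(sample_sheet_path)
  expr_set(values, samples)
}

#' Read a sample sheet
#'
#' @param path TSV file with the columns documented in
#'   [read_expression_matrix()].
#' @return A validated sample tibble (with an `included` flag column).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), subject_id = readr::col_character(),
    timepoint = readr::col_character(), gender = readr::col_character(),
    distance_km = readr::col_double(), .default = readr::col_guess()
  ), progress = FALSE)
  validate_sample_sheet(sheet)
}

#' Write an expression set to TSV
#'
#' Inverse of [read_expression_matrix()]: full-precision TSV round-trips are
#' value-identical.
#'
#' @param x An [expr_set()].
#' @param matrix_path Output path for the matrix TSV.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @return `x`, invisibly.
#' @export
write_expression_matrix <- function(x, matrix_path, sample_sheet_path = NULL) {
  stopifnot(inherits(x, "expr_set"))
  df <- tibble::as_tibble(x$values, rownames = "feature_id")
  readr::write_tsv(df, matrix_path, progress = FALSE)
  if (!is.null(sample_sheet_path)) {
    readr::write_tsv(x$samples, sample_sheet_path, progress = FALSE)
  }
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' One term per line, tab-separated: term id, description, then gene ids.
#' Duplicate genes within a line are collapsed; lines with fewer than three
#' fields are skipped with a warning; empty lines are ignored.
#'
#' @param gmt_path Path to a GMT file (optionally `.gz`).
#' @param category Optional category label stored on every term (e.g. the
#'   database name).
#' @return A `gene_set_db`: tibble with columns `term_id`, `term_name`,
#'   `category` and a list-column `genes` (character vectors); the attribute
#'   `universe` holds the union of all gene sets.
#' @export
read_gene_sets <- function(gmt_path, category = NA_character_) {
  lines <- readr::read_lines(gmt_path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    warn(sprintf("Skipping %d GMT line(s) with fewer than 3 fields.", sum(short)))
    fields <- fields[!short]
  }
  if (!length(fields)) abort(sprintf("No valid gene-set lines in %s.", gmt_path))
  gene_set_db(
    term_id = vapply(fields, `[[`, "", 1),
    term_name = vapply(fields, `[[`, "", 2),
    genes = lapply(fields, function(f) unique(f[-(1:2)][nzchar(f[-(1:2)])])),
    category = category
  )
}

#' Construct a gene-set database
#'
#' @param term_id,term_name Character vectors.
#' @param genes List of character vectors (one non-empty set per term).
#' @param category Character scalar or vector of category labels.
#' @return A `gene_set_db` tibble; see [read_gene_sets()].
#' @export
gene_set_db <- function(term_id, term_name = term_id, genes, category = NA_character_) {
  if (anyDuplicated(term_id)) abort("Gene-set term ids must be unique.")
  if (any(lengths(genes) == 0)) abort("Every gene set must be non-empty.")
  db <- tibble::tibble(term_id = as.character(term_id),
                       term_name = as.character(term_name),
                       category = rep_len(as.character(category), length(term_id)),
                       genes = lapply(genes, function(g) unique(as.character(g))))
  structure(db, universe = unique(unlist(db$genes, use.names = FALSE)),
            class = c("gene_set_db", class(db)))
}

#' Write a gene-set database as GMT
#'
#' @param db A `gene_set_db`.
#' @param gmt_path Output path.
#' @return `db`, invisibly.
#' @export
write_gene_sets <- function(db, gmt_path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$term_id[i], db$term_name[i], db$genes[[i]]), collapse = "\t")
  }, "")
  readr::write_lines(lines, gmt_path)
  invisible(db)
}

#' Universe of a gene-set or regulator-target database
#'
#' @param db A `gene_set_db` or `tr_target_db`.
#' @return Character vector: the union of all member sets.
#' @export
db_universe <- function(db) attr(db, "universe")

#' Read a regulator-to-target table
#'
#' TSV with columns `tr_id`, `target_gene_id`, `type`. Only rows whose
#' `type` equals `type_filter` are kept (the transcription-factor-binding-site
#' subset of an ORegAnno-style interaction dump, by default); duplicated
#' (regulator, target) pairs collapse to one edge.
#'
#' @param tsv_path Path to the TSV (optionally `.gz`).
#' @param type_filter Regulation type to keep.
#' @return A `tr_target_db`: tibble with columns `tr_id` and list-column
#'   `targets`; attribute `universe` is the set of distinct targets. The
#'   numbers of regulators and distinct targets are reported via a message.
#' @export
read_tr_targets <- function(tsv_path, type_filter = "transcription factor binding site") {
  raw <- readr::read_tsv(tsv_path, col_types = readr::cols(
    tr_id = readr::col_character(), target_gene_id = readr::col_character(),
    type = readr::col_character()
  ), progress = FALSE)
  kept <- raw[raw$type == type_filter, , drop = FALSE]
  if (!nrow(kept)) {
    abort(sprintf("No rows with type '%s' in %s.", type_filter, tsv_path))
  }
  db <- tr_target_db(split(kept$target_gene_id, kept$tr_id))
  inform(sprintf("Regulator-target database: %d regulators, %d distinct targets.",
                 nrow(db), length(db_universe(db))))
  db
}

#' Construct a regulator-target database
#'
#' @param targets Named list: regulator id -> character vector of target
#'   gene ids.
#' @return A `tr_target_db` tibble (columns `tr_id`, `targets`), with the
#'   distinct-target universe as attribute.
#' @export
tr_target_db <- function(targets) {
  if (is.null(names(targets)) || anyDuplicated(names(targets))) {
    abort("`targets` must be a uniquely named list of regulator target sets.")
  }
  db <- tibble::tibble(tr_id = names(targets),
                       targets = lapply(targets, function(g) unique(as.character(g))))
  structure(db, universe = unique(unlist(db$targets, use.names = FALSE)),
            class = c("tr_target_db", class(db)))
}

#' View a regulator-target database as a gene-set database
#'
#' Regulators become terms whose gene sets are their targets; the enrichment
#' engine then serves pathway and regulator analyses identically.
#'
#' @param db A `tr_target_db`.
#' @return A `gene_set_db` with category `"TR"`.
#' @export
as_gene_set_db <- function(db) {
  stopifnot(inherits(db, "tr_target_db"))
  gene_set_db(term_id = db$tr_id, term_name = db$tr_id,
              genes = db$targets, category = "TR")
}
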