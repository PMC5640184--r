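#' Expression set container
#'
#' An `expr_set` couples a log2 expression matrix (features in rows, samples
#' in columns) with its sample sheet. The sample sheet is a tibble with one
#' row per matrix column, in matrix column order, holding the covariates the
#' per-feature linear model uses: subject, pre/post timepoint, gender and the
#' completed distance in km.
#'
#' @param values Numeric matrix, features x samples, log2 intensities, with
#'   rownames (feature ids) and colnames (sample ids). No missing values.
#' @param samples Tibble/data frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`"pre"`/`"post"`), `gender` (`"male"`/`"female"`),
#'   `distance_km` (non-negative; 0 for pre-race samples under the default
#'   encoding). Rows must match `colnames(values)` in order or be matchable
#'   by `sample_id`.
#'
#' @return An object of class `expr_set`: a list with elements `values`
#'   (matrix) and `samples` (tibble with an `included` QC flag column).
#' @export
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
#' sheet <- tibble::tibble(
#'   sample_id = paste0("s", 1:4), subject_id = c("a", "a", "b", "b"),
#'   timepoint = c("pre", "post", "pre", "post"),
#'   gender = c("male", "male", "female", "female"),
#'   distance_km = c(0, 50, 0, 82))
#' es <- expr_set(m, sheet)
#' es
expr_set <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Expression matrix contains missing values (first at feature '%s', sample '%s').",
      rownames(values)[bad[1]] %||% bad[1], colnames(values)[bad[2]] %||% bad[2]
    ))
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry feature ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(sprintf("Duplicate feature id(s): %s", paste(head(dup, 5), collapse = ", ")))
  }
  if (nrow(values) < 1 || ncol(values) < 2) {
    abort("Expression matrix needs at least 1 feature and 2 samples.")
  }
  samples <- validate_sample_sheet(samples)
  missing_in_sheet <- setdiff(colnames(values), samples$sample_id)
  missing_in_matrix <- setdiff(samples$sample_id, colnames(values))
  if (length(missing_in_sheet) || length(missing_in_matrix)) {
    abort(paste0(
      "Sample ids of matrix and sample sheet do not match.",
      if (length(missing_in_sheet)) {
        sprintf("\n  In matrix but not sheet: %s", paste(missing_in_sheet, collapse = ", "))
      },
      if (length(missing_in_matrix)) {
        sprintf("\n  In sheet but not matrix: %s", paste(missing_in_matrix, collapse = ", "))
      }
    ))
  }
  values <- values[, samples$sample_id, drop = FALSE]
  structure(list(values = values, samples = samples), class = "expr_set")
}

validate_sample_sheet <- function(samples) {
  required <- c("sample_id", "subject_id", "timepoint", "gender", "distance_km")
  miss <- setdiff(required, names(samples))
  if (length(miss)) {
    abort(sprintf("Sample sheet lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  samples <- tibble::as_tibble(samples)
  samples$sample_id <- as.character(samples$sample_id)
  samples$subject_id <- as.character(samples$subject_id)
  if (anyDuplicated(samples$sample_id)) {
    abort("Sample ids in the sample sheet must be unique.")
  }
  if (!all(samples$timepoint %in% c("pre", "post"))) {
    abort("`timepoint` must be 'pre' or 'post'.")
  }
  if (!all(samples$gender %in% c("male", "female"))) {
    abort("`gender` must be 'male' or 'female'.")
  }
  if (!is.numeric(samples$distance_km) || any(samples$distance_km < 0)) {
    abort("`distance_km` must be non-negative numeric.")
  }
  per <- table(samples$subject_id, samples$timepoint)
  if (any(per > 1)) {
    abort("Each subject may have at most one pre and one post sample.")
  }
  if (!"included" %in% names(samples)) samples$included <- TRUE
  samples
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf(
    "<expr_set> %d features x %d samples (%d pre, %d post)\n",
    nrow(x$values), ncol(x$values),
    sum(x$samples$timepoint == "pre"), sum(x$samples$timepoint == "post")
  ))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Subset an expression set
#'
#' @param x An [expr_set()].
#' @param features,samples Character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return An `expr_set` restricted to the requested features/samples.
#' @export
expr_subset <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_set"))
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  sheet <- x$samples
  if (!is.null(samples)) {
    v <- v[, samples, drop = FALSE]
    sheet <- sheet[match(colnames(v), sheet$sample_id), , drop = FALSE]
  }
  expr_set(v, sheet)
}
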