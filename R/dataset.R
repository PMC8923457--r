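#' Build an expression dataset from a samples-by-genes data frame
#'
#' The central container used by every stage of the pipeline: a numeric
#' expression matrix (samples in rows, genes in columns), sample and gene
#' identifiers, and one class label per sample. Labels may be arbitrary
#' (integers, characters, factors); internally they are remapped to contiguous
#' integers `1..C` in order of first appearance, and the original labels are
#' restored on output.
#'
#' @param data A data frame with one row per sample: a label column
#'   (`label_col`), optionally a sample-identifier column (`id_col`), and one
#'   numeric column per gene.
#' @param label_col Name of the class-label column. Default `"class"`.
#' @param id_col Name of the sample-identifier column, or `NULL` to use row
#'   numbers. Default `"sample_id"` when present, otherwise `NULL`.
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix` (samples x genes), `gene_ids`, `sample_ids`, `labels` (integer
#'   `1..C`), and `label_levels` (original label of each internal class).
#' @examples
#' d <- tibble::tibble(
#'   class = c(1, 1, 2, 2),
#'   g1 = rnorm(4), g2 = rnorm(4)
#' )
#' ds <- as_expression_dataset(d)
#' ds$gene_ids
#' @export
as_expression_dataset <- function(data, label_col = "class", id_col = NULL) {
  if (inherits(data, "expression_dataset")) {
    return(data)
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!label_col %in% names(data)) {
    abort(
      paste0("label column '", label_col, "' not found"),
      class = "pgsa_error_missing_labels"
    )
  }
  if (is.null(id_col) && "sample_id" %in% names(data)) {
    id_col <- "sample_id"
  }
  sample_ids <- if (!is.null(id_col)) {
    as.character(data[[id_col]])
  } else {
    sprintf("s%03d", seq_len(nrow(data)))
  }
  raw_labels <- data[[label_col]]
  gene_cols <- setdiff(names(data), c(label_col, id_col))
  mat <- as.matrix(data[gene_cols])
  if (!is.numeric(mat)) {
    bad <- gene_cols[!vapply(data[gene_cols], is.numeric, logical(1))]
    abort(
      paste0(
        "non-numeric expression column(s): ",
        paste(head(bad, 5), collapse = ", ")
      ),
      class = "pgsa_error_parse"
    )
  }
  new_expression_dataset(mat, gene_cols, sample_ids, raw_labels)
}

# Low-level constructor from parts; remaps labels to 1..C by first appearance.
new_expression_dataset <- function(matrix, gene_ids, sample_ids, labels) {
  levels <- unique(labels)
  ds <- structure(
    list(
      matrix = unname(as.matrix(matrix)),
      gene_ids = as.character(gene_ids),
      sample_ids = as.character(sample_ids),
      labels = match(labels, levels),
      label_levels = levels
    ),
    class = "expression_dataset"
  )
  validate_dataset(ds)
}

#' Validate an expression dataset
#'
#' Checks every structural invariant of [as_expression_dataset()] and returns
#' the dataset unchanged if all hold. Each violation raises a distinct,
#' classed error so callers can react programmatically:
#' `pgsa_error_dimension` (matrix rows/columns disagree with identifier or
#' label lengths), `pgsa_error_missing_values` (any `NA`/`NaN`),
#' `pgsa_error_too_few_classes` (fewer than 2 distinct labels), and
#' `pgsa_error_small_class` (a class with fewer than 2 samples).
#'
#' @param dataset An `expression_dataset`.
#' @return The dataset, invisibly unchanged.
#' @export
validate_dataset <- function(dataset) {
  m <- dataset$matrix
  if (nrow(m) != length(dataset$labels) ||
    nrow(m) != length(dataset$sample_ids)) {
    abort(
      "matrix row count must equal the number of labels and sample ids",
      class = "pgsa_error_dimension"
    )
  }
  if (ncol(m) != length(dataset$gene_ids)) {
    abort(
      "matrix column count must equal the number of gene ids",
      class = "pgsa_error_dimension"
    )
  }
  if (anyNA(m) || any(!is.finite(m))) {
    abort(
      "expression matrix contains missing or non-finite values",
      class = "pgsa_error_missing_values"
    )
  }
  counts <- tabulate(dataset$labels)
  if (length(counts) < 2) {
    abort(
      "fewer than 2 classes in labels",
      class = "pgsa_error_too_few_classes"
    )
  }
  if (any(counts < 2)) {
    abort(
      paste0(
        "every class needs at least 2 samples; class(es) ",
        paste(which(counts < 2), collapse = ", "), " too small"
      ),
      class = "pgsa_error_small_class"
    )
  }
  if (anyDuplicated(dataset$gene_ids)) {
    abort("duplicate gene identifiers", class = "pgsa_error_duplicate_ids")
  }
  dataset
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(
    "<expression_dataset> ", nrow(x$matrix), " samples x ",
    ncol(x$matrix), " genes, ", length(x$label_levels), " classes\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

# Subset genes by column index, keeping order; used by the filter and pyramid.
subset_genes <- function(dataset, gene_idx) {
  structure(
    list(
      matrix = dataset$matrix[, gene_idx, drop = FALSE],
      gene_ids = dataset$gene_ids[gene_idx],
      sample_ids = dataset$sample_ids,
      labels = dataset$labels,
      label_levels = dataset$label_levels
    ),
    class = "expression_dataset"
  )
}

n_classes <- function(dataset) length(dataset$label_levels)

#' Convert an expression dataset back to a tibble
#'
#' Inverse of [as_expression_dataset()]: one row per sample with `sample_id`,
#' `class` (original labels) and one column per gene.
#'
#' @param x An `expression_dataset`.
#' @param ... Unused.
#' @return A tibble.
#' @export
as_tibble.expression_dataset <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$matrix), .name_repair = "minimal")
  names(out) <- x$gene_ids
  dplyr::bind_cols(
    tibble(
      sample_id = x$sample_ids,
      class = x$label_levels[x$labels]
    ),
    out
  )
}
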