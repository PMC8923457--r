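#' Read a delimited expression matrix
#'
#' Reads a CSV/TSV expression table (delimiter sniffed from the header line)
#' into an `expression_dataset`. Two layouts are supported:
#' `orientation = "samples"` — one row per sample, first column sample ids,
#' a label column named by `label_col`, remaining columns genes; and
#' `orientation = "genes"` — one row per gene (series-matrix convention),
#' first column gene ids, one column per sample, in which case labels come
#' from `labels_path`, a two-column delimited file (sample id, label).
#'
#' Parse problems raise distinct classed errors: a non-numeric cell names
#' its row and column (`pgsa_error_parse`), duplicate identifiers raise
#' `pgsa_error_duplicate_ids`, and absent labels raise
#' `pgsa_error_missing_labels`.
#'
#' @param path Path to the matrix file.
#' @param orientation `"samples"` (default) or `"genes"`.
#' @param label_col Label column name for samples-in-rows input.
#'   Default `"class"`.
#' @param labels_path Label file for genes-in-rows input.
#' @return A validated `expression_dataset`.
#' @export
read_expression_matrix <- function(path, orientation = c("samples", "genes"),
                                   label_col = "class", labels_path = NULL) {
  orientation <- match.arg(orientation)
  delim <- sniff_delim(path)
  header <- strsplit(readLines(path, n = 1), delim, fixed = TRUE)[[1]]
  check_duplicates(header, if (orientation == "samples") "gene" else "sample")
  raw <- readr::read_delim(
    path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (orientation == "samples") {
    if (!label_col %in% names(raw)) {
      abort(
        paste0("label column '", label_col, "' not found in ", path),
        class = "pgsa_error_missing_labels"
      )
    }
    ids <- raw[[1]]
    labels <- parse_labels(raw[[label_col]])
    gene_cols <- setdiff(names(raw), c(names(raw)[1], label_col))
    mat <- parse_numeric_matrix(raw[gene_cols], rownames = ids)
    check_duplicates(ids, "sample")
    check_duplicates(gene_cols, "gene")
    new_expression_dataset(mat, gene_cols, ids, labels)
  } else {
    if (is.null(labels_path)) {
      abort("genes-in-rows input needs labels_path",
        class = "pgsa_error_missing_labels"
      )
    }
    gene_ids <- raw[[1]]
    sample_ids <- names(raw)[-1]
    mat <- parse_numeric_matrix(raw[-1], rownames = gene_ids)
    check_duplicates(gene_ids, "gene")
    check_duplicates(sample_ids, "sample")
    lab_tbl <- readr::read_delim(
      labels_path,
      delim = sniff_delim(labels_path),
      col_types = readr::cols(.default = readr::col_character()),
      progress = FALSE, show_col_types = FALSE
    )
    idx <- match(sample_ids, lab_tbl[[1]])
    if (anyNA(idx)) {
      abort(
        paste0(
          "labels missing for sample(s): ",
          paste(head(sample_ids[is.na(idx)], 5), collapse = ", ")
        ),
        class = "pgsa_error_missing_labels"
      )
    }
    labels <- parse_labels(lab_tbl[[2]][idx])
    new_expression_dataset(t(mat), gene_ids, sample_ids, labels)
  }
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1)
  if (grepl("\t", header)) "\t" else ","
}

# Integer-looking labels become integers; anything else stays character
# (remapped to 1..C inside the dataset constructor either way).
parse_labels <- function(x) {
  num <- suppressWarnings(as.integer(x))
  if (!anyNA(num)) num else x
}

parse_numeric_matrix <- function(df, rownames) {
  mat <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df))
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !is.na(df[[j]]) | is.na(df[[j]]))
    if (length(bad)) {
      abort(
        sprintf(
          "non-numeric value '%s' at row '%s', column '%s'",
          df[[j]][bad[1]], rownames[bad[1]], names(df)[j]
        ),
        class = "pgsa_error_parse"
      )
    }
    mat[, j] <- v
  }
  mat
}

check_duplicates <- function(ids, what) {
  if (anyDuplicated(ids)) {
    abort(
      paste0(
        "duplicate ", what, " identifier(s): ",
        paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", ")
      ),
      class = "pgsa_error_duplicate_ids"
    )
  }
}

#' Write an expression dataset as delimited text
#'
#' Samples-in-rows layout, readable by [read_expression_matrix()]: columns
#' `sample_id`, `class` (original labels), then one column per gene.
#'
#' @param data A samples-by-genes data frame, `expression_dataset`, or
#'   `pgsa_sim`.
#' @param path Output path; `.tsv` extension writes tab-separated, anything
#'   else comma-separated.
#' @inheritParams as_expression_dataset
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(data, path, label_col = "class") {
  if (inherits(data, "pgsa_sim")) data <- data$data
  ds <- as_expression_dataset(data, label_col = label_col)
  tbl <- as_tibble(ds)
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(tbl, path, progress = FALSE)
  } else {
    readr::write_csv(tbl, path, progress = FALSE)
  }
  invisible(path)
}

#' Serialize a selection result
#'
#' Writes a structured JSON report (final genes, per-cycle trace, seed, and
#' a full configuration echo sufficient for an exact re-run) to `path`, plus
#' a flat one-gene-per-line text file at `<path without extension>_genes.txt`.
#'
#' @param result A `pgsa_result`.
#' @param path Output path for the JSON report.
#' @return `path`, invisibly.
#' @seealso [read_selection_result()]
#' @export
write_selection_result <- function(result, path) {
  trace <- result$cycle_trace
  payload <- list(
    final_genes = result$final_genes,
    final_accuracy = result$final_accuracy,
    n_evaluations = result$n_evaluations,
    filtered_genes = result$filtered_genes,
    cycle_trace = lapply(seq_len(nrow(trace)), function(i) {
      list(
        cycle = trace$cycle[i],
        pool_size_in = trace$pool_size_in[i],
        pool_size = trace$pool_size[i],
        best_accuracy = trace$best_accuracy[i],
        genes = trace$genes[[i]],
        empty_mask = trace$empty_mask[i]
      )
    }),
    config = config_to_list(result$config)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  genes_path <- sub("\\.[^.]*$", "", path)
  writeLines(result$final_genes, paste0(genes_path, "_genes.txt"))
  invisible(path)
}

#' Read back a serialized selection result
#'
#' Reconstructs a `pgsa_result` from the JSON written by
#' [write_selection_result()] (the entropy ranking and split, which are
#' derivable from the data and config echo, are not stored).
#'
#' @param path Path to the JSON report.
#' @return A `pgsa_result`.
#' @export
read_selection_result <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  chr <- function(x) vapply(x, as.character, character(1))
  trace <- dplyr::bind_rows(lapply(p$cycle_trace, function(cy) {
    tibble(
      cycle = as.integer(cy$cycle),
      pool_size_in = as.integer(cy$pool_size_in),
      pool_size = as.integer(cy$pool_size),
      best_accuracy = as.numeric(cy$best_accuracy),
      genes = list(chr(cy$genes)),
      empty_mask = isTRUE(cy$empty_mask)
    )
  }))
  structure(
    list(
      final_genes = chr(p$final_genes),
      final_accuracy = as.numeric(p$final_accuracy),
      cycle_trace = trace,
      ranking = NULL,
      filtered_genes = chr(p$filtered_genes),
      n_evaluations = as.integer(p$n_evaluations),
      split = NULL,
      config = config_from_list(p$config)
    ),
    class = "pgsa_result"
  )
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$ibgsa <- unclass(out$ibgsa)
  out
}

config_from_list <- function(lst) {
  ib <- lst$ibgsa %||% list()
  pyramid_config(
    n_filter = lst$n_filter %||% 500,
    n_cycles = lst$n_cycles %||% 8,
    ibgsa = do.call(ibgsa_params, ib),
    eval_budget = lst$eval_budget %||% 480,
    train_fraction = lst$train_fraction %||% 0.7,
    svm_degree = lst$svm_degree %||% 3,
    svm_gamma = lst$svm_gamma %||% 1,
    svm_tol = lst$svm_tol %||% 0.001,
    entropy_bins = lst$entropy_bins %||% 10,
    standardize = lst$standardize %||% TRUE,
    swarm_init = lst$swarm_init %||% "random_plus_ones",
    seed = lst$seed %||% 1
  )
}

#' Read / write a pyramid configuration as YAML
#'
#' The YAML file mirrors [pyramid_config()] field for field, with the
#' optimizer parameters nested under `ibgsa`. Unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return [read_pgsa_config()] returns a `pyramid_config`;
#'   [write_pgsa_config()] returns `path` invisibly.
#' @export
read_pgsa_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- c(
    "n_filter", "n_cycles", "ibgsa", "eval_budget", "train_fraction",
    "svm_degree", "svm_gamma", "svm_tol", "entropy_bins", "standardize",
    "swarm_init", "seed"
  )
  unknown <- setdiff(names(lst), known)
  if (length(unknown)) {
    abort(
      paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
      class = "pgsa_error_params"
    )
  }
  config_from_list(lst)
}

#' @rdname read_pgsa_config
#' @param config A `pyramid_config`.
#' @export
write_pgsa_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}
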