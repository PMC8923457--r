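#' Multi-class confusion matrix
#'
#' @param y_true,y_pred Integer labels in `1..n_classes`, equal length.
#' @param n_classes Number of classes C.
#' @return C x C integer matrix; entry `(r, c)` counts samples of true class
#'   `r` predicted as class `c`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length",
      class = "pgsa_error_dimension"
    )
  }
  if (any(y_true < 1 | y_true > n_classes | y_pred < 1 | y_pred > n_classes)) {
    abort("labels out of range 1..n_classes", class = "pgsa_error_label")
  }
  m <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true)) {
    m[y_true[i], y_pred[i]] <- m[y_true[i], y_pred[i]] + 1L
  }
  m
}

#' Per-class TPR, PPV and F1 from a confusion matrix
#'
#' One-vs-rest for each class: `TPR = TP / (TP + FN)` (row-wise recall),
#' `PPV = TP / (TP + FP)` (column-wise precision), and F1 the harmonic mean
#' `2 * PPV * TPR / (PPV + TPR)`. Overall accuracy is the trace over the
#' total. Zero denominators are defined as 0 so the metrics are total.
#'
#' @param confusion C x C matrix of non-negative counts (rows = true class).
#' @return An object of class `pgsa_metrics`: list with `confusion`,
#'   `per_class` (tibble: class, tpr, ppv, f1, n_true) and
#'   `overall_accuracy`. [tidy()] returns the per-class tibble, [glance()]
#'   the overall row.
#' @export
per_class_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion), all(confusion >= 0))
  total <- sum(confusion)
  if (total == 0) {
    abort("confusion matrix is all zero", class = "pgsa_error_empty")
  }
  tp <- diag(confusion)
  row_tot <- rowSums(confusion)
  col_tot <- colSums(confusion)
  safe_div <- function(num, den) ifelse(den > 0, num / den, 0)
  tpr <- safe_div(tp, row_tot)
  ppv <- safe_div(tp, col_tot)
  f1 <- safe_div(2 * ppv * tpr, ppv + tpr)
  structure(
    list(
      confusion = confusion,
      per_class = tibble(
        class = seq_len(nrow(confusion)),
        tpr = unname(tpr), ppv = unname(ppv), f1 = unname(f1),
        n_true = unname(as.integer(row_tot))
      ),
      overall_accuracy = sum(tp) / total
    ),
    class = "pgsa_metrics"
  )
}

#' Min, max and sample standard deviation of a metric row
#'
#' @param values Numeric vector with at least 2 entries.
#' @return A tibble with `min`, `max` and `sd` (sample standard deviation,
#'   n - 1 denominator).
#' @export
summary_stats <- function(values) {
  if (length(values) < 2) {
    abort("need at least 2 values", class = "pgsa_error_empty")
  }
  tibble(min = min(values), max = max(values), sd = sd(values))
}

# Kernel registry for the cross-validated sweep. Polynomial gammas follow
# the wrapper settings; the radial gamma uses the usual 1/D heuristic.
kernel_spec <- function(name, n_features, gamma = 1) {
  switch(name,
    linear = list(kernel = "linear"),
    quadratic = list(kernel = "polynomial", degree = 2, gamma = gamma, coef0 = 1),
    cubic = list(kernel = "polynomial", degree = 3, gamma = gamma, coef0 = 1),
    rbf = list(kernel = "radial", gamma = 1 / n_features),
    abort(paste0("unknown kernel '", name, "'"), class = "pgsa_error_params")
  )
}

# Stratified k-fold assignment keyed to sample identifiers: within each
# class, members are ordered by sample_id and fold labels are a seeded
# permutation of rep(1:k). Shuffling the row order of the input therefore
# leaves the partition of actual samples unchanged.
stratified_folds <- function(labels, sample_ids, k, seed) {
  fold <- integer(length(labels))
  local_seed(seed, {
    for (cl in seq_len(max(labels))) {
      members <- which(labels == cl)
      if (length(members) < k) {
        abort(
          paste0("class ", cl, " has fewer than k = ", k, " samples"),
          class = "pgsa_error_small_class"
        )
      }
      members <- members[order(sample_ids[members])]
      fold[members] <- sample(rep_len(seq_len(k), length(members)))
    }
  })
  fold
}

#' Cross-validated kernel sweep over a gene subset
#'
#' Evaluates a fixed gene subset by stratified k-fold cross-validation: for
#' each kernel, out-of-fold predictions are pooled into one confusion matrix
#' and the kernel with the highest pooled accuracy is returned together with
#' its per-class metrics. Deterministic given `seed`; fold assignment depends
#' only on the labels and sample identifiers, not on row order.
#'
#' @param data A samples-by-genes data frame or `expression_dataset`.
#' @param genes Character vector of gene identifiers to evaluate (e.g.
#'   `final_genes` of a [pgsa_select()] run).
#' @param kernels Kernel names among `"linear"`, `"quadratic"`, `"cubic"`,
#'   `"rbf"`. Default all four.
#' @param k Number of folds. Default 5.
#' @param seed Integer seed for the fold assignment. Default 1.
#' @param gamma Gamma of the polynomial kernels. Default 1.
#' @param tolerance SVM solver tolerance. Default 0.001.
#' @param standardize Standardize genes per fold (train statistics).
#'   Default `TRUE`.
#' @inheritParams as_expression_dataset
#' @return An object of class `pgsa_cv`: list with `best_kernel`, `metrics`
#'   (a `pgsa_metrics` for the best kernel), `kernel_accuracy` (tibble:
#'   kernel, accuracy), `genes`, `k`, `seed`.
#' @export
crossval_evaluate <- function(data, genes, kernels = c(
                                "linear", "quadratic", "cubic", "rbf"
                              ), k = 5, seed = 1, gamma = 1,
                              tolerance = 0.001, standardize = TRUE,
                              label_col = "class") {
  ds <- as_expression_dataset(data, label_col = label_col)
  stopifnot(k >= 2)
  sel <- match(genes, ds$gene_ids)
  if (anyNA(sel)) {
    abort(
      paste0(
        "unknown gene id(s): ",
        paste(head(genes[is.na(sel)], 5), collapse = ", ")
      ),
      class = "pgsa_error_label"
    )
  }
  x <- ds$matrix[, sel, drop = FALSE]
  y <- ds$labels
  fold <- stratified_folds(y, ds$sample_ids, k, seed)

  conf_by_kernel <- lapply(kernels, function(kn) {
    spec <- kernel_spec(kn, n_features = ncol(x), gamma = gamma)
    pred <- integer(length(y))
    for (f in seq_len(k)) {
      te <- which(fold == f)
      tr <- which(fold != f)
      pred[te] <- fit_predict_svm(
        x[tr, , drop = FALSE], y[tr], x[te, , drop = FALSE],
        kernel_spec = spec, tolerance = tolerance, standardize = standardize
      )
    }
    confusion_matrix(y, pred, n_classes(ds))
  })
  acc <- vapply(
    conf_by_kernel, function(m) sum(diag(m)) / sum(m), numeric(1)
  )
  best <- which.max(acc) # ties: first kernel in the given order
  structure(
    list(
      best_kernel = kernels[best],
      metrics = per_class_metrics(conf_by_kernel[[best]]),
      kernel_accuracy = tibble(kernel = kernels, accuracy = acc),
      genes = genes,
      k = as.integer(k),
      seed = as.integer(seed)
    ),
    class = "pgsa_cv"
  )
}

#' @rdname crossval_evaluate
#' @param result A `pgsa_result`; convenience wrapper that evaluates its
#'   final gene subset.
#' @param ... Passed on to [crossval_evaluate()].
#' @export
pgsa_evaluate <- function(data, result, ...) {
  crossval_evaluate(data, result$final_genes, ...)
}

#' @export
print.pgsa_metrics <- function(x, ...) {
  cat("<pgsa_metrics> overall accuracy ",
    sprintf("%.3f", x$overall_accuracy), "\n",
    sep = ""
  )
  print(x$per_class)
  invisible(x)
}

#' @export
print.pgsa_cv <- function(x, ...) {
  cat(
    "<pgsa_cv> ", x$k, "-fold CV over ", length(x$genes),
    " genes; best kernel: ", x$best_kernel, " (accuracy ",
    sprintf("%.3f", x$metrics$overall_accuracy), ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.pgsa_metrics <- function(x, ...) x$per_class

#' @export
glance.pgsa_metrics <- function(x, ...) {
  tibble(
    accuracy = x$overall_accuracy,
    n_classes = nrow(x$confusion),
    n_samples = sum(x$confusion)
  )
}

#' @export
tidy.pgsa_cv <- function(x, ...) tidy(x$metrics)

#' @export
glance.pgsa_cv <- function(x, ...) {
  dplyr::bind_cols(
    tibble(best_kernel = x$best_kernel),
    glance(x$metrics),
    tibble(n_genes = length(x$genes), k = x$k, seed = x$seed)
  )
}

#' Plot a confusion matrix as a tile heatmap
#'
#' @param object A `pgsa_metrics` or `pgsa_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgsa_metrics <- function(object, ...) {
  m <- object$confusion
  df <- tidyr::expand_grid(
    true = seq_len(nrow(m)), predicted = seq_len(ncol(m))
  )
  df$count <- as.vector(t(m))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$predicted, y = .data$true, fill = .data$count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(m))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(m))) +
    ggplot2::labs(
      x = "predicted class", y = "true class",
      title = sprintf(
        "Confusion matrix (accuracy %.3f)", object$overall_accuracy
      )
    )
}

#' @export
autoplot.pgsa_cv <- function(object, ...) autoplot(object$metrics, ...)

#' Plain-text report of a cross-validated evaluation
#'
#' Formats the per-class TPR/PPV/F1 of a `pgsa_cv` as a fixed-width table
#' (classes as columns), with the pooled accuracy and best kernel on top.
#'
#' @param cv A `pgsa_cv`.
#' @return The report as a character vector of lines, invisibly printed.
#' @export
format_metrics_table <- function(cv) {
  pc <- cv$metrics$per_class
  fmt_row <- function(name, vals) {
    paste0(formatC(name, width = 6, flag = "-"), paste(
      formatC(sprintf("%.2f", vals), width = 8),
      collapse = ""
    ))
  }
  lines <- c(
    sprintf(
      "Overall accuracy: %.3f (best kernel: %s, %d genes)",
      cv$metrics$overall_accuracy, cv$best_kernel, length(cv$genes)
    ),
    paste0(
      formatC("", width = 6),
      paste(formatC(paste0("C", pc$class), width = 8), collapse = "")
    ),
    fmt_row("TPR", pc$tpr),
    fmt_row("PPV", pc$ppv),
    fmt_row("F1", pc$f1)
  )
  lines
}
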