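#' Stratified train/test split for the selection phase
#'
#' Draws one stratified split of the samples: within each class,
#' `round(train_fraction * n_c)` samples (clamped so both sides keep at least
#' one member) go to training, the rest to test. Deterministic given `seed`.
#'
#' @param data A samples-by-genes data frame or `expression_dataset`.
#' @param train_fraction Fraction of each class assigned to training, in
#'   (0, 1). Default 0.7.
#' @param seed Integer seed controlling the draw.
#' @inheritParams as_expression_dataset
#' @return A list of class `split_spec`: integer `train_indices`,
#'   `test_indices`, plus the fraction and seed used.
#' @export
make_split <- function(data, train_fraction = 0.7, seed = 1,
                       label_col = "class") {
  ds <- as_expression_dataset(data, label_col = label_col)
  stopifnot(train_fraction > 0, train_fraction < 1)
  labels <- ds$labels
  counts <- tabulate(labels)
  if (any(counts < 2)) {
    abort("every class needs >= 2 samples to appear on both sides",
      class = "pgsa_error_small_class"
    )
  }
  train <- integer(0)
  local_seed(seed, {
    for (cl in seq_along(counts)) {
      members <- which(labels == cl)
      n_train <- round(train_fraction * length(members))
      n_train <- min(max(n_train, 1L), length(members) - 1L)
      train <- c(train, sort(sample(members, n_train)))
    }
  })
  train <- sort(train)
  structure(
    list(
      train_indices = train,
      test_indices = setdiff(seq_along(labels), train),
      train_fraction = train_fraction,
      seed = as.integer(seed)
    ),
    class = "split_spec"
  )
}

# Standardize columns by train-set mean/sd; constant-on-train genes map to 0
# on both sides so they can never influence the kernel.
standardize_by_train <- function(x_train, x_test) {
  mu <- colMeans(x_train)
  sigma <- apply(x_train, 2, sd)
  keep <- sigma > 0
  scale_mat <- function(x) {
    x <- sweep(x, 2, mu, "-")
    x[, keep] <- sweep(x[, keep, drop = FALSE], 2, sigma[keep], "/")
    x[, !keep] <- 0
    x
  }
  list(train = scale_mat(x_train), test = scale_mat(x_test))
}

# One SVM fit + prediction on pre-extracted matrices. Kernel spec is a list
# with fields kernel / degree / gamma / coef0 as e1071 expects.
fit_predict_svm <- function(x_train, y_train, x_test, kernel_spec,
                            tolerance = 0.001, standardize = TRUE) {
  if (standardize) {
    std <- standardize_by_train(x_train, x_test)
    x_train <- std$train
    x_test <- std$test
  }
  fit <- e1071::svm(
    x = x_train, y = factor(y_train),
    kernel = kernel_spec$kernel,
    degree = kernel_spec$degree %||% 3,
    gamma = kernel_spec$gamma %||% 1,
    coef0 = kernel_spec$coef0 %||% 1,
    tolerance = tolerance, scale = FALSE
  )
  as.integer(as.character(predict(fit, x_test)))
}

#' Wrapper fitness: held-out SVM accuracy of a gene subset
#'
#' Trains a polynomial-kernel support vector machine (one-vs-one for
#' multi-class) on the training side of `split`, restricted to the genes
#' where `gene_mask` is 1, and returns the accuracy on the test side.
#' Features are standardized by train-set mean/sd (constant genes map to 0)
#' unless `standardize = FALSE`. An all-zero mask denotes an empty model and
#' returns fitness 0 without training.
#'
#' @param data A samples-by-genes data frame or `expression_dataset`.
#' @param split A `split_spec` from [make_split()].
#' @param gene_mask 0/1 vector, one entry per gene.
#' @param degree,gamma Polynomial kernel degree and gamma. Defaults 3 and 1.
#' @param tolerance Termination tolerance of the SVM solver. Default 0.001.
#' @param standardize Standardize genes by train statistics. Default `TRUE`.
#' @inheritParams as_expression_dataset
#' @return Test-set accuracy in `[0, 1]`.
#' @export
svm_fitness <- function(data, split, gene_mask, degree = 3, gamma = 1,
                        tolerance = 0.001, standardize = TRUE,
                        label_col = "class") {
  ds <- as_expression_dataset(data, label_col = label_col)
  if (length(gene_mask) != ncol(ds$matrix)) {
    abort("gene_mask length must equal the gene count",
      class = "pgsa_error_dimension"
    )
  }
  sel <- which(gene_mask == 1)
  if (length(sel) == 0) {
    return(0)
  }
  tr <- split$train_indices
  te <- split$test_indices
  pred <- fit_predict_svm(
    ds$matrix[tr, sel, drop = FALSE], ds$labels[tr],
    ds$matrix[te, sel, drop = FALSE],
    kernel_spec = list(kernel = "polynomial", degree = degree, gamma = gamma,
                       coef0 = 1),
    tolerance = tolerance, standardize = standardize
  )
  mean(pred == ds$labels[te])
}

#' Compare two candidate gene subsets
#'
#' Implements the dual objective of the search: higher accuracy wins; on an
#' exact accuracy tie the smaller gene set wins; on a full tie the first
#' argument is retained.
#'
#' @param acc_a,acc_b Wrapper accuracies.
#' @param n_genes_a,n_genes_b Subset sizes.
#' @return `1L` if the first candidate is kept, `2L` if the second wins.
#' @export
compare_agents <- function(acc_a, n_genes_a, acc_b, n_genes_b) {
  if (acc_b > acc_a) {
    return(2L)
  }
  if (acc_b == acc_a && n_genes_b < n_genes_a) {
    return(2L)
  }
  1L
}
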