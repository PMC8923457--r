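#' Simulate a multi-class expression matrix with planted informative genes
#'
#' Emulates the shape of multi-class transcriptomic data: many Gaussian
#' noise genes, balanced classes, and a small set of informative genes whose
#' class means are shifted. Every gene starts as `Normal(0, noise_sd)`
#' independent of class; each informative gene then receives a distinct
#' per-class mean shift, a per-gene random permutation of
#' `{0, effect_size, 2 * effect_size, ...}` (in `noise_sd` units when
#' `noise_sd = 1`). With `effect_size = 0` no gene carries class signal.
#' Deterministic given `seed`.
#'
#' @param n_samples_per_class Samples per class. Default 30.
#' @param n_classes Number of balanced classes (>= 2). Default 3.
#' @param n_genes Total genes. Default 100.
#' @param n_informative Number of planted informative genes
#'   (`<= n_genes`). Default 5.
#' @param effect_size Class-mean shift step, in standard-deviation units
#'   (>= 0). Default 2.
#' @param noise_sd Standard deviation of the expression noise. Default 1.
#' @param seed Integer seed. Default 1.
#' @return A list of class `pgsa_sim`: `data` (tibble with `sample_id`,
#'   `class`, and one numeric column per gene), `informative` (character ids
#'   of the planted genes), and `params` (the generator settings).
#' @examples
#' sim <- simulate_expression(n_samples_per_class = 5, n_genes = 20, seed = 7)
#' sim$informative
#' @export
simulate_expression <- function(n_samples_per_class = 30, n_classes = 3,
                                n_genes = 100, n_informative = 5,
                                effect_size = 2, noise_sd = 1, seed = 1) {
  stopifnot(
    n_informative <= n_genes, n_informative >= 0, n_classes >= 2,
    effect_size >= 0, noise_sd > 0, n_samples_per_class >= 2
  )
  n <- n_samples_per_class * n_classes
  labels <- rep(seq_len(n_classes), each = n_samples_per_class)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  local_seed(seed, {
    mat <- matrix(rnorm(n * n_genes, sd = noise_sd), nrow = n, ncol = n_genes)
    informative <- sort(sample(n_genes, n_informative))
    shifts <- effect_size * (seq_len(n_classes) - 1)
    for (g in informative) {
      per_class <- sample(shifts) # distinct shift per class, permuted per gene
      mat[, g] <- mat[, g] + per_class[labels]
    }
  })
  colnames(mat) <- NULL
  data <- dplyr::bind_cols(
    tibble(
      sample_id = sprintf("s%03d", seq_len(n)),
      class = labels
    ),
    setNames(as_tibble(as.data.frame(mat), .name_repair = "minimal"), gene_ids)
  )
  structure(
    list(
      data = data,
      informative = gene_ids[informative],
      params = list(
        n_samples_per_class = n_samples_per_class, n_classes = n_classes,
        n_genes = n_genes, n_informative = n_informative,
        effect_size = effect_size, noise_sd = noise_sd, seed = seed
      )
    ),
    class = "pgsa_sim"
  )
}

#' @export
print.pgsa_sim <- function(x, ...) {
  p <- x$params
  cat(
    "<pgsa_sim> ", p$n_samples_per_class * p$n_classes, " samples x ",
    p$n_genes, " genes, ", p$n_classes, " classes, ",
    p$n_informative, " informative (effect ", p$effect_size, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Recall and precision of a selected gene set against planted truth
#'
#' @param selected Character (or integer) vector of selected genes.
#' @param truth Non-empty vector of truly informative genes, same universe.
#' @return A tibble with `recall` (`|selected n truth| / |truth|`),
#'   `precision` (`|selected n truth| / |selected|`; 0 when `selected` is
#'   empty), `n_selected` and `n_truth`.
#' @export
recovery_score <- function(selected, truth) {
  if (length(truth) == 0) {
    abort("truth set is empty", class = "pgsa_error_empty")
  }
  hits <- length(intersect(selected, truth))
  tibble(
    recall = hits / length(truth),
    precision = if (length(selected) == 0) 0 else hits / length(selected),
    n_selected = length(selected),
    n_truth = length(truth)
  )
}
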