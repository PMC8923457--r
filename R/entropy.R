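#' Shannon entropy of one gene's expression values
#'
#' Discretizes the values into `n_bins` equal-width bins spanning the
#' observed min-max range and returns the Shannon entropy (base 2) of the bin
#' occupancies: `-sum(q_b * log2(q_b))` over non-empty bins. A constant gene
#' (min equals max) carries no discriminative signal and is assigned entropy
#' 0. The result lies in `[0, log2(n_bins)]`.
#'
#' @param values Numeric vector: one gene measured across samples.
#' @param n_bins Number of equal-width histogram bins (>= 2). Default 10.
#' @return Entropy in bits.
#' @examples
#' gene_entropy(c(0, 0, 0, 1), n_bins = 2) # entropy of (3/4, 1/4)
#' @export
gene_entropy <- function(values, n_bins = 10) {
  if (length(values) == 0) {
    abort("empty value vector", class = "pgsa_error_empty")
  }
  stopifnot(n_bins >= 2)
  lo <- min(values)
  hi <- max(values)
  if (hi == lo) {
    return(0)
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1)
  bins <- .bincode(values, breaks = breaks, include.lowest = TRUE)
  q <- tabulate(bins, nbins = n_bins) / length(values)
  q <- q[q > 0]
  -sum(q * log2(q))
}

#' Rank genes by entropy
#'
#' Computes the marginal Shannon entropy of every gene and ranks genes by
#' descending entropy. Ties are broken by original gene position (ascending)
#' so the ranking is deterministic.
#'
#' @param data A samples-by-genes data frame (see [as_expression_dataset()])
#'   or an `expression_dataset`.
#' @param n_bins Histogram bins per gene. Default 10.
#' @inheritParams as_expression_dataset
#' @return A tibble of class `pgsa_ranking` with columns `gene_id`, `entropy`
#'   (bits) and `rank` (1 = highest entropy), in original gene order. The
#'   number of bins is carried in attribute `n_bins`.
#' @export
entropy_rank <- function(data, n_bins = 10, label_col = "class") {
  ds <- as_expression_dataset(data, label_col = label_col)
  ent <- apply(ds$matrix, 2, gene_entropy, n_bins = n_bins)
  ord <- order(-ent, seq_along(ent))
  rank <- integer(length(ent))
  rank[ord] <- seq_along(ent)
  out <- tibble(gene_id = ds$gene_ids, entropy = unname(ent), rank = rank)
  class(out) <- c("pgsa_ranking", class(out))
  attr(out, "n_bins") <- n_bins
  out
}

# Phase-1 filter: keep the n_filter genes of highest entropy, preserving
# original column order within the selection. Returns list(ranking, dataset,
# gene_idx) where gene_idx indexes the original columns.
filter_by_entropy <- function(dataset, n_filter, n_bins = 10) {
  if (n_filter < 1 || n_filter > length(dataset$gene_ids)) {
    abort(
      paste0(
        "n_filter (", n_filter, ") must be between 1 and the gene count (",
        length(dataset$gene_ids), ")"
      ),
      class = "pgsa_error_n_filter"
    )
  }
  ranking <- entropy_rank(dataset, n_bins = n_bins)
  keep <- sort(which(ranking$rank <= n_filter))
  list(
    ranking = ranking,
    dataset = subset_genes(dataset, keep),
    gene_idx = keep
  )
}

#' @export
autoplot.pgsa_ranking <- function(object, n_filter = NULL, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$rank)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$entropy)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "gene rank (by descending entropy)", y = "entropy (bits)",
      title = "Entropy ranking of genes"
    )
  if (!is.null(n_filter)) {
    p <- p + ggplot2::geom_vline(xintercept = n_filter, linetype = "dashed")
  }
  p
}
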