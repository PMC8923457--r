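#' Configuration of a pyramid gene-selection run
#'
#' Bundles every tunable of the pipeline: entropy filter size and bins, cycle
#' count, optimizer parameters, evaluation budget, selection split, and SVM
#' wrapper settings. Defaults follow the reference protocol: 8 cycles and a
#' total budget of 480 wrapper evaluations, split evenly (20 agents times 3
#' evaluation rounds per cycle), with a degree-3 polynomial kernel
#' (gamma 1, tolerance 0.001) scored on a stratified 70/30 split.
#'
#' @param n_filter Pool size after the entropy filter; capped at the gene
#'   count of the data. Default 500.
#' @param n_cycles Number of pyramid cycles. Default 8.
#' @param ibgsa An [ibgsa_params()] object.
#' @param eval_budget Total wrapper-fitness evaluations across all cycles.
#'   Each cycle spends `n_agents * (n_iterations + 1)`; the configuration is
#'   rejected if that exceeds the budget. Default 480.
#' @param train_fraction Training fraction of the selection split.
#'   Default 0.7.
#' @param svm_degree,svm_gamma,svm_tol Polynomial-kernel SVM settings of the
#'   wrapper. Defaults 3, 1, 0.001.
#' @param entropy_bins Histogram bins of the entropy filter. Default 10.
#' @param standardize Standardize genes (train statistics) before SVM fits.
#'   Default `TRUE`.
#' @param swarm_init `"random_plus_ones"` (each bit Bernoulli(0.5), with one
#'   agent forced to all-ones so the incumbent pool is always evaluated) or
#'   `"ones"` (every agent all-ones). Default `"random_plus_ones"`.
#' @param seed Integer seed for the whole run. Default 1.
#' @return A list of class `pyramid_config`.
#' @export
pyramid_config <- function(n_filter = 500, n_cycles = 8,
                           ibgsa = ibgsa_params(), eval_budget = 480,
                           train_fraction = 0.7, svm_degree = 3,
                           svm_gamma = 1, svm_tol = 0.001, entropy_bins = 10,
                           standardize = TRUE,
                           swarm_init = c("random_plus_ones", "ones"),
                           seed = 1) {
  swarm_init <- match.arg(swarm_init)
  stopifnot(
    n_filter >= 1, n_cycles >= 1, eval_budget >= 1,
    train_fraction > 0, train_fraction < 1,
    svm_degree >= 1, svm_gamma > 0, svm_tol > 0, entropy_bins >= 2
  )
  if (!inherits(ibgsa, "ibgsa_params")) {
    abort("`ibgsa` must be an ibgsa_params() object",
      class = "pgsa_error_params"
    )
  }
  per_cycle <- ibgsa$n_agents * (ibgsa$n_iterations + 1)
  if (per_cycle * n_cycles > eval_budget) {
    abort(
      paste0(
        "n_agents * (n_iterations + 1) * n_cycles = ", per_cycle * n_cycles,
        " exceeds eval_budget = ", eval_budget
      ),
      class = "pgsa_error_budget"
    )
  }
  structure(
    list(
      n_filter = as.integer(n_filter), n_cycles = as.integer(n_cycles),
      ibgsa = ibgsa, eval_budget = as.integer(eval_budget),
      train_fraction = as.numeric(train_fraction),
      svm_degree = as.numeric(svm_degree),
      svm_gamma = as.numeric(svm_gamma), svm_tol = as.numeric(svm_tol),
      entropy_bins = as.integer(entropy_bins),
      standardize = isTRUE(standardize),
      swarm_init = swarm_init, seed = as.integer(seed)
    ),
    class = "pyramid_config"
  )
}

#' Shrink a gene pool to the genes a mask selects
#'
#' @param pool Vector of gene identifiers (or indices).
#' @param best_mask 0/1 vector of the same length.
#' @return The entries of `pool` where `best_mask` is 1, order preserved
#'   (possibly empty; the pyramid orchestrator handles that case).
#' @export
reduce_gene_pool <- function(pool, best_mask) {
  if (length(pool) != length(best_mask)) {
    abort("mask length must equal pool length",
      class = "pgsa_error_dimension"
    )
  }
  pool[best_mask == 1]
}

#' Pyramid gene selection
#'
#' Runs the full pipeline on a labeled expression table: (1) rank genes by
#' Shannon entropy and keep the top `n_filter`; (2) for each of `n_cycles`,
#' initialize a fresh binary gravitational-search swarm over the current
#' pool, maximize held-out SVM accuracy, and shrink the pool to the genes of
#' the cycle's best agent (accuracy first, fewer genes on ties). Pool sizes
#' are non-increasing across cycles; a cycle whose best agent selects zero
#' genes keeps the previous pool and is flagged in the trace. One stratified
#' selection split is drawn per run and reused by every cycle so the fitness
#' landscape stays stationary.
#'
#' The whole run is deterministic given `config$seed`.
#'
#' @param data A samples-by-genes data frame (label column plus numeric gene
#'   columns) or an `expression_dataset`.
#' @param config A [pyramid_config()].
#' @param verbose Print one progress line per cycle. Default `FALSE`.
#' @inheritParams as_expression_dataset
#' @return An object of class `pgsa_result`: a list with `final_genes`
#'   (character), `final_accuracy`, `cycle_trace` (tibble: cycle, pool sizes
#'   before/after, best accuracy, selected genes as a list-column, empty-mask
#'   flag), `ranking` (the entropy ranking), `filtered_genes`,
#'   `n_evaluations`, `split`, and `config`. Use [tidy()] for the per-cycle
#'   trace, [glance()] for a one-row summary, [autoplot()] to plot the
#'   pyramid.
#' @examples
#' sim <- simulate_expression(n_samples_per_class = 10, n_classes = 2,
#'   n_genes = 12, n_informative = 2, seed = 1)
#' cfg <- pyramid_config(n_filter = 12, n_cycles = 2,
#'   ibgsa = ibgsa_params(n_agents = 5, n_iterations = 1),
#'   eval_budget = 20, seed = 1)
#' res <- pgsa_select(sim$data, cfg)
#' glance(res)
#' @export
pgsa_select <- function(data, config = pyramid_config(), verbose = FALSE,
                        label_col = "class") {
  ds <- as_expression_dataset(data, label_col = label_col)
  run_pgsa(ds, config, verbose = verbose)
}

#' @rdname pgsa_select
#' @param dataset An `expression_dataset` (engine-level interface;
#'   [pgsa_select()] is the data-frame front end).
#' @export
run_pgsa <- function(dataset, config = pyramid_config(), verbose = FALSE) {
  dataset <- validate_dataset(dataset)
  n_filter <- min(config$n_filter, length(dataset$gene_ids))
  filtered <- filter_by_entropy(dataset, n_filter, config$entropy_bins)
  pool_ds <- filtered$dataset

  local_seed(config$seed, {
    split <- make_split_labels(pool_ds$labels, config$train_fraction)
    pool_idx <- seq_along(pool_ds$gene_ids) # indices into the filtered pool
    n_evals <- 0L
    best_acc <- NA_real_
    trace <- vector("list", config$n_cycles)

    for (cycle in seq_len(config$n_cycles)) {
      d <- length(pool_idx)
      cycle_ds <- subset_genes(pool_ds, pool_idx)
      fitness_fn <- function(bits) {
        svm_fitness(
          cycle_ds, split, bits,
          degree = config$svm_degree, gamma = config$svm_gamma,
          tolerance = config$svm_tol, standardize = config$standardize
        )
      }
      init <- init_swarm(config$ibgsa$n_agents, d, config$swarm_init)
      # Best tracking inside a cycle is by strict fitness improvement only:
      # the all-ones incumbent is evaluated first, so the pool shrinks only
      # when a strictly better subset is found. Cycle accuracy is therefore
      # non-decreasing, and the accuracy-then-fewer-genes comparison of
      # compare_agents() always resolves to the last cycle; the same
      # comparator ranks independent runs (CLI --runs).
      res <- ibgsa_search(
        fitness_fn, d,
        params = config$ibgsa,
        initial_positions = init
      )
      n_evals <- n_evals + res$n_evaluations

      empty_best <- sum(res$best_position) == 0
      new_pool <- if (empty_best) {
        pool_idx
      } else {
        reduce_gene_pool(pool_idx, res$best_position)
      }
      trace[[cycle]] <- tibble(
        cycle = cycle,
        pool_size_in = d,
        pool_size = length(new_pool),
        best_accuracy = res$best_fitness,
        genes = list(pool_ds$gene_ids[new_pool]),
        empty_mask = empty_best
      )
      if (verbose) {
        message(sprintf(
          "cycle %d: pool %d -> %d, best accuracy %.3f",
          cycle, d, length(new_pool), res$best_fitness
        ))
      }
      pool_idx <- new_pool
      best_acc <- res$best_fitness
    }
  })

  structure(
    list(
      final_genes = pool_ds$gene_ids[pool_idx],
      final_accuracy = best_acc,
      cycle_trace = dplyr::bind_rows(trace),
      ranking = filtered$ranking,
      filtered_genes = pool_ds$gene_ids,
      n_evaluations = n_evals,
      split = split,
      config = config
    ),
    class = "pgsa_result"
  )
}

# Split on a label vector using the current RNG stream (run_pgsa seeds it
# once for the whole run).
make_split_labels <- function(labels, train_fraction) {
  counts <- tabulate(labels)
  train <- integer(0)
  for (cl in seq_along(counts)) {
    members <- which(labels == cl)
    n_train <- round(train_fraction * length(members))
    n_train <- min(max(n_train, 1L), length(members) - 1L)
    train <- c(train, sample(members, n_train))
  }
  train <- sort(train)
  structure(
    list(
      train_indices = train,
      test_indices = setdiff(seq_along(labels), train),
      train_fraction = train_fraction,
      seed = NA_integer_
    ),
    class = "split_spec"
  )
}

init_swarm <- function(n_agents, dimension, swarm_init) {
  if (swarm_init == "ones") {
    return(matrix(1, n_agents, dimension))
  }
  pos <- matrix(rbinom(n_agents * dimension, 1, 0.5),
    nrow = n_agents, ncol = dimension
  )
  pos[1, ] <- 1 # incumbent pool is always evaluated
  pos
}

#' @export
print.pgsa_result <- function(x, ...) {
  cat(
    "<pgsa_result> ", length(x$final_genes), " genes selected from ",
    length(x$filtered_genes), " (entropy-filtered), wrapper accuracy ",
    sprintf("%.3f", x$final_accuracy), "\n",
    sep = ""
  )
  cat("cycles:", paste(x$cycle_trace$pool_size, collapse = " -> "), "\n")
  invisible(x)
}

#' Tidy the per-cycle trace of a pyramid run
#'
#' @param x A `pgsa_result`.
#' @param ... Unused.
#' @return A tibble with one row per cycle: `cycle`, `pool_size_in`,
#'   `pool_size`, `best_accuracy`, `n_selected`, `empty_mask`.
#' @export
tidy.pgsa_result <- function(x, ...) {
  dplyr::mutate(
    dplyr::select(
      x$cycle_trace, "cycle", "pool_size_in", "pool_size",
      "best_accuracy", "empty_mask"
    ),
    n_selected = x$cycle_trace$pool_size,
    .after = "pool_size"
  )
}

#' One-row summary of a pyramid run
#'
#' @param x A `pgsa_result`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `accuracy`, `n_cycles`, `n_filtered`,
#'   `n_evaluations`, `seed`.
#' @export
glance.pgsa_result <- function(x, ...) {
  tibble(
    n_genes = length(x$final_genes),
    accuracy = x$final_accuracy,
    n_cycles = x$config$n_cycles,
    n_filtered = length(x$filtered_genes),
    n_evaluations = x$n_evaluations,
    seed = x$config$seed
  )
}

#' Plot the pyramid: pool size and wrapper accuracy per cycle
#'
#' @param object A `pgsa_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pgsa_result <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    dplyr::select(df, "cycle", "pool_size", "best_accuracy"),
    -"cycle",
    names_to = "metric", values_to = "value"
  )
  labeller <- ggplot2::as_labeller(c(
    pool_size = "genes in pool", best_accuracy = "best wrapper accuracy"
  ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric),
      scales = "free_y", ncol = 1, labeller = labeller
    ) +
    ggplot2::labs(
      x = "cycle", y = NULL,
      title = "Pyramid gene selection trajectory"
    )
}
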