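# Small programmatic fixtures shared across test files.

# A tiny labeled expression tibble: n_per_class samples per class, one
# strongly separating gene per class boundary plus pure-noise genes.
tiny_dataset <- function(n_per_class = 10, n_classes = 2, n_noise = 3,
                         separation = 6, seed = 42) {
  sim <- simulate_expression(
    n_samples_per_class = n_per_class, n_classes = n_classes,
    n_genes = n_noise + 2, n_informative = 2,
    effect_size = separation, noise_sd = 1, seed = seed
  )
  sim
}

# Independent entropy oracle: same equal-width binning contract, written
# with a different code path (explicit loop over bins).
oracle_entropy <- function(x, n_bins) {
  lo <- min(x)
  hi <- max(x)
  if (lo == hi) {
    return(0)
  }
  width <- (hi - lo) / n_bins
  counts <- numeric(n_bins)
  for (v in x) {
    b <- min(n_bins, max(1, ceiling((v - lo) / width)))
    if (v == lo) b <- 1
    counts[b] <- counts[b] + 1
  }
  q <- counts[counts > 0] / length(x)
  -sum(q * log2(q))
}

# Independent mass oracle: literal transcription of the mass formula.
oracle_masses <- function(fit) {
  worst <- min(fit)
  num <- fit - worst
  den <- sum(fit - worst)
  if (den == 0) rep(1 / length(fit), length(fit)) else num / den
}

# Independent per-class metric oracle via explicit one-vs-rest counts.
oracle_metrics <- function(conf) {
  C <- nrow(conf)
  out <- matrix(0, C, 3, dimnames = list(NULL, c("tpr", "ppv", "f1")))
  for (cl in seq_len(C)) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, -cl])
    fp <- sum(conf[-cl, cl])
    tpr <- if (tp + fn > 0) tp / (tp + fn) else 0
    ppv <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (tpr + ppv > 0) 2 * tpr * ppv / (tpr + ppv) else 0
    out[cl, ] <- c(tpr, ppv, f1)
  }
  out
}

# Per-class TPR/PPV/F1 rows of the published five-fold benchmark (six
# breast-cancer subtypes; four selection algorithms).
published_benchmark <- function() {
  list(
    GA = list(
      tpr = c(1.00, 0.85, 0.63, 0.63, 0.79, 0.59),
      ppv = c(0.81, 0.65, 0.73, 0.68, 0.80, 0.65),
      f1 = c(0.90, 0.73, 0.67, 0.65, 0.80, 0.62)
    ),
    PSO = list(
      tpr = c(1.00, 0.62, 0.64, 0.57, 0.80, 0.59),
      ppv = c(0.65, 0.62, 0.78, 0.57, 0.90, 0.57),
      f1 = c(0.79, 0.62, 0.70, 0.57, 0.85, 0.58)
    ),
    ICA = list(
      tpr = c(0.94, 0.79, 0.77, 0.76, 0.82, 0.72),
      ppv = c(0.81, 0.76, 0.83, 0.72, 0.80, 0.82),
      f1 = c(0.87, 0.78, 0.80, 0.74, 0.81, 0.77)
    ),
    PGSA = list(
      tpr = c(0.94, 0.87, 0.81, 0.77, 0.94, 0.80),
      ppv = c(0.84, 0.79, 0.85, 0.90, 0.80, 0.88),
      f1 = c(0.89, 0.83, 0.83, 0.83, 0.87, 0.83)
    )
  )
}

# Fast pyramid configuration for structural tests.
fast_config <- function(seed = 1, n_cycles = 3, n_agents = 8,
                        n_iterations = 1, ...) {
  pyramid_config(
    n_cycles = n_cycles,
    ibgsa = ibgsa_params(n_agents = n_agents, n_iterations = n_iterations),
    eval_budget = n_agents * (n_iterations + 1) * n_cycles,
    seed = seed,
    ...
  )
}
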