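# pgsa: pyramid gravitational search for gene selection

High-dimensional expression studies routinely measure tens of thousands of
genes on a few hundred samples, yet only a handful of genes carry the signal
that separates disease subtypes. `pgsa` implements a hybrid filter/wrapper
selector for this setting, aimed at analysts who need a small,
classification-ready gene panel from a labeled samples-by-genes matrix
(bulk or single-cell, multi-class).

## The method

Selection runs in two stages:

1. **Entropy filter.** Each gene is scored by the Shannon entropy of its
   expression distribution, *H(g) = −Σ_b q_b log₂ q_b*, over an equal-width
   histogram of its observed range; the *n* highest-entropy genes form the
   initial pool.
2. **Pyramid of binary gravitational searches.** For each of *c* cycles, a
   population of binary "agents" (bit masks over the current pool) is
   evolved by an improved binary gravitational search algorithm (IBGSA).
   Agent *i* gets a mass from its fitness,
   *Mᵢ = (fitᵢ − worst) / Σⱼ(fitⱼ − worst)*, is pulled toward the *K*
   heaviest agents with force
   *Fᵢᵈ = Σⱼ randⱼ · G(t) · MᵢMⱼ/(Rᵢⱼᵖ + ε) · (xⱼᵈ − xᵢᵈ)*, and flips bits
   with probability *Tfn = A + (1 − A)·tanh|v|*, where
   *A = k₁(1 − e^(−Fc/k₂))* rises with the failure counter *Fc* whenever the
   best solution stalls. Fitness is the held-out accuracy of a
   degree-3 polynomial-kernel SVM trained on the genes the agent selects
   (stratified 70/30 split, one-vs-one multi-class). The best mask of a
   cycle becomes the (smaller) gene pool of the next cycle — the pyramid.

Defaults follow the reference protocol: 8 cycles, a total budget of 480
wrapper evaluations (20 agents × 3 evaluation rounds per cycle), k₁ = 1,
k₂ = 500, SVM degree 3 / gamma 1 / tolerance 0.001. The final panel is
evaluated by a stratified 5-fold cross-validated kernel sweep
(linear / quadratic / cubic / RBF) with per-class TPR, PPV and F1.

The package also ships a synthetic-data generator with planted informative
genes (class-shifted Gaussians among noise genes), delimited-matrix I/O, a
YAML config mirror, and a command-line front end
(`inst/cli/pgsa.R`: `select`, `evaluate`, `simulate`, `bench`).

## Worked example

```r
library(pgsa)

sim <- simulate_expression(
  n_samples_per_class = 30, n_classes = 3, n_genes = 100,
  n_informative = 5, effect_size = 2, seed = 7
)
res <- pgsa_select(sim$data, pyramid_config(seed = 7))
res
#> <pgsa_result> 6 genes selected from 100 (entropy-filtered), wrapper accuracy 1.000
#> cycles: 51 -> 28 -> 15 -> 6 -> 6 -> 6 -> 6 -> 6

cv <- pgsa_evaluate(sim$data, res)
glance(cv)
#> # A tibble: 1 × 7
#>   best_kernel accuracy n_classes n_samples n_genes     k  seed
#>   <chr>          <dbl>     <int>     <int>   <int> <int> <int>
#> 1 linear         0.978         3        90       6     5     1

recovery_score(res$final_genes, sim$informative)
#> # A tibble: 1 × 4
#>   recall precision n_selected n_truth
#>    <dbl>     <dbl>      <int>   <int>
#> 1    0.6       0.5          6       5
```

The trace reads: the entropy filter kept all 100 genes (fewer than the
default pool size), the first cycle cut the pool to 51 genes, and the
pyramid settled on a 6-gene panel whose wrapper accuracy on the selection
split is 1.0. Five-fold cross-validation of that panel over all 90 samples
reaches 97.8% accuracy (linear kernel); 3 of the 5 planted informative
genes are in the panel — redundant planted genes are dropped once accuracy
saturates. `tidy(res)` returns the per-cycle trace, `autoplot(res)` plots
pool size and accuracy per cycle, and `write_selection_result()` serializes
the run (with a config echo that reproduces it exactly).

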