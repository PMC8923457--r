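---
title: "Pyramid gravitational search for gene selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pyramid gravitational search for gene selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgsa)
```

## The problem

Multi-class expression data (disease subtypes, cell states) typically has
far more genes than samples. A classifier trained on everything overfits;
most genes are irrelevant or redundant. `pgsa` searches for a small gene
panel that preserves — usually improves — classification accuracy, by
combining a cheap univariate filter with a wrapper search that scores whole
subsets through the classifier itself.

## The procedure

### Stage 1: entropy filter

Every gene is scored by the Shannon entropy (base 2) of its expression
values over an equal-width histogram spanning its observed min–max range:
$H(g) = -\sum_b q_b \log_2 q_b$ with $q_b$ the fraction of samples in bin
$b$. Genes whose expression spreads across many levels score high; a
constant gene carries no discriminative information and is defined to have
entropy 0. The top `n_filter` genes form the search pool.

Two points deserve emphasis. First, this is *marginal* entropy: it ignores
the class labels, so it is a variability filter, not a relevance filter —
its job is to discard flat, uninformative genes cheaply, and it pairs with
the label-aware wrapper that follows. A class-conditional variant would be
a different filter with different behavior; we deliberately implement the
marginal one. Second, equal-width binning on the per-gene range makes the
score invariant to per-gene affine rescaling and to sample order; ties are
broken by original gene position so the ranking is reproducible.

`entropy_bins` defaults to 10 — coarse enough that 30–300 samples populate
the histogram meaningfully, fine enough to distinguish spread from
constancy. `n_filter` defaults to 500 (and is capped at the gene count):
large enough to retain the informative genes of a typical panel-finding
problem, small enough that a few hundred wrapper evaluations can make
progress in the reduced space.

### Stage 2: cycles of binary gravitational search

Each cycle runs an improved binary gravitational search (IBGSA) over bit
masks of the current pool:

* **Masses** (higher fitness = heavier):
  $M_i = (fit_i - worst) / \sum_j (fit_j - worst)$, $worst$ the population
  minimum. Masses sum to 1 and the worst agent gets 0. If all fitnesses tie
  the ratio is 0/0; the population is symmetric and we assign uniform
  masses $1/N$.
* **Forces**: agent $i$ is pulled toward each of the $K$ heaviest agents,
  $F_i^d = \sum_{j \in Kbest, j \ne i} rand_j\, G(t)\, M_i M_j /(R_{ij}^p +
  \varepsilon)\,(x_j^d - x_i^d)$, with $R_{ij}$ the Euclidean distance
  between the binary positions, $p = 1$ (the classic form; configurable)
  and $\varepsilon = 10^{-9}$ guarding coincident agents. $rand_j$ is drawn
  once per $(i,j)$ pair. Note the mechanism: on bits where $x_i$ already
  agrees with the elite, the difference term vanishes and the bit feels no
  pressure; disagreement bits accumulate velocity. That is what turns the
  direction-free bit-flip rule below into hill climbing toward the elite's
  consensus.
* **Kbest** shrinks linearly from $N$ to 1 over the run (half-up rounding):
  everyone attracts early (exploration), only the best attracts late
  (exploitation).
* **Acceleration** $a_i^d = F_i^d/(M_i + 10^{-12})$. The guard matters only
  for the worst agent, whose mass is exactly 0; since its force also
  carries the factor $M_i$, the quotient stays finite and well scaled.
* **Velocity** $v' = rand \cdot v + a$, clamped to $\pm v_{max}$ with
  $v_{max} = 6$, which keeps $\tanh$ in its responsive range.
* **Transfer function** $Tfn = A + (1-A)\tanh|v|$,
  $A = k_1(1 - e^{-Fc/k_2})$. Each bit is complemented with probability
  $Tfn$. $Fc$ is a global failure counter: it increments whenever the
  best-found fitness fails to *strictly* improve in an iteration (ties
  count as failures) and resets to 0 on improvement. As failures
  accumulate, $A$ raises the flip-probability floor toward $k_1$, forcing
  exploration out of stagnation. Defaults $k_1 = 1$, $k_2 = 500$. The
  transfer function uses $|v|$ so it is a probability for either velocity
  sign.
* **Gravitational constant** $G(t) = G_0\, e^{-\alpha t/T}$, $G_0 = 100$.
  We default $\alpha = 8$ rather than the $\alpha = 20$ of the continuous
  ancestor: in the binary setting the flip probability is a saturating
  function of $G$-scaled velocities, and with $\alpha = 20$ the constant is
  below $10^{-2}$ for the last two thirds of the run — the swarm freezes
  and re-evaluates identical positions, doing no better than random
  sampling at equal budget. With $\alpha = 8$ the flip probabilities anneal
  smoothly from near-random exploration to near-zero drift across the whole
  horizon, and the optimizer reliably beats a random-search baseline on the
  OneMax check the test suite runs. The decay rate is configurable.

The wrapper fitness of a mask is the test-side accuracy of a
degree-3 polynomial-kernel SVM (gamma 1, coef0 1, tolerance 0.001,
one-vs-one multi-class, via `e1071`/libsvm) trained on the training side of
one stratified 70/30 split. Genes are standardized by training-set mean and
standard deviation (applied to the test side; constant genes map to 0) —
polynomial kernels are scale-sensitive and raw expression columns can
differ by orders of magnitude. Standardization can be disabled. An all-zero
mask is an empty model and scores 0 without training.

One split is drawn per run, not per cycle, so all cycles optimize the same
stationary objective; re-splitting each cycle would add level noise between
cycles that the small per-cycle budget cannot average away.

Each cycle initializes a fresh swarm (each bit Bernoulli(0.5)) with one
agent forced to all-ones, so the incumbent pool is always evaluated, and
resets the failure counter. The cycle's best mask (strict fitness
improvement over the incumbent; ties keep the incumbent) defines the next,
never larger, pool. Should a best mask select zero genes (impossible in
practice because the all-ones incumbent scores at least as well and is
evaluated first), the previous pool is retained and the cycle flagged in
the trace. Because cycle $c{+}1$'s incumbent *is* cycle $c$'s best subset,
the best accuracy is non-decreasing across cycles and the final panel's
wrapper accuracy can never fall below the full filtered pool's accuracy.

### Budget accounting

The evaluation budget (default 480) is split evenly across cycles. A swarm
of $N$ agents run for $T$ movement iterations costs $N(T+1)$ fitness
evaluations, counting the initialization sweep. The defaults $N = 20$,
$T = 2$ give 60 evaluations per cycle and $8 \times 60 = 480$ total —
exactly the reference budget. `pyramid_config()` rejects settings whose
per-cycle cost would exceed the budget.

### Where the "fewer genes" objective lives

The method's dual objective — accuracy first, parsimony second — is *not* a
weighted fitness. Inside a cycle, only strict accuracy improvements move
the best; shrinkage happens because better subsets found by the search are,
on average, about half the pool. Between whole runs, `compare_agents()`
ranks candidates by accuracy and then by gene count (first argument wins a
full tie), which is how the command-line `--runs` loop picks the reported
model, mirroring a best-of-thirty-runs protocol. Putting the gene-count
tie-break *inside* the optimizer is available (`prefer_fewer_bits`) but off
by default: once the wrapper accuracy saturates, it collapses the panel to
a minimal perfect subset, discarding redundant but genuinely informative
genes.

### Randomness and reproducibility

All uniform draws are consumed in a documented, fixed order (forces:
agents outer, elite ascending; velocities and flips: agent-major,
dimensions inner), and every seeded entry point restores the caller's RNG
state. The same `pyramid_config(seed=)` therefore reproduces a run bit for
bit, and the config echo written by `write_selection_result()` suffices for
an exact re-run.

## Final evaluation

`crossval_evaluate()` scores a fixed panel by stratified $k$-fold
cross-validation (default $k = 5$): for each kernel (linear, quadratic,
cubic, RBF) the out-of-fold predictions are pooled into one confusion
matrix — pooled rather than per-fold-averaged, so every sample contributes
exactly once and per-class counts stay integers. The best pooled accuracy
picks the kernel (ties resolve to the earlier kernel in the list). Fold
assignment is keyed to sample identifiers (within-class ordering by id, a
seeded permutation of fold labels), so shuffling row order cannot change
the result. Per-class one-vs-rest metrics follow the standard definitions
TPR $= TP/(TP{+}FN)$, PPV $= TP/(TP{+}FP)$, F1 the harmonic mean;
zero-denominator cases are defined as 0 so the metrics are total.
`summary_stats()` reports min, max and the sample ($n{-}1$) standard
deviation; for the six-class benchmark rows the package reproduces, both
standard-deviation conventions round identically at two decimals.

## The synthetic generator

`simulate_expression()` emulates the shape of subtype-labeled expression
data: balanced classes, every gene Gaussian noise, and `n_informative`
planted genes whose per-class means are a per-gene random permutation of
$\{0, e, 2e, \dots\}$ ($e$ = `effect_size`, in noise-sd units). It is the
simplest structure that the entropy filter (shifted mixtures have wider
spread) and the SVM wrapper (linear mean separation) can provably exploit,
which is what makes it a useful correctness probe.

What it does *not* emulate: gene–gene correlation, batch effects,
heavy-tailed or count-valued noise, unbalanced classes, probe saturation.
Passing the planted-recovery tests therefore demonstrates that the
machinery finds mean-shifted signal embedded in independent noise — not
that it handles the correlation structure of real microarray or single-cell
data. Default conditions (30 samples × 3 classes, 100 genes, 5 informative,
effect 2.0) match the simulation protocol the test suite and acceptance
script use.

One behavior of accuracy-driven selection shows up clearly in this regime
and is worth knowing: with strong effects the wrapper accuracy saturates at
1.0 on the held-out split while several planted genes are still redundant,
and from that point the search cannot distinguish a panel containing three
planted genes from one containing five. Recovery of *all* planted genes is
therefore not guaranteed even when classification is perfect — parsimony
and completeness are competing objectives, and this selector is built to
favor accuracy-preserving parsimony.

## Problem sizes

The test suite runs the full pipeline only at desk scale — up to 100 genes,
90 samples, the default 480-evaluation budget (about a second per run) —
and the acceptance script uses 10 simulation seeds for recovery statistics,
20 seeds for the OneMax comparison, and 3 for the null control. These sizes
were chosen so the whole suite re-runs in well under a minute of compute
per component while keeping the stochastic comparisons stable.

## Known limitations

* The wrapper fitness uses a single 70/30 split; its 1/|test| accuracy
  resolution is coarse on small cohorts, and panels are mildly overfit to
  that split (the cross-validated kernel sweep on the full data gives the
  honest final number, and the null-control test quantifies the optimism).
* The optimizer's failure counter is global, per the method's narrative;
  per-agent counters are not implemented.
* The entropy filter is marginal, so a gene that is bimodal for reasons
  unrelated to class survives it; the wrapper must then discard it within
  its evaluation budget.
* No probe-to-gene mapping, normalization or batch correction: the input is
  assumed preprocessed.
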