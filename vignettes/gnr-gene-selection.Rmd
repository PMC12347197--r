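---
title: "Wrapper gene selection with crossover-embedded nuclear reaction optimization"
author: "gnrSelect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapper gene selection with crossover-embedded nuclear reaction optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gnrSelect)
```

## The problem

Microarray (and suitably normalized RNA-seq) studies measure thousands of
genes on a few dozen samples. Classifiers fit on the full matrix overfit;
biologically interpretable results need a *compact* panel of genes that
still separates the phenotype classes. `gnrSelect` implements a two-stage
hybrid selection strategy:

1. **Filter**: a univariate relevance score shrinks the matrix to a pool
   of the top-*k* genes (default 500).
2. **Wrapper search**: a population metaheuristic searches over fixed-size
   gene subsets inside the pool, scoring each subset by the leave-one-out
   cross-validated accuracy of a linear support vector machine (C = 1).

The search engine is a nuclear-reaction optimizer whose *fusion*
(exploitation) step is, with probability 0.3, replaced by a genetic
uniform crossover with the best-known solution. The crossover counteracts
the late-stage stagnation that plain nuclear-reaction search exhibits on
these landscapes.

## Preprocessing

The pipeline order is fixed: mean imputation, per-gene Z-score
normalization, label encoding, then filtering. Each choice has a rationale:

* **Mean imputation** replaces a missing cell with the mean of the gene's
  observed values. It is unbiased per gene and appropriate when
  missingness is spread thinly across many genes (the regime the audit in
  `maskReport()` is designed to confirm). Genes with no observed values
  are an error, not a guess.
* **Z-score normalization** maps every gene to mean 0, standard
  deviation 1, so that no gene dominates the SVM margin by scale alone.
  The default denominator is the *sample* standard deviation (n−1),
  matching common library defaults; `sdType = "population"` switches to
  the n denominator. Genes that are constant after imputation become
  all-zero columns (recorded in the preprocessing report) rather than a
  division by zero.
* **Label encoding** maps class names to codes 0..C−1 in
  byte-lexicographic order, so the encoding does not depend on file
  ordering or locale.

## The filter stage

Two statistics are available, selected by `rankGenes(..., method=)`:

* `fScore()` — the two-class variance-ratio score
  \[
  F_i=\frac{(\mu_i^+-\mu_i)^2+(\mu_i^--\mu_i)^2}
           {(s_i^+)^2+(s_i^-)^2},
  \]
  with class sample variances (n−1 denominators). When both class
  variances vanish the score is defined as $\infty$ if the class means
  differ and 0 otherwise.
* `anovaF()` — the one-way ANOVA F statistic (between-group mean square
  over within-group mean square), which generalizes to any number of
  classes.

The two statistics are *different* quantities; on balanced two-class data
they are related by a fixed monotone map and produce identical rankings
(a property the test suite asserts empirically), but on unbalanced data
they can disagree. The pipeline default is `anova`, with `fscore`
available as a documented variant; neither is silently preferred. Ties at
the top-*k* boundary are broken toward the lower original gene index, so
`selectTopK()` is deterministic and idempotent.

## The search engine

Candidates are continuous vectors in $[0,1]^D$, where $D$ is the pool
size. A candidate's gene subset is the index set of its $k$ largest
components (ties toward the lower index) — the minimal decoding rule
consistent with a fixed subset size over a continuous encoding. Each
generation applies three operators to every candidate:

* **Fission** (exploration): a Gaussian perturbation around the best or
  the current solution with dispersion
  $\sigma = \frac{\log g}{g}\,\lVert X - X_{best}\rVert$ (Euclidean norm,
  common scalar per call), plus a "heated neutron" term
  $z\,(X_{best} - P\,Nei)$, where $z$ is one standard-normal draw,
  $P \in \{1,2\}$ or $\{2,3\}$ is a discrete mutation factor, and
  $Nei$ combines two random peers. The branch is chosen with probability
  $P_\beta$.
* **Ionization**: component-wise perturbation built from two random peers,
  $X_{r1,d} \pm u_d\,(X_{r2,d}-X_{i,d})$; when the difference vector is
  numerically degenerate (norm below `stagnationEpsilon`), a Lévy flight
  $X_i + \alpha\,L(\beta)\odot(X_i - X_{best})$ is applied instead.
* **Gated fusion** (exploitation): with probability `pCrossover` a
  uniform crossover with the best solution (each component inherited from
  the best parent with probability `pInheritBest`, otherwise from a
  random peer drawn from the population excluding the best slot);
  otherwise the fusion move
  $X_i + u_1(X_{r1}-X_{best}) + u_2(X_{r2}-X_{best})$, or its Lévy-escape
  form when the run is stagnant (two or more consecutive non-improving
  generations).

Every operator output is clipped to $[0,1]^D$; the clipping contract is
enforced by tests with adversarial draw sources.

### Greedy phase acceptance

A design point that the printed recurrence equations leave open is what
happens to the population between phases. This package applies
**per-candidate greedy acceptance** after each phase: a product replaces
its parent only when its fitness is at least as good (ties accepted, to
allow neutral drift). This is the selection scheme of the
nuclear-reaction-optimizer lineage. The alternative — replacing the
population wholesale with the fused products — was measured during
development and destroys exploitation entirely: the population's mean
fitness stays at the level of random sampling because crossover offspring
are corrupted by clip-saturated components of random peers, and planted
markers are recovered in well under half of seeded runs. With greedy
acceptance the engine recovers planted markers reliably (the test suite
asserts ≥ 9/10 seeded runs on the scaled task below). Fitness values are
cached per decoded subset, so the extra evaluations are cheap once the
population concentrates.

### Stopping rules and the improvement counter

The best-known solution is updated only on *strictly* greater fitness, so
the recorded best-fitness trajectory is non-decreasing. A
generation-level counter increments whenever a generation ends without a
new best; the first recorded generation always counts as an improvement
(the baseline is an empty trajectory), so a run whose fitness never moves
executes exactly `patience + 1` generations before stopping. The run
also stops at the generation cap, and when the best fitness reaches
`targetFitness` (default 1): the LOOCV-accuracy objective is bounded
above by 1, so further search cannot improve it.

### Tunables

| parameter | default | meaning |
|---|---|---|
| `populationSize` | 500 | candidates per generation |
| `maxGenerations` | 30 | generation cap |
| `patience` | 5 | consecutive non-improving generations before stopping |
| `nRuns` | 30 | independent restarts in the experiment harness |
| `pCrossover` | 0.3 | probability fusion is replaced by crossover |
| `pInheritBest` | 0.8 | per-component inheritance from the best parent |
| `subsetSizes` | 2..25 | panel sizes swept by the harness |
| `pBeta` | 0.5 | fission branch probability (no published value; a neutral coin) |
| `levyAlpha` | 0.01 | Lévy scale (conventional) |
| `levyExponent` | 1.5 | Lévy stability exponent (conventional, Mantegna generator) |
| `stagnationEpsilon` | 1e-12 | degenerate-difference threshold |
| `neutron` | mean | peer combination; `"product"` gives the literal element-wise product |

The `neutron` default follows the optimizer literature (element-wise mean
of the two peers); the product reading of the printed formula is kept as
a switch because the source notation is ambiguous. The probabilities,
population size, generation cap, patience, run count and sweep range are
the published study conditions.

## Fitness and reporting

`loocvFitness()` is fully deterministic: n folds, one held-out sample per
fold, a linear SVM (C = 1) refit per fold, metrics pooled over held-out
predictions. Multiclass prediction is one-vs-rest on SVM decision values
(ties toward the lower class code). Precision, recall and F1 are
class-wise, combined by support-weighted average — a single number per
metric even for 3- and 4-class panels. `kfoldFitness()` provides the
stratified k-fold comparison; its fold assignment is cyclic over a
within-class shuffle, which makes `folds = n` reduce *exactly* to LOOCV.

`aggregateRuns()` summarizes independent runs as best/average/worst
accuracy with a Student-t 95% confidence interval over the per-run
accuracies. All-equal runs give a degenerate interval flagged
`"constant"` (rendered as e.g. `100% (constant)` in the report tables); a
single run reports no interval. The choice of a t interval over run
accuracies is the package's own: the benchmark table format this layout
mirrors does not name its construction.

`runExperiment()` sweeps subset sizes with `nRuns` seeded restarts each
(run r uses `masterSeed + r`, so the whole experiment is reproducible
from one integer) and by default stops the sweep at the first size whose
best accuracy reaches 1 — the "smallest perfect panel" reporting
convention.

## The synthetic generator

`simulateExpression()` produces the ground-truth datasets every stage is
tested against: background genes are $N(0,\sigma^2)$ independent of
class; a planted gene's class-c mean is $c\cdot\text{effectSize}$;
missing cells are masked completely at random, either at a Bernoulli rate
or as an exact count. Defaults (62 samples × 2000 genes, two classes, 3
planted markers at a 3-sd shift) emulate the shape of a small
tumor/normal microarray study, and the exact-count masking option
reproduces the missingness regime of a 62 × 4026 three-class panel with
12,264 missing cells used in the audit tests — that object is synthetic,
not the original benchmark.

What the generator deliberately does **not** model: correlated gene
blocks, batch effects, heavy-tailed intensity distributions,
class-dependent missingness. Passing tests on this family therefore
demonstrate that the machinery is correct and that the search recovers
planted signal under Gaussian class shifts; they do not certify
performance on real microarray marginals.

## Problem sizes used by the tests

The test suite and the acceptance script run scaled-down study
conditions chosen as the package's own verification sizes: recovery tasks
use a 62 × 1000 matrix filtered to a 200-gene pool with population 50 and
at most 20 generations over 10 seeded runs; combinatorial recovery uses
D = 50 with population 40; the operator-rate checks use $10^4$–$10^5$
draws against 99% binomial intervals. The full published conditions
(population 500, 30 generations, 30 runs, pool 500, sizes 2–25) remain
the defaults of `gnrConfig()` and are what `runExperiment()` uses unless
overridden.

## Known limitations

* The fission/fusion recurrences freely leave $[0,1]^D$ and are clipped
  back; heavy clipping saturates components at the bounds, which is one
  reason greedy acceptance matters (see above).
* One-vs-rest with a linear kernel cannot separate a class that is not
  linearly separable from the union of the others (e.g. a "middle" class
  on a single gene); this is a property of the classifier geometry, not a
  bug in the fold loop.
* LOOCV on a few dozen samples has high variance; the multi-run
  best/average/worst spread in the reports is the honest signal of that.
* The filter stage is univariate: genes informative only in combination
  can be cut before the wrapper ever sees them. Increasing `poolSize`
  trades speed for recall.
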