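---
title: "Gene selection and classification with hidimsel: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene selection and classification with hidimsel: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hidimsel)
```

# The problem

Two-class expression studies (tumour vs normal tissue, case vs control
cohorts) routinely measure tens of thousands of genes on tens of samples.
Most genes are irrelevant or redundant for separating the classes, and both
the statistics and the classifiers degrade when they are kept.  `hidimsel`
extracts a small subset of discriminative genes in three stages — a cheap
univariate curation pass, a rank-based statistical filtration, and a
classifier-driven wrapper search — and reports how well the final subset
classifies the samples.

The package accepts curated CSV matrices (samples as rows, genes as
columns, class label in the last column) and raw GEO SOFT GDS files, for
which the user must supply the two sample-class ranges since GDS files do
not encode them.

# Stage 1: curation by near-unity class ratios

For every gene the package computes a dispersion measure — the coefficient
of variation `sd(x)/|mean(x)|` over all samples — and a between-class ratio
of a location statistic.  Dispersed genes (CV at or above 0.15) are judged
by the ratio of their class-wise *medians*, because the mean is unstable
under high variance; stable genes are judged by the ratio of class-wise
*means*.  A gene whose ratio falls inside the band `[0.95, 1/0.95]`
(inclusive) shows essentially identical expression in the two classes and
is removed.

Choices worth knowing:

* The band is symmetric under ratio inversion (`r -> 1/r`), so swapping
  which class is the numerator cannot change a verdict; we report
  class1/class2.
* Dispersion is computed over *all* samples, not per class.  The
  per-class alternative would let a strong class shift push a gene into
  the median branch; computing it globally makes the criterion choice a
  property of the gene's overall variability.  It is configurable via
  `curation_config()`.
* The coefficient of variation is the only dispersion measure with a
  natural "15 percent" reading: raw variance carries squared units of
  intensity and no percent scale.
* Sign edge cases: both class statistics negative — the ratio of absolute
  values is used; opposite signs — the gene is obviously differential and
  is kept (the signed ratio is negative and can never fall in the band);
  a zero denominator with non-zero numerator yields `Inf`, also kept.
* Curation is mandatory for SOFT inputs (they are never pre-curated and
  are otherwise prohibitively large downstream) and optional for CSV; an
  explicit `force_no_curation` flag overrides the rule.

# Stage 2: k-fold filter ranking and the global weight

Two univariate filters score every gene:

* **Welch t** — `t = (c1 - c2) / sqrt(s1^2/n + s2^2/m)` with sample
  variances and Welch–Satterthwaite degrees of freedom for the two-sided
  p-value.  The unequal-variance form matches the heteroscedastic, noisy
  character of expression data.  Ranking uses `|t|`.
* **Rank-sum importance** — the pair count
  `s(g) = sum_i sum_j I(x1_j - x0_i <= 0)` over all cross-class sample
  pairs (ties count), summarised as `q(g) = max(s, N0*N1 - s)`.  `q` is
  maximal when one class stochastically dominates the other and minimal
  (`~N0*N1/2`) when the classes interleave.  It is invariant under class
  swap, which `s` alone is not.

To keep the ranking from overfitting any particular set of samples, the
filter is run in a stratified k-fold scheme (default `k = 10`): on each
fold's *training* nine-tenths the genes are scored and ranked, the rank is
converted to a positional (Borda) weight `w_i(f) = G - rank_i(f) + 1`, and
the global weight is the sum over folds, `w(f) = sum_i w_i(f)`.  Genes that
rank consistently high on every training split accumulate the largest
global weight.  Rank-based fold weights (rather than raw scores) make the
aggregation scale-free, which matters because `|t|` and `q` live on
entirely different scales; ties within a fold get average ranks, so the
procedure is order-independent.

The two filters are combined by min-max-normalising each global weight
vector to `[0, 1]` and averaging.  Averaging normalised weights (rather
than intersecting or unioning top lists) preserves information from both
filters, degrades gracefully when one filter is uninformative (a constant
weight vector normalises to a constant and leaves the other filter's
ordering untouched), and needs no extra tuning parameter.  The top `n`
genes (default 200) proceed to the wrapper.

# Stage 3: geometric binary PSO with SVM fitness

The wrapper searches the space of gene subsets (bit masks over the
filtered genes) for the subset with the best classifier performance.  The
particle swarm operates *geometrically* on the Hamming space: instead of a
velocity update, each particle's new position is a three-parent crossover —
every bit is copied from the particle's current mask, its personal best,
or the swarm's global best with probabilities `(w_self, w_pbest, w_gbest)`
(defaults 1/3 each) — followed by an independent per-bit mutation (default
rate `1/L`).  With zero mutation the offspring always lies in the parents'
Hamming convex hull, which is what makes the operator a geometric
crossover; no velocity vector exists in this formulation.

Fitness is the mean per-fold accuracy of a polynomial-kernel SVM under
stratified 10-fold cross-validation on the masked genes.  Defaults are
degree 1 and cost `C = 1` — the simplest member of the polynomial family —
and one fixed fold assignment is used for the entire swarm run so every
particle is scored on identical splits; fitness differences then reflect
the gene subsets, not fold luck.  Inside each fold the features are
standardised with the training fold's mean and standard deviation (applied
unchanged to the held-out fold).  This keeps the margin penalty `C`
meaningful across intensity scales and is the conventional preprocessing
for margin classifiers; zero-variance features are passed through
unscaled.  The empty mask scores 0 by convention.  Fitness values are
cached by mask, since converging swarms revisit positions constantly.

Equal-fitness ties are broken toward fewer selected genes, then toward
the lexicographically smaller mask — parsimony is the point of wrapper
selection, and the lexicographic step makes the whole run deterministic
under its seed.  The global-best fitness trace is non-decreasing by
construction and is exported alongside the selected genes.

Swarm size (20), iteration cap (100) and the optional stall-based early
stop are package defaults; the underlying method prescribes none of them.

# Evaluation

The final subset is assessed by (repeated) stratified 10-fold
cross-validation.  Accuracy is `(TP + TN) / (TP + TN + FP + FN)` averaged
over folds, reported as a percentage with the standard deviation of
per-fold accuracies; precision is `TP / (TP + FP)` computed from the
*pooled* confusion counts (per-fold precision is undefined whenever a fold
predicts no positives, pooling is not).  The positive class defaults to
the second listed class — by biomedical convention the disease group.
When nothing is predicted positive, precision is reported as
not-applicable rather than zero.  With one repeat and the wrapper's CV
seed, the evaluation reproduces the wrapper's fitness value exactly, which
the test suite asserts.

# The synthetic generator

`synthetic_spec()` / `make_dataset()` produce the ground-truth datasets
used throughout the tests: log-normal positive intensities
(`meanlog = log(base_mean)`, `sdlog = base_sd/base_mean`, defaults 100 and
20 — a 20 percent coefficient of variation typical of intensity-scale
arrays), identical across classes except for `n_informative` planted genes
whose class-1 values are shifted on the log scale by
`effect_size * sdlog`, plus an optional fraction of redundant genes that
are multiplicatively jittered copies of other genes.  The defaults — 1000
genes, 5 informative at effect size 3, 30 samples per class — define the
standard recovery scenario: strong, sparse signal in a moderately sized
two-class study.

What the generator does *not* emulate: probe-level physics, batch and
array effects, correlated co-expression modules, heavy-tailed outliers,
class imbalance beyond what the spec requests.  Passing recovery tests
therefore demonstrate that the machinery finds strong planted signal; they
do not certify performance on real arrays, where the reproduction datasets
(see `tests/testthat/test-acceptance.R`) are the relevant check.

`make_soft_fixture()` serialises a generated dataset as a miniature GDS
SOFT file, optionally injecting `null` cells at a chosen rate, so the SOFT
parser's drop/impute policies are testable without any download.

# Numerical and degenerate-input choices

* Welch t with both variances zero: `t = 0` for equal means, an infinite
  (flagged) score for unequal means — such a gene separates the classes
  perfectly and should rank first, not crash the run.
* Fold counts are reduced (with a warning) when the smaller class has
  fewer samples than the requested folds.
* Duplicate SOFT probe identifiers get a `#k` suffix; unparseable cells
  follow the drop (default) or gene-mean-impute policy, and every such
  action is logged.
* Label coding follows first appearance in the file, so no configuration
  is needed; a dataset whose first sample belongs to the second class
  round-trips with flipped 0/1 codes but identical class names.
* Test problem sizes: the oracle suites run on hundreds of miniature
  instances (8–100 genes, 6–30 samples) where exhaustive enumeration is
  exact; the end-to-end scenario uses the generator defaults with a
  40-iteration swarm, which the fitness traces show is well past the
  plateau on this problem size.

# Known limitations

* **Fitness plateaus hide redundant true positives.**  When the planted
  (or real) effects are strong, many small subsets already reach 100 %
  cross-validated accuracy; the fitness landscape is flat at the top, and
  the parsimony tie-break deliberately prefers the smallest such subset.
  The wrapper therefore returns *a minimal sufficient* gene set, not *all*
  truly differential genes — on the default recovery scenario it
  typically keeps 2–4 of the 5 planted genes while still classifying
  perfectly.  Users wanting exhaustive recovery should rely on the filter
  ranking (which does place all planted genes at the top) rather than the
  wrapper subset.
* The wrapper's internal CV accuracy is an optimistically biased estimate
  of generalisation error, since the subset was chosen to maximise it;
  the package reports it as the method defines it and does not perform
  nested cross-validation.
* Only two-class problems are supported; multi-class labels, paired
  designs and survival outcomes are out of scope, as are normalisation,
  batch correction and probe-to-gene collapsing, which should happen
  upstream.
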