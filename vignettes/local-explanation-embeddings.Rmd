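---
title: "Local explanation embeddings for cross-study microbiome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local explanation embeddings for cross-study microbiome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gut microbiome case-control studies routinely train random-forest
classifiers on species-level relative-abundance profiles and then ask which
taxa drive the classification. The usual answer — a global feature-importance
ranking such as the Gini-impurity decrease — averages over the whole cohort
and cannot say anything about an individual subject. Two patients can both
be classified as cases for entirely different microbial reasons, and a taxon
that is decisive for a handful of subjects can be invisible in a global
ranking.

`microshap` takes the per-sample route. For every subject it computes
Shapley (SHAP) attributions of the classifier's predicted case probability
over all taxa, and then treats the resulting samples-by-taxa attribution
matrix as a data set in its own right: it is embedded with PCA, the case
subjects are subtyped by K-means on the embedding, and each subtype is
characterized by nonparametric taxon-enrichment tests. The package covers
the whole path from raw abundance tables to subtype enrichment reports,
with a command-line front end and a seeded synthetic-cohort generator so
every stage is testable without any data download.

## The attribution model

For a fitted model $p(\cdot)$ over $n$ taxa, the Shapley value of taxon $i$
for one subject is

$$\phi_i \;=\; \sum_{S \subseteq N \setminus \{i\}}
\frac{|S|!\,(n-|S|-1)!}{n!}\,\bigl(v(S \cup \{i\}) - v(S)\bigr),$$

the coalition-weighted average of taxon $i$'s marginal contributions. The
value $v(S)$ of a coalition $S$ is *interventional*: the mean model output
over a background data set (the training matrix) in which the coordinates
in $S$ are replaced by the explained subject's values,

$$v(S) \;=\; \tfrac{1}{|B|}\sum_{z \in B} p\!\left(x_S \cup z_{\bar S}\right).$$

Consequently $v(\varnothing)$ is the expected model output over the
background (the *base value*) and $v(N)$ is the subject's own prediction, so
the attributions satisfy *local accuracy*:
$\text{base} + \sum_i \phi_i = \text{prediction}$, enforced in every test to
$10^{-8}$.

Published tree explainers offer a second, path-dependent expectation that
weights tree branches by training cover counts. We deliberately implement
only the interventional form: it has an unambiguous brute-force definition
(enumerate all $2^n$ coalitions), which makes correctness *testable* — the
fast engine is checked against full enumeration on hundreds of fuzzed
ensembles, and the enumeration itself is checked against an independent
all-orderings permutation average. Numbers therefore differ from
path-dependent implementations, while satisfying the same axioms
(efficiency, dummy, symmetry, linearity).

### The fast algorithm

Enumeration costs $2^n$ and is capped at $n \le 20$ (`shap_exact`). The
production path (`shap_fast`, `explain_table`) walks each (tree, background
row) pair once. Along a root-to-leaf path, each feature's accumulated split
conditions are either satisfied by the explained sample $x$, by the
background row $z$, or by both; a branch satisfiable by neither is pruned.
If a leaf's path features split into $a$ features passed only by $x$ and
$b$ passed only by $z$ (with $f = n - a - b$ unconstrained), the Shapley
sum over all coalitions collapses to closed forms
$P(a,b) = \sum_k \binom{f}{k} w(a-1+k)$ for the $x$-side features and
$N(a,b) = \sum_k \binom{f}{k} w(a+k)$ for the $z$-side ones, with
$w(s) = s!(n-s-1)!/n!$. The weight tables are computed once per feature
count in log-space (stable to $n$ in the hundreds), and the kernel is C++;
overall complexity is linear in trees × background rows × tree nodes, with
no exponential term.

## The pipeline and its parameters

* **Filtering.** Abundances strictly below `abundance_threshold`
  (default $10^{-15}$, dimensionless fractions) are zeroed, then taxa whose
  zero fraction is *strictly above* `prevalence_threshold` (default 0.9)
  are dropped. Both comparisons are strict, and boundary behavior is
  unit-tested (a taxon zero in exactly 90% of samples survives the default
  threshold). Values are assumed already relative; nothing is renormalized
  after filtering.
* **Leave-one-dataset-out (LODO).** Each study in turn is held out; the
  rest are concatenated on the union of their taxon sets. The retained-taxa
  set is computed on the training concatenation only and then imposed on
  the held-out study (missing taxa become zero columns), so no information
  flows from test to train; a test asserts that scrambling the held-out
  study's values leaves the trained model bit-identical.
* **Forest.** `ranger` probability forests, 500 trees, unlimited depth,
  seed 42 by default; leaf values are case-class probabilities, and routing
  is `x <= threshold` to the left child. The neutral tree representation is
  verified against the framework's own probabilities to $10^{-9}$ and can
  be serialized to JSON for re-explanation without refitting.
* **Explanation.** The background defaults to the full training matrix;
  `background_size` subsamples it (seeded) when speed matters more than an
  exact base value.
* **Embedding.** PCA on the SHAP matrix centers but does not scale the
  columns — they already share probability units, and scaling would inflate
  near-constant taxa. The embedding is fitted on *all* held-out samples
  (cases and controls, as in the package's comparison of class separation),
  while clustering uses only the correctly predicted cases
  (label = case and prediction strictly $> 0.5$; the threshold is a
  convention, chosen as the natural decision boundary). Signs are fixed for
  reproducibility: PC1 is flipped so the case-label mean is non-negative
  (cases on the right), any other component so its largest-magnitude
  loading is positive.
* **Clustering.** K-means++ seeding plus Lloyd iterations, best of 10
  seeded restarts. The cluster count comes from the elbow rule: run
  $k = 1..k_{\max}$ (default 10) and take the $k$ farthest, in
  perpendicular distance, from the chord joining the first and last points
  of the inertia curve; ties break toward smaller $k$, and identical points
  yield $k = 1$. Clusters are renumbered by decreasing median case
  probability so "cluster 1" is the highest-risk subgroup in every data
  set, making indices comparable across studies.
* **Enrichment.** Per taxon, a Kruskal-Wallis H test (tie-corrected,
  chi-square p) across the case clusters and a two-sided Mann-Whitney U
  test (normal approximation with tie and continuity correction) of each
  cluster against the controls, on relative abundances, flagged at raw
  $p < 0.05$. No multiple-testing correction is applied to the flag —
  that matches the analysis style this package reproduces — but
  Benjamini-Hochberg q-values are reported alongside so users can apply a
  corrected cutoff. The enriched/depleted call compares medians; when the
  medians tie (typical for sparse taxa: both zero), it falls back to the
  rank-mean direction implied by the U statistic, since the median rule is
  undefined exactly where sparse data live. Fully tied inputs return
  $H = 0, p = 1$ rather than an error.

## What the synthetic generator emulates — and what it does not

`generate_cohort` draws, per sample, latent log-abundances
(taxon base level + per-study batch shift + class/subtype effect + noise),
exponentiates, zeroes everything below the study-wide sparsity quantile
(default zero fraction 0.6, so prevalence filtering has real work to do),
and renormalizes each sample to sum to one. Because the effects act
*before* closure, a planted enrichment depresses every other taxon's
fraction — the self-induced compositional artifact real relative-abundance
data exhibit.

Defaults define the package's reference study conditions: 5 studies of
40 + 40 samples, 60 taxa, five 4-fold-enriched and one 4-fold-depleted
signal taxa, batch shifts of SD 0.25 and within-sample noise of SD 0.7 on
the log scale. The noise scales were fixed once so that the planted 4-fold
signature puts the cohort in the near-separable regime the test suite
assumes (Bayes-level AUC ≈ 1); the optional subtype configuration
(`default_subtypes()`: two disjoint five-taxon signatures at 8-fold) is
likewise sized so its ground truth is recoverable from the embedding —
8-fold is the regime of hallmark taxa that are nearly absent in the
contrasting group. Planted biomarkers receive base abundances from the
upper half of the taxon distribution: a "signature" taxon that is 99% zero
everywhere would be undetectable by construction, which is not what
reported signature taxa look like.

The generator does **not** emulate phylogenetic correlation between taxa,
over-dispersed count noise (data are continuous compositions, not reads),
unequal study sizes, or covariate structure (age, BMI, batch-confounded
labels). Passing tests on these cohorts therefore demonstrates the
*machinery* — attribution correctness, leakage-free LODO, embedding and
subtype recovery under known truth — not performance on any real cohort.

## Test and verification design

The suite checks, among others: the fast engine against exact enumeration
on 200 fuzzed ensembles ($n \le 12$, depth $\le 4$, tolerance $10^{-8}$)
and enumeration against the permutation oracle ($10^{-10}$); local accuracy
of every emitted explanation; exactly-zero attributions for features no
tree uses; hand-counted filtering boundary cases; LODO AUC above 0.9 on
every held-out default-cohort study versus chance-level AUC under label
permutation (20 seeds); Spearman $\rho \ge 0.7$ between PC1 and predicted
probability plus better class separation than raw-abundance PCA; subtype
recovery at median adjusted-Rand $\ge 0.8$ over 20 seeds; enrichment power
$\ge 0.9$ at the default effect size with a type-I rate $\le 0.08$ over 500
null taxa; and the $m \times n \to m \times 2 \to$ cluster-label shape
contracts on full pipeline runs. Simulation sizes inside the tests (e.g.
one held-out study per subtype seed, background subsampled to 160 rows)
are the package's chosen verification conditions; all thresholds were fixed
before the corresponding code paths were tuned, and the acceptance script
(`scripts/acceptance.R`) recomputes every headline quantity from scratch.

## Known limitations

* Only binary case-control problems; the case class is the explained
  output (control attributions are the negation).
* The interventional value function makes explanations depend on the
  background choice; subsampling the background trades base-value
  exactness for speed.
* Exact enumeration is capped at 20 features; beyond that only the fast
  path (which is exact for tree ensembles) applies.
* Gradient-boosted trees, interaction values, and path-dependent
  expectations are out of scope.
* The elbow rule is a heuristic; for flat inertia curves the chord
  criterion can be indecisive, which is why the cluster count can be pinned
  (`k`) in the pipeline config.
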