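---
title: "Topological characterization and guilt-by-association prediction of seed gene sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological characterization and guilt-by-association prediction of seed gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairnet)
```

## The scientific question

Genes that act in a common cellular program — DNA repair is the motivating
case — encode proteins that tend to work as physical complexes and
signaling cascades. On a genome-scale protein–protein interaction (PPI)
network this leaves a topological signature: the seed proteins have more
interaction partners than the background, they concentrate in the dense
global core of the network rather than in peripheral local hubs, and they
interact directly with one another. `repairnet` measures that signature,
tests it statistically, and exploits it to rank every unlabeled protein by
how likely it is to belong to the seed program.

## The model

For each node $i$ of a simple undirected graph (self-interactions and
duplicate edges removed at load time) the package computes:

- **Degree** $K_i$: the number of direct neighbors.
- **Core number**: the largest $K$ such that $i$ survives recursively
  deleting all nodes of degree $< K$. Degree and core number separate
  *local* hubs (high degree, low core) from *globally central* proteins
  (high core). We use igraph's linear-time peeling; its correctness is
  checked in the test suite against a literal recursive-removal oracle on
  hundreds of random graphs.
- **Repair-neighbor ratio** $\mathrm{RNR}_i = |N(i) \cap S| / K_i$ for
  seed set $S$: the fraction of $i$'s neighbors that are seeds. A node's
  own label never enters its ratio, and degree-0 nodes are assigned 0 so
  that the classifier input is total (the alternative, NA, would silently
  drop nodes from prediction).

Seed-versus-background location and shape differences in each feature are
tested with the two-sample Kolmogorov–Smirnov statistic
$D = \sup_t |F_1(t) - F_2(t)|$. Both empirical CDFs are evaluated at the
pooled sorted sample points, which handles the heavy ties of integer
degrees exactly and without jitter. The p-value uses the asymptotic
Kolmogorov distribution at effective size $n_1 n_2 / (n_1 + n_2)$ — the
appropriate regime for hundreds of seeds against a background of
thousands — with an exact-distribution option for small, tie-free samples.

### Classification

The three features are affinely scaled to $[-1, 1]$ (fitted min/max per
feature; constant features map to 0), then fed to LIBSVM through
**e1071**. The radial-basis kernel at the library's default cost and gamma
is the default model, with a polynomial-kernel SVM and an **rpart**
decision tree as alternatives. Decision values are calibrated to posterior
probabilities with a sigmoid (Platt) fit, which is what LIBSVM implements
internally; an equal-width binning calibrator (Laplace-smoothed positive
fraction per bin) is provided as an alternative. The sigmoid posterior is
monotone in the decision value; the binning posterior is not forced to be,
which is why it is not the default.

### Evaluation and the leakage policy

Performance is measured by stratified 5-fold cross-validation:
$\text{precision} = TP/(TP+FP)$, $\text{recall} = TP/(TP+FN)$, their
harmonic mean $F_1$, and the midrank Mann–Whitney AUC (equal to the
fraction of positive/negative pairs ranked correctly, ties counting one
half — verified in the tests against literal pair enumeration). Confusion
counts use a posterior threshold of 0.5; when nothing is predicted
positive, precision is reported as 0 with an explicit flag rather than
NaN. Pooled metrics come from summed per-fold counts, and the pooled AUC
from the single posterior each node receives as a test case.

Two design points deserve emphasis:

- **Stratification.** With ~50–150 positives against thousands of
  negatives, unstratified 20% splits can leave folds nearly without
  positives; folds are therefore stratified by label, with the fold seed a
  recorded parameter.
- **RNR leakage.** RNR is the only label-dependent feature. Computing it
  once on the fully labeled network lets test-fold labels leak into the
  features of their neighbors during CV. The default policy
  (`rnr_policy = "per_fold"`) therefore recomputes RNR inside each fold
  from training-fold positives only, for training and test rows alike; the
  `global` policy, which evaluates the single-table protocol, is
  selectable and recorded in the report. The report exposes the fold
  assignment and the per-fold RNR seed sets, so the no-leakage invariant
  is asserted directly in the test suite rather than taken on faith.
  Full-data *prediction* (candidate ranking) deliberately uses the global
  RNR: no held-out evaluation is claimed for the candidate list.

`cross_validate` takes the network and annotation rather than a prebuilt
feature table precisely because the per-fold policy must rebuild the RNR
column from the graph inside each fold.

### Candidate ranking

The full-data model scores every non-seed node; candidates are the nodes
with posterior above a threshold (default 0.5, configurable), sorted by
descending posterior with identifier tie-breaks so reruns are
byte-identical. Per-pathway classifiers reuse the CV machinery with a
single pathway as the positive class; reports for pathways under 30
members carry a `small_positive_set` flag, since a handful of positives
drowned in thousands of negatives is expected to evaluate poorly however
real the signal.

## The synthetic generator

`synthetic_spec()` describes a background Erdős–Rényi graph (default 2000
nodes at mean degree 6 — sparse, like a thresholded interactome at desk
scale) with a planted module of 60 nodes. The module receives extra
intra-module edges (each pair with probability 0.25) and 8 extra
attachments per planted node to background nodes sampled proportionally to
degree. Injection is additive — planted nodes keep their background edges
— so strengthening either signal parameter can only raise the planted
contrast in expectation, a monotonicity the tests check by paired
comparison across seeds. Ten planted nodes are withheld from the labels,
modeling true program members hidden among the negatives; recovering them
in the top of the candidate ranking is the pipeline's end-to-end benchmark.
A preferential-attachment background is available because real PPI degree
distributions are heavy-tailed, and the planted-contrast tests pass under
both backgrounds.

The defaults were chosen once to emulate the contrast a curated repair set
shows against a real interactome — positives several-fold above background
in mean degree and coreness, and an order of magnitude above it in mean
RNR — at a size where the whole study (simulation, characterization,
three-model CV, ranking) runs in seconds. What passing on these data shows
is that the pipeline recovers a planted topological signal of realistic
relative magnitude; it does **not** show robustness to the study biases of
real interactomes (heavily studied proteins accumulate edges), to false
interactions, or to seed lists whose curation itself followed network
proximity. Degree is the feature most exposed to study bias; core number
and RNR less so.

## Numerical choices and degenerate inputs

- Identifiers are compared verbatim after whitespace stripping; no case
  folding (gene symbols are case-sensitive by convention).
- Edge cleaning is idempotent, and the edge-list writer orders endpoints
  lexicographically within lines and sorts lines, so output is bit-stable.
- Feature tables print RNR to 4 decimal places; round-tripping through TSV
  therefore preserves RNR to $10^{-4}$, and exactly for the ratios of
  small integers that dominate.
- Group summaries suppress means for pathways under 4 members: averages
  over a couple of proteins are noise, and 4 is the smallest threshold
  that keeps an 8-member pathway while excluding a 3-member one.
- Scaling is fitted on training data only, so test values may fall outside
  $[-1, 1]$; this is intended and harmless to the SVM.
- All stochastic steps (graph generation, fold assignment, LIBSVM's
  internal Platt cross-validation) are seeded; identical seeds give
  identical reports down to the byte.

## A complete run

```{r pipeline, eval = FALSE}
sim <- generate_synthetic_network(synthetic_spec(seed = 1))
tab <- build_feature_table(sim$network, sim$annotation)
summarize_groups(tab, sim$annotation)
ks_two_sample(tab$rnr[tab$label == "positive"],
              tab$rnr[tab$label == "negative"])
cross_validate(sim$network, sim$annotation, kind = "svm_rbf", seed = 1)
cand <- predict_candidates(sim$network, sim$annotation, seed = 1)
head(cand, 10)
```

The numbered scripts under `analysis/` run the same study step by step and
leave all tables under `results/`.

## Known limitations

- The pipeline presumes an unweighted, undirected, simple interaction
  graph; confidence scores on edges are ignored.
- Per-pathway prediction with few members is reported but expected to be
  weak — the flag in the report is a warning, not a defect.
- Identifier mapping between gene and protein namespaces is the user's
  responsibility (supply a mapped list); the package does no remote
  lookups.
- Posterior probabilities are calibrated within the training distribution;
  with a different positive/negative prevalence at deployment they rank
  correctly but are not calibrated frequencies.
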