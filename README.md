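# repairnet

Network-based characterization and prediction of DNA repair genes on a
protein–protein interaction (PPI) network.

Curated seed sets such as the human DNA repair genes occupy a distinctive
position in the interactome: their proteins have more interaction partners
than background proteins, sit in the dense global core of the network, and
interact directly with one another far more often than chance predicts.
`repairnet` turns those three observations into a reusable
guilt-by-association pipeline for anyone with an edge list and a gene list:
it quantifies the seed set's topological signature, tests whether it differs
from the background, and ranks every unlabeled protein as a new candidate
member of the set.

## The method

For every node *i* of a simple undirected PPI graph the package computes
three features:

- **degree** `K_i` — the number of direct interaction partners;
- **k-core number** `K` — the largest `K` such that *i* survives
  recursively removing all nodes of degree `< K`; high values mark the
  global network center rather than local hubs;
- **repair-neighbor ratio** `RNR_i = |N(i) ∩ S| / K_i` — the fraction of
  *i*'s neighbors belonging to the seed set `S` (a node's own label never
  enters its ratio; isolated nodes get 0).

Seed-versus-background differences in each feature are assessed with the
two-sample Kolmogorov–Smirnov test, `D = sup_t |F1(t) − F2(t)|`, with an
asymptotic p-value at effective sample size `n1·n2/(n1+n2)`.

For prediction, the three features are scaled to `[−1, 1]` and fed to a
support vector machine (LIBSVM via **e1071**; radial-basis kernel at
default cost and gamma, with polynomial-kernel and decision-tree
alternatives). Decision values are converted to posterior probabilities by
a sigmoid (Platt) fit, and unlabeled proteins are ranked by posterior.
Evaluation uses stratified 5-fold cross-validation with precision
`TP/(TP+FP)`, recall `TP/(TP+FN)`, `F1`, and midrank Mann–Whitney AUC.
Because the RNR feature depends on the labels, the default CV policy
recomputes it inside every fold from training-fold labels only (an honest,
leakage-free protocol); the single-table `global` policy is also available.

A synthetic planted-module generator (sparse background graph plus a small
module with extra intra-set edges and hub attachments, some members
deliberately hidden among the negatives) lets the entire pipeline run and
be tested without downloading any interactome.

## Worked example

The `analysis/` scripts run the whole study on synthetic data
(`Rscript analysis/01_simulate.R` through `05_predict.R`). Condensed:

```r
library(repairnet)

sim <- generate_synthetic_network(synthetic_spec(seed = 1))
tab <- build_feature_table(sim$network, sim$annotation)
aggregate(cbind(degree, k_core, rnr) ~ label, tab, mean)
#>      label    degree   k_core        rnr
#> 1 negative  6.341538 3.785128 0.05684251
#> 2 positive 28.960000 9.900000 0.41988535

ks_two_sample(tab$degree[tab$label == "positive"],
              tab$degree[tab$label == "negative"])
#> two-sample KS: D = 0.9949, p = 2.46e-42 (n1 = 50, n2 = 1950)

cross_validate(sim$network, sim$annotation, kind = "svm_rbf", seed = 1)
#> 5-fold CV, model svm_rbf, rnr_policy per_fold, seed 1
#> pooled: precision 0.845, recall 0.980, F1 0.907, AUC 0.997

cand <- predict_candidates(sim$network, sim$annotation, seed = 1)
head(cand, 3)
#>      id degree k_core       rnr posterior_probability
#> 1 P0053     31     10 0.4193548             0.8594342
#> 2 P1603     30     10 0.3333333             0.8480732
#> 3 P0851     29     10 0.4827586             0.8441384

sum(sim$truth$held_out %in% head(cand$id, 20))
#> [1] 9
```

The seed set's mean degree, coreness and RNR are several-fold above
background; the KS test rejects equality decisively; cross-validation
recovers the planted module almost perfectly; and 9 of the 10 module nodes
hidden among the negatives surface in the top 20 ranked candidates —
exactly the behavior a guilt-by-association predictor must show before it
is pointed at real data. (As a sanity control, a generator with no injected
signal yields CV AUC ≈ 0.5.)

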