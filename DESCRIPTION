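Package: repairnet
Title: Network-Based Characterization and Prediction of DNA Repair Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes a seed set of genes (such as human DNA repair
    genes) on a protein-protein interaction network using three per-node
    topological features (degree, k-core number, and the repair-neighbor
    ratio), compares feature distributions between the seed set and the
    background with two-sample Kolmogorov-Smirnov tests, and trains a
    cross-validated support vector machine that ranks unlabeled proteins
    as new candidates by calibrated posterior probability. Includes a
    synthetic planted-module network generator so the full pipeline runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    e1071,
    rpart,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
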