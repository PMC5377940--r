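#!/usr/bin/env Rscript
# Step 2 — load the cleaned network and gene set from disk and compute the
# three per-node topological features: degree, k-core number and the
# repair-neighbor ratio (RNR).

suppressMessages(library(repairnet))

network <- load_edge_list("results/data/network_edges.tsv")
annotation <- load_gene_set("results/data/positive_genes.txt", network,
                            pathway_map = "results/data/pathway_map.tsv")

tab <- build_feature_table(network, annotation)
write_feature_table(tab, "results/feature_table.tsv")

pos <- tab$label == "positive"
cat(sprintf("mean degree : positives %.2f vs background %.2f\n",
            mean(tab$degree[pos]), mean(tab$degree[!pos])))
cat(sprintf("mean k-core : positives %.2f vs background %.2f\n",
            mean(tab$k_core[pos]), mean(tab$k_core[!pos])))
cat(sprintf("mean RNR    : positives %.4f vs background %.4f\n",
            mean(tab$rnr[pos]), mean(tab$rnr[!pos])))
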