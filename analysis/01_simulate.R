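#!/usr/bin/env Rscript
# Step 1 — simulate the study data: a sparse background interactome with a
# planted repair-like module (elevated degree, coreness, and intra-set
# edges), plus a positive gene list with 10 planted nodes deliberately
# hidden among the negatives. Writes the same file formats the loaders read.

suppressMessages(library(repairnet))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

spec <- synthetic_spec(seed = 1)  # defaults: 2000 nodes, 60 planted, 10 hidden
sim <- generate_synthetic_network(spec)

write_edge_list(sim$network, "results/data/network_edges.tsv")
writeLines(sim$annotation$positives, "results/data/positive_genes.txt")
write_truth(sim$truth, "results/data/truth.json")

# split the planted set into 3 overlapping pseudo-pathways for the
# per-pathway analyses (mirroring real pathway annotations that overlap)
paths <- split_pathways(sim$truth, n_pathways = 3, overlap_fraction = 0.2,
                        seed = 1)
pm <- data.frame(id = unlist(paths, use.names = FALSE),
                 pathway = rep(names(paths), lengths(paths)))
pm <- pm[pm$id %in% sim$annotation$positives, ]
write.table(pm, "results/data/pathway_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)

cat(sprintf("network: %d nodes, %d edges\n",
            igraph::vcount(sim$network), igraph::ecount(sim$network)))
cat(sprintf("positives: %d labeled, %d planted nodes hidden as negatives\n",
            length(sim$annotation$positives), length(sim$truth$held_out)))
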