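test_that("generation is deterministic and yields a simple labeled network", {
  sp <- synthetic_spec(n_background = 300L, n_planted = 20L, hold_out = 4L,
                       seed = 12)
  a <- suppressMessages(generate_synthetic_network(sp))
  b <- suppressMessages(generate_synthetic_network(sp))
  expect_identical(igraph::as_edgelist(a$network), igraph::as_edgelist(b$network))
  expect_identical(a$truth$planted, b$truth$planted)
  expect_true(igraph::is_simple(a$network))
  expect_equal(igraph::vcount(a$network), 300)
  expect_true(all(a$truth$held_out %in% a$truth$planted))
  expect_setequal(a$annotation$positives,
                  setdiff(a$truth$planted, a$truth$held_out))
})

test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(n_planted = 0L), "non-empty")
  expect_error(synthetic_spec(n_background = 50L, n_planted = 50L), "<")
  expect_error(synthetic_spec(p_intra = 1.2), "p_intra")
  expect_error(synthetic_spec(n_planted = 5L, hold_out = 9L), "hold_out")
})

test_that("the planted module shows the three expected signals under both backgrounds", {
  for (bg in c("er", "pa")) {
    sp <- synthetic_spec(background_model = bg, seed = 2)
    sim <- suppressMessages(generate_synthetic_network(sp))
    tab <- suppressMessages(build_feature_table(sim$network, sim$annotation))
    pos <- tab$label == "positive"
    expect_gt(mean(tab$degree[pos]), mean(tab$degree[!pos]))
    expect_gt(mean(tab$k_core[pos]), mean(tab$k_core[!pos]))
    expect_gt(mean(tab$rnr[pos]), mean(tab$rnr[!pos]))
  }
})

test_that("planted degree distributions separate from background; null does not", {
  p_sig <- p_null <- numeric(10)
  for (s in 1:10) {
    sim <- suppressMessages(generate_synthetic_network(
      synthetic_spec(n_background = 600L, n_planted = 30L, hold_out = 0L,
                     seed = s)))
    deg <- compute_degrees(sim$network)
    in_planted <- names(deg) %in% sim$truth$planted
    p_sig[s] <- ks_two_sample(deg[in_planted], deg[!in_planted])$p_value

    nul <- suppressMessages(generate_synthetic_network(
      synthetic_spec(n_background = 600L, n_planted = 30L, hold_out = 0L,
                     p_intra = 0, extra_attach = 0L, seed = s)))
    ndeg <- compute_degrees(nul$network)
    nin <- names(ndeg) %in% nul$truth$planted
    p_null[s] <- ks_two_sample(ndeg[nin], ndeg[!nin])$p_value
  }
  expect_gte(sum(p_sig < 0.01), 9)
  expect_lte(sum(p_null < 0.01), 2)
})

test_that("raising the intra-module edge probability raises planted RNR", {
  wins <- 0L
  for (s in 1:10) {
    rnr_at <- function(p) {
      sim <- suppressMessages(generate_synthetic_network(
        synthetic_spec(n_background = 400L, n_planted = 25L, hold_out = 0L,
                       p_intra = p, extra_attach = 0L, seed = s)))
      rnr <- compute_rnr(sim$network, sim$truth$planted)
      mean(rnr[sim$truth$planted])
    }
    if (rnr_at(0.3) >= rnr_at(0.1)) wins <- wins + 1L
  }
  # one-sided sign test at the 5% level: 9+ of 10 under H0 has p < 0.011
  expect_gte(wins, 9)
})

test_that("truth files round-trip losslessly", {
  sp <- synthetic_spec(n_background = 300L, n_planted = 20L, seed = 6)
  sim <- suppressMessages(generate_synthetic_network(sp))
  f <- withr::local_tempfile()
  write_truth(sim$truth, f)
  back <- read_truth(f)
  expect_identical(back$planted, sim$truth$planted)
  expect_identical(back$held_out, sim$truth$held_out)
  expect_equal(unclass(back$spec), unclass(sim$truth$spec))
})

test_that("generator output files feed straight back into network_io", {
  sp <- synthetic_spec(n_background = 300L, n_planted = 20L, seed = 3)
  sim <- suppressMessages(generate_synthetic_network(sp))
  ef <- withr::local_tempfile(); gf <- withr::local_tempfile()
  write_edge_list(sim$network, ef)
  writeLines(sim$annotation$positives, gf)
  g <- suppressMessages(load_edge_list(ef))
  ann <- suppressMessages(load_gene_set(gf, g))
  expect_equal(igraph::ecount(g), igraph::ecount(sim$network))
  expect_setequal(ann$positives, sim$annotation$positives)
})

test_that("pathway splits cover the planted set with controlled overlap", {
  sp <- synthetic_spec(n_background = 300L, n_planted = 24L, seed = 5)
  sim <- suppressMessages(generate_synthetic_network(sp))
  one <- split_pathways(sim$truth, 1)
  expect_identical(one[[1]], sort(sim$truth$planted))
  parts <- split_pathways(sim$truth, 3, overlap_fraction = 0.2, seed = 2)
  expect_setequal(unlist(parts, use.names = FALSE), sim$truth$planted)
  sizes <- lengths(parts)
  total <- sum(sizes)
  # each pathway borrowed floor(0.2 * base size) members
  expect_gt(total, length(sim$truth$planted))
  expect_lte(total, length(sim$truth$planted) * 1.3)
  disjoint <- split_pathways(sim$truth, 3, overlap_fraction = 0, seed = 2)
  expect_equal(sum(lengths(disjoint)), length(sim$truth$planted))
  expect_error(split_pathways(sim$truth, 3, overlap_fraction = 1), "overlap")
  expect_error(split_pathways(sim$truth, 0), "n_pathways")
})
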