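small_sim <- function(seed = 1, ...) {
  sp <- synthetic_spec(n_background = 500L, n_planted = 30L, hold_out = 5L,
                       seed = seed, ...)
  suppressMessages(generate_synthetic_network(sp))
}

test_that("scaling maps observed min/max to -1/+1 and constants to 0", {
  tab <- data.frame(degree = c(0L, 5L, 10L), k_core = c(3L, 3L, 3L),
                    rnr = c(0, 0.5, 1))
  p <- fit_scaling(tab)
  x <- apply_scaling(p, tab)
  expect_equal(unname(x[, "degree"]), c(-1, 0, 1))
  expect_equal(unname(x[, "k_core"]), c(0, 0, 0))
  expect_equal(unname(x[, "rnr"]), c(-1, 0, 1))
  # train-only fitting: out-of-range test values may exceed [-1, 1]
  out <- apply_scaling(p, data.frame(degree = 20L, k_core = 3L, rnr = 0.5))
  expect_gt(out[, "degree"], 1)
})

test_that("training separates a cleanly separated toy problem", {
  set.seed(1)
  n <- 40
  tab <- data.frame(
    degree = c(rpois(n, 4), rpois(n, 40)),
    k_core = c(rpois(n, 2), rpois(n, 20)),
    rnr = c(runif(n, 0, 0.05), runif(n, 0.6, 1)),
    label = factor(rep(c("negative", "positive"), each = n),
                   levels = c("negative", "positive")))
  m <- train_model(tab, "svm_rbf", seed = 1)
  p <- posterior(m, tab)
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(mean((p >= 0.5) == (tab$label == "positive")), 1)
  # monotonicity: a row deep in the positive region outranks a deep negative
  deep <- data.frame(degree = c(2L, 50L), k_core = c(1L, 25L), rnr = c(0, 0.9))
  pp <- posterior(m, deep)
  expect_gt(pp[2], pp[1])
})

test_that("training is deterministic given a seed and rejects one-class data", {
  sim <- small_sim()
  tab <- suppressMessages(build_feature_table(sim$network, sim$annotation))
  m1 <- train_model(tab, "svm_rbf", seed = 7)
  m2 <- train_model(tab, "svm_rbf", seed = 7)
  expect_identical(posterior(m1, tab), posterior(m2, tab))
  onecls <- tab[tab$label == "negative", ]
  expect_error(train_model(onecls, "svm_rbf"), "both classes")
})

test_that("all three model kinds and both calibrators yield valid posteriors", {
  sim <- small_sim()
  tab <- suppressMessages(build_feature_table(sim$network, sim$annotation))
  for (kind in c("svm_rbf", "svm_poly", "decision_tree")) {
    m <- train_model(tab, kind, seed = 1)
    p <- posterior(m, tab)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_gt(auc_midrank(p, tab$label), 0.8)
  }
  mb <- train_model(tab, "svm_rbf", seed = 1, calibration = "binning")
  pb <- posterior(mb, tab)
  expect_true(all(pb >= 0 & pb <= 1))
  expect_gt(auc_midrank(pb, tab$label), 0.8)
  mu <- train_model(tab, "svm_rbf", seed = 1, calibration = "none")
  expect_error(posterior(mu, tab), "without calibration")
})

test_that("metric formulas hold exactly, with degenerate flags", {
  m <- compute_metrics(5, 0, 10, 0)
  expect_equal(c(m$precision, m$recall, m$f1), c(1, 1, 1))
  m2 <- compute_metrics(37, 13, 1000, 34)
  expect_equal(m2$precision, 0.74)
  expect_equal(m2$recall, 37 / 71)
  expect_equal(m2$f1, 2 * m2$precision * m2$recall / (m2$precision + m2$recall))
  m3 <- compute_metrics(0, 0, 10, 5)
  expect_equal(m3$precision, 0)
  expect_equal(m3$f1, 0)
  expect_true(all(c("no_predicted_positives", "zero_true_positives") %in% m3$flags))
})

test_that("F1 lies between precision and recall and vanishes iff TP = 0", {
  set.seed(33)
  for (i in 1:50) {
    cts <- as.list(rpois(4, 8))
    names(cts) <- c("tp", "fp", "tn", "fn")
    m <- do.call(compute_metrics, cts)
    if (cts$tp == 0) {
      expect_equal(m$f1, 0)
    } else {
      expect_gte(m$f1, min(m$precision, m$recall) - 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  }
})

test_that("midrank AUC matches hand rankings and tie conventions", {
  expect_equal(auc_midrank(rep(0.3, 8), c(rep(TRUE, 3), rep(FALSE, 5))), 0.5)
  # 6 items, hand-enumerated pairs: pos {0.9, 0.7, 0.4}, neg {0.8, 0.4, 0.1}
  s <- c(0.9, 0.7, 0.4, 0.8, 0.4, 0.1)
  l <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(auc_midrank(s, l), oracle_auc(s, l))
  expect_equal(auc_midrank(s, l), 6.5 / 9)
  expect_error(auc_midrank(1:3, c(TRUE, TRUE, TRUE)), "at least one")
})

test_that("stratified CV fills every fold with both classes and sums counts", {
  sim <- small_sim()
  rep <- suppressMessages(cross_validate(sim$network, sim$annotation, seed = 2))
  expect_equal(nrow(rep$folds), 5)
  npos <- length(sim$annotation$positives)
  expect_equal(sum(rep$folds$tp + rep$folds$fn), npos)
  expect_equal(rep$pooled$tp + rep$pooled$fn, npos)
  expect_equal(rep$pooled$tn + rep$pooled$fp,
               igraph::vcount(sim$network) - npos)
  expect_true(all(rep$folds$tp + rep$folds$fn >= 1))  # stratification
  expect_true(rep$pooled$auc >= 0 && rep$pooled$auc <= 1)
  # every node scored exactly once across folds
  expect_setequal(rep$predictions$id, igraph::V(sim$network)$name)
})

test_that("per-fold RNR policy never uses test-fold positive labels", {
  sim <- small_sim()
  rep <- suppressMessages(cross_validate(sim$network, sim$annotation,
                                         seed = 3, rnr_policy = "per_fold"))
  pos <- sim$annotation$positives
  for (k in seq_len(rep$n_folds)) {
    test_ids <- names(rep$fold_assignment)[rep$fold_assignment == k]
    expect_length(intersect(rep$rnr_seed_sets[[k]], intersect(test_ids, pos)), 0)
    expect_setequal(rep$rnr_seed_sets[[k]], setdiff(pos, test_ids))
  }
  glob <- suppressMessages(cross_validate(sim$network, sim$annotation,
                                          seed = 3, rnr_policy = "global"))
  expect_true(all(vapply(glob$rnr_seed_sets, setequal, logical(1), pos)))
})

test_that("shuffled labels carry no signal: CV AUC near one half", {
  aucs <- vapply(1:5, function(s) {
    sim <- small_sim(seed = s)
    set.seed(100 + s)
    fake <- gene_set_annotation(sample(igraph::V(sim$network)$name,
                                       length(sim$annotation$positives)))
    r <- suppressMessages(cross_validate(sim$network, fake, seed = s))
    r$pooled$auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("CV refuses fewer positives than folds and reports are serializable", {
  g <- random_named_gnp(60, 0.1)
  tiny <- gene_set_annotation(igraph::V(g)$name[1:3])
  expect_error(suppressMessages(cross_validate(g, tiny, n_folds = 5)),
               "n_folds")
  sim <- small_sim()
  rep <- suppressMessages(cross_validate(sim$network, sim$annotation, seed = 1))
  f <- withr::local_tempfile()
  write_evaluation_report(rep, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$pooled$auc, rep$pooled$auc, tolerance = 1e-12)
  expect_equal(back$rnr_policy, "per_fold")
})
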