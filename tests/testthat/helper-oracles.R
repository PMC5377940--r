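# Independent brute-force oracles and small graph builders used across tests.

# Core number by literally iterating "remove all nodes with degree < K" to a
# fixpoint for each K, independent of any peeling implementation.
oracle_kcore <- function(g) {
  nodes <- igraph::V(g)$name
  core <- stats::setNames(integer(length(nodes)), nodes)
  k <- 0L
  repeat {
    k <- k + 1L
    h <- g
    repeat {
      deg <- igraph::degree(h)
      drop <- names(deg)[deg < k]
      if (length(drop) == 0L) break
      h <- igraph::delete_vertices(h, drop)
    }
    surv <- igraph::V(h)$name
    if (length(surv) == 0L) break
    core[surv] <- k
  }
  core
}

# AUC as the literal fraction of (positive, negative) pairs correctly
# ordered, ties counting one half.
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  total / (length(sp) * length(sn))
}

# KS D as a double loop over all pooled sample points.
oracle_ks_D <- function(x, y) {
  best <- 0
  for (t in c(x, y)) {
    d <- abs(mean(x <= t) - mean(y <= t))
    if (d > best) best <- d
  }
  best
}

random_named_gnp <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  g
}

# Star with `n_leaves` leaves; the first `n_pos` leaves form the seed set.
star_network <- function(n_leaves, n_pos) {
  leaves <- sprintf("L%03d", seq_len(n_leaves))
  em <- cbind("center", leaves)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  list(network = g, positives = leaves[seq_len(n_pos)])
}

toy_path <- function(file) system.file("extdata", file, package = "repairnet")
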