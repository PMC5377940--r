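#' Node degrees
#'
#' The degree of a protein is the number of its direct interaction partners
#' in the simple undirected network.
#'
#' @param network A simple undirected `igraph` graph.
#' @return Named integer vector, one entry per node.
#' @export
compute_degrees <- function(network) {
  d <- igraph::degree(network, loops = FALSE)
  storage.mode(d) <- "integer"
  d
}

#' K-core numbers
#'
#' A node's core number is the largest K such that it survives recursively
#' removing all nodes of degree < K. High core numbers mark globally
#' central proteins, as opposed to local hubs whose high degree is confined
#' to a sparse neighborhood.
#'
#' @param network A simple undirected `igraph` graph.
#' @return Named integer vector of core numbers.
#' @export
kcore_decomposition <- function(network) {
  k <- igraph::coreness(network)
  storage.mode(k) <- "integer"
  k
}

#' Repair-neighbor ratio (RNR)
#'
#' For each node, the fraction of its direct neighbors that belong to the
#' positive (seed) set: `|neighbors(i) ∩ positives| / degree(i)`. A node's
#' own label never enters its ratio, and degree-0 nodes get RNR 0 by
#' convention so the classifier input is total.
#'
#' @param network A simple undirected `igraph` graph.
#' @param positives Character vector of positive identifiers; must all be
#'   network nodes (intersect first if necessary).
#' @return Named numeric vector in `[0, 1]`.
#' @export
compute_rnr <- function(network, positives) {
  nodes <- igraph::V(network)$name
  positives <- unique(as.character(positives))
  missing <- setdiff(positives, nodes)
  if (length(missing))
    stop("positives not present in the network: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         " — intersect with the node set first")
  is_pos <- nodes %in% positives
  # one sparse product: positive-neighbor counts for all nodes at once
  adj <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  pos_neighbors <- as.numeric(adj %*% is_pos)
  deg <- igraph::degree(network, loops = FALSE)
  rnr <- ifelse(deg > 0, pos_neighbors / deg, 0)
  if (any(deg == 0))
    message(sum(deg == 0), " isolated node(s) assigned RNR = 0")
  names(rnr) <- nodes
  rnr
}

#' Build the per-node feature table
#'
#' Joins degree, core number, RNR and the positive/negative label into one
#' data frame with one row per network node.
#'
#' @param network A simple undirected `igraph` graph.
#' @param annotation A `gene_set_annotation`.
#' @return A `data.frame` with columns `id`, `degree`, `k_core`, `rnr`,
#'   `label` (factor, levels `negative`/`positive`).
#' @export
build_feature_table <- function(network, annotation) {
  nodes <- igraph::V(network)$name
  positives <- intersect(annotation$positives, nodes)
  tab <- data.frame(
    id = nodes,
    degree = as.integer(compute_degrees(network)),
    k_core = as.integer(kcore_decomposition(network)),
    rnr = as.numeric(compute_rnr(network, positives)),
    label = factor(ifelse(nodes %in% positives, "positive", "negative"),
                   levels = c("negative", "positive")),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  tab
}

#' Write a feature table as TSV
#'
#' Fixed column order (id, degree, k_core, rnr, label); RNR is printed to
#' 4 decimal places.
#'
#' @param table Feature table from [build_feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  out$rnr <- sprintf("%.4f", out$rnr)
  utils::write.table(out[, c("id", "degree", "k_core", "rnr", "label")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Input path.
#' @return A feature-table `data.frame`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  tab$degree <- as.integer(tab$degree)
  tab$k_core <- as.integer(tab$k_core)
  tab$rnr <- as.numeric(tab$rnr)
  tab$label <- factor(tab$label, levels = c("negative", "positive"))
  tab
}
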