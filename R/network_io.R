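#' Read and clean an interaction network from an edge-list file
#'
#' Parses a two-column TSV edge list or a SIF file into a simple undirected
#' \pkg{igraph} graph. Self-interactions are dropped and redundant edges
#' (the same unordered pair listed more than once, in either orientation)
#' are collapsed to a single edge; the counts of dropped lines are reported
#' via [message()].
#'
#' @param path Path to the edge-list file.
#' @param dialect `"tsv2col"` (default): whitespace/tab-separated lines with
#'   two identifier columns (extra columns are ignored with a warning);
#'   `"sif"`: `node relation node [node ...]` lines, one edge per trailing
#'   node.
#' @param header `"auto"` (default) inspects the first line for common
#'   column-header words (`source`, `target`, `protein1`, ...); `TRUE`
#'   always skips the first line; `FALSE` never does.
#' @param node_list Optional path to a plain-text file of identifiers, one
#'   per line, to add as (possibly isolated) nodes. Edge lists cannot
#'   express isolated nodes on their own.
#'
#' @return A simple undirected `igraph` graph whose vertex names are the
#'   whitespace-stripped identifiers.
#' @export
load_edge_list <- function(path, dialect = c("tsv2col", "sif"),
                           header = "auto", node_list = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("edge-list file is empty: ", path)

  if (identical(header, "auto")) {
    toks <- strsplit(trimws(lines[[1L]]), "[\t ]+")[[1L]]
    hdr_re <- "^(source|target|from|to|node[12ab]?|protein[._]?[12ab]?|gene[12ab]?|interactor[._]?[12ab]?|id[12ab]?)$"
    skip <- length(toks) >= 2L && all(grepl(hdr_re, tolower(toks[1:2])))
  } else {
    skip <- isTRUE(header)
  }
  offset <- if (skip) 1L else 0L
  if (skip) lines <- lines[-1L]
  if (length(lines) == 0L) stop("edge-list file has a header but no data: ", path)

  pairs <- vector("list", length(lines))
  warned_extra <- FALSE
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[[i]]), "[\t ]+")[[1L]]
    if (dialect == "tsv2col") {
      if (length(toks) < 2L)
        stop("malformed edge line ", i + offset, ": expected 2 identifier columns, got ",
             length(toks))
      if (length(toks) > 2L && !warned_extra) {
        warning("extra columns beyond the first two are ignored (first at line ",
                i + offset, ")")
        warned_extra <- TRUE
      }
      pairs[[i]] <- cbind(toks[1L], toks[2L])
    } else {
      if (length(toks) < 3L)
        stop("malformed SIF line ", i + offset,
             ": expected 'node relation node [node ...]', got ", length(toks),
             " tokens")
      pairs[[i]] <- cbind(toks[1L], toks[-(1:2)])
    }
  }
  em <- do.call(rbind, pairs)

  self <- em[, 1L] == em[, 2L]
  n_self <- sum(self)
  em <- em[!self, , drop = FALSE]
  if (nrow(em) == 0L) stop("no edges remain after removing self-interactions")

  key <- ifelse(em[, 1L] < em[, 2L],
                paste(em[, 1L], em[, 2L], sep = "\r"),
                paste(em[, 2L], em[, 1L], sep = "\r"))
  dup <- duplicated(key)
  n_dup <- sum(dup)
  em <- em[!dup, , drop = FALSE]

  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  if (!is.null(node_list)) {
    extra <- trimws(readLines(node_list, warn = FALSE))
    extra <- setdiff(extra[nzchar(extra)], igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra), name = extra)
  }
  message("loaded network: ", igraph::vcount(g), " nodes, ", igraph::ecount(g),
          " edges (dropped ", n_self, " self-interactions, ", n_dup,
          " redundant interactions)")
  g
}

#' Write a cleaned network as a bit-stable two-column TSV
#'
#' Endpoints are lexicographically ordered within each line and lines are
#' sorted, so the same graph always serializes to the same bytes.
#'
#' @param network A simple undirected `igraph` graph.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  em <- igraph::as_edgelist(network, names = TRUE)
  if (nrow(em) > 0L) {
    swap <- em[, 1L] > em[, 2L]
    em[swap, ] <- em[swap, c(2L, 1L), drop = FALSE]
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  }
  writeLines(paste(em[, 1L], em[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Load a positive gene set, restricted to the network
#'
#' Reads one identifier per line, intersects with the network's nodes, and
#' optionally attaches pathway labels from a two-column TSV
#' (identifier, pathway); a gene may belong to several pathways.
#'
#' @param path Path to the gene-set file.
#' @param network The `igraph` interaction network.
#' @param pathway_map Optional path to a two-column identifier/pathway TSV.
#' @return An object of class `gene_set_annotation`: a list with `positives`
#'   (identifiers present in the network), `pathways` (named list of
#'   character vectors, each a subset of `positives`), and `unmapped`
#'   (listed identifiers absent from the network).
#' @export
load_gene_set <- function(path, network, pathway_map = NULL) {
  ids <- unique(trimws(readLines(path, warn = FALSE)))
  ids <- ids[nzchar(ids)]
  nodes <- igraph::V(network)$name
  positives <- intersect(ids, nodes)
  unmapped <- setdiff(ids, nodes)
  if (length(positives) == 0L)
    stop("no gene in the positive set maps into the network; nothing to characterize")

  pathways <- NULL
  if (!is.null(pathway_map)) {
    pm <- utils::read.table(pathway_map, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE,
                            col.names = c("id", "pathway"))
    pm$id <- trimws(pm$id)
    pm <- pm[pm$id %in% positives, , drop = FALSE]
    pathways <- split(pm$id, pm$pathway)
    pathways <- lapply(pathways, unique)
  }
  message("gene set: ", length(positives), " of ", length(ids),
          " identifiers mapped into the network (", length(unmapped),
          " unmapped)")
  gene_set_annotation(positives, pathways, unmapped)
}

#' Construct a gene-set annotation
#'
#' @param positives Character vector of positive identifiers (already
#'   restricted to the network).
#' @param pathways Optional named list of character vectors; every member
#'   must be in `positives`.
#' @param unmapped Identifiers from the original list absent from the
#'   network.
#' @return A `gene_set_annotation` object.
#' @export
gene_set_annotation <- function(positives, pathways = NULL, unmapped = character()) {
  positives <- unique(as.character(positives))
  if (!is.null(pathways)) {
    stray <- setdiff(unlist(pathways, use.names = FALSE), positives)
    if (length(stray))
      stop("pathway members not in the positive set: ",
           paste(utils::head(stray, 5L), collapse = ", "))
  }
  structure(list(positives = positives,
                 pathways = pathways,
                 unmapped = unique(as.character(unmapped))),
            class = "gene_set_annotation")
}

#' @export
print.gene_set_annotation <- function(x, ...) {
  cat("gene_set_annotation:", length(x$positives), "positives,",
      length(x$unmapped), "unmapped")
  if (!is.null(x$pathways))
    cat(",", length(x$pathways), "pathways")
  cat("\n")
  invisible(x)
}

#' Number of negative (background) samples in the network
#'
#' Every network node not in the positive set counts as a negative sample;
#' with 14,706 proteins and 149 positives this is 14,557.
#'
#' @param network The `igraph` interaction network.
#' @param annotation A `gene_set_annotation`.
#' @return Integer count of negatives.
#' @export
count_negatives <- function(network, annotation) {
  nodes <- igraph::V(network)$name
  length(nodes) - length(intersect(annotation$positives, nodes))
}
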