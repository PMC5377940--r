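#' Specification for a synthetic planted-module network
#'
#' Describes a sparse background interaction network with a small planted
#' "repair-like" module carrying the three signals the analysis assumes:
#' elevated degree, elevated coreness, and enriched within-set edges. The
#' defaults emulate, at desk scale, the contrast a curated seed set shows
#' against a genome-wide interactome background (positives several-fold
#' above background in mean degree and coreness, with strongly enriched
#' intra-set interaction).
#'
#' @param n_background Total number of nodes (default 2000).
#' @param n_planted Size of the planted module, drawn from the background
#'   nodes (default 60).
#' @param mean_degree Target mean degree of the background graph
#'   (default 6).
#' @param p_intra Probability of an extra edge between each pair of planted
#'   nodes (default 0.25).
#' @param extra_attach Extra attachments from each planted node to
#'   high-degree background nodes (default 8).
#' @param hold_out Number of planted nodes left unlabeled, modeling true
#'   members hidden among the negatives (default 10).
#' @param background_model `"er"` (Erdős–Rényi, default, analytically
#'   transparent) or `"pa"` (preferential attachment, heavy-tailed like
#'   real interactomes).
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_background = 2000L, n_planted = 60L,
                           mean_degree = 6, p_intra = 0.25,
                           extra_attach = 8L, hold_out = 10L,
                           background_model = c("er", "pa"), seed = 1L) {
  background_model <- match.arg(background_model)
  if (n_planted < 1L) stop("planted set must be non-empty")
  if (n_planted >= n_background) stop("n_planted must be < n_background")
  if (p_intra < 0 || p_intra > 1) stop("p_intra must be in [0, 1]")
  if (hold_out > n_planted) stop("hold_out cannot exceed n_planted")
  structure(list(n_background = as.integer(n_background),
                 n_planted = as.integer(n_planted),
                 mean_degree = mean_degree, p_intra = p_intra,
                 extra_attach = as.integer(extra_attach),
                 hold_out = as.integer(hold_out),
                 background_model = background_model,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labeled network
#'
#' Builds the background graph, plants the module by adding intra-module
#' edges (each pair with probability `p_intra`) and extra attachments from
#' each planted node to background nodes sampled proportionally to their
#' background degree. Signal injection is additive — a planted node keeps
#' its background edges — so strengthening the signal parameters never
#' weakens the planted contrast in expectation. `hold_out` planted nodes
#' are omitted from the positive labels, emulating true members hidden
#' among the negatives.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `network` (simple undirected `igraph`),
#'   `annotation` (`gene_set_annotation` labeling planted-minus-held-out
#'   as positive), and `truth` (`synthetic_truth`: planted set, held-out
#'   subset, the spec and seed).
#' @export
generate_synthetic_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_background
  g <- switch(spec$background_model,
    er = igraph::sample_gnp(n, p = min(spec$mean_degree / (n - 1), 1)),
    pa = igraph::sample_pa(n, m = max(1L, round(spec$mean_degree / 2)),
                           directed = FALSE))
  igraph::V(g)$name <- sprintf("P%04d", seq_len(n))
  bg_degree <- igraph::degree(g)

  planted <- sort(sample(igraph::V(g)$name, spec$n_planted))
  pidx <- match(planted, igraph::V(g)$name)

  new_edges <- integer(0)
  if (spec$p_intra > 0 && spec$n_planted >= 2L) {
    pairs <- utils::combn(pidx, 2L)
    keep <- stats::runif(ncol(pairs)) < spec$p_intra
    new_edges <- c(new_edges, as.vector(pairs[, keep, drop = FALSE]))
  }
  if (spec$extra_attach > 0L) {
    hubs <- setdiff(seq_len(n), pidx)
    w <- bg_degree[hubs] + 1e-9  # degree-proportional: favors hubs
    for (v in pidx) {
      targets <- sample(hubs, min(spec$extra_attach, length(hubs)),
                        prob = w)
      new_edges <- c(new_edges, rbind(v, targets))
    }
  }
  if (length(new_edges))
    g <- igraph::add_edges(g, new_edges)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)

  held_out <- sort(sample(planted, spec$hold_out))
  annotation <- gene_set_annotation(setdiff(planted, held_out))
  truth <- structure(list(planted = planted, held_out = held_out,
                          spec = spec, seed = spec$seed),
                     class = "synthetic_truth")
  list(network = g, annotation = annotation, truth = truth)
}

#' Write / read a synthetic truth file (lossless JSON round-trip)
#'
#' @param truth A `synthetic_truth`.
#' @param path File path.
#' @return `path` invisibly (writer); a `synthetic_truth` (reader).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(list(planted = truth$planted,
                            held_out = truth$held_out,
                            spec = unclass(truth$spec),
                            seed = truth$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(synthetic_spec, as.list(x$spec))
  structure(list(planted = x$planted, held_out = x$held_out,
                 spec = spec, seed = x$seed),
            class = "synthetic_truth")
}

#' Split the planted set into pseudo-pathways
#'
#' Partitions the planted set into `n_pathways` named groups; with a
#' positive `overlap_fraction`, each pathway additionally receives that
#' fraction of its size as random members drawn from the other pathways,
#' so membership may overlap (as real pathway annotations do).
#'
#' @param truth A `synthetic_truth`.
#' @param n_pathways Number of pathways (>= 1).
#' @param overlap_fraction Fraction in `[0, 1)` of each pathway's size
#'   borrowed from other pathways.
#' @param seed Integer seed.
#' @return Named list of character vectors whose union is the planted set.
#' @export
split_pathways <- function(truth, n_pathways, overlap_fraction = 0,
                           seed = 1L) {
  if (n_pathways < 1L) stop("n_pathways must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1)")
  set.seed(seed)
  planted <- truth$planted
  assign <- rep_len(seq_len(n_pathways), length(planted))
  parts <- split(sample(planted), assign)
  names(parts) <- sprintf("pathway_%02d", seq_len(n_pathways))
  if (overlap_fraction > 0 && n_pathways > 1L) {
    for (p in names(parts)) {
      others <- setdiff(planted, parts[[p]])
      k <- min(floor(overlap_fraction * length(parts[[p]])), length(others))
      if (k > 0) parts[[p]] <- sort(c(parts[[p]], sample(others, k)))
    }
  }
  lapply(parts, sort)
}
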