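#' Rank unlabeled proteins as new candidates
#'
#' Trains the classifier on the full labeled table (seed set vs all
#' remaining nodes) and returns every non-positive node whose posterior
#' probability exceeds the threshold, sorted by descending posterior.
#' The full-data model uses the global RNR: no held-out evaluation is
#' claimed for the candidate list, so there is no leakage concern here.
#'
#' @param network The `igraph` interaction network.
#' @param annotation A `gene_set_annotation`.
#' @param kind Model kind; see [train_model()].
#' @param seed Integer seed for training.
#' @param threshold Posterior cutoff in `(0, 1)`, default 0.5.
#' @param ... Passed to [train_model()].
#' @return A `data.frame` with columns `id`, `degree`, `k_core`, `rnr`,
#'   `posterior_probability`, sorted by descending posterior (ties broken
#'   by id so reruns are byte-identical). Attributes `seed`, `kind` and
#'   `threshold` record provenance.
#' @export
predict_candidates <- function(network, annotation, kind = "svm_rbf",
                               seed = 1L, threshold = 0.5, ...) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)")
  tab <- build_feature_table(network, annotation)
  model <- train_model(tab, kind = kind, seed = seed, ...)
  unlabeled <- tab[tab$label == "negative", , drop = FALSE]
  prob <- posterior(model, unlabeled)
  out <- data.frame(id = unlabeled$id, degree = unlabeled$degree,
                    k_core = unlabeled$k_core, rnr = unlabeled$rnr,
                    posterior_probability = prob,
                    stringsAsFactors = FALSE)
  out <- out[out$posterior_probability > threshold, , drop = FALSE]
  out <- out[order(-out$posterior_probability, out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "kind") <- kind
  attr(out, "threshold") <- threshold
  out
}

#' Write a candidate report as TSV
#'
#' Columns (id, degree, k_core, rnr, posterior_probability); rnr and
#' posterior printed to 4 decimal places, rows sorted by descending
#' posterior.
#'
#' @param candidates Output of [predict_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  out <- candidates
  out$rnr <- sprintf("%.4f", out$rnr)
  out$posterior_probability <- sprintf("%.4f", out$posterior_probability)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-validate a classifier for a single pathway
#'
#' Uses the pathway's members as positives and every other network node as
#' a negative, with the same CV machinery as the full seed set. Pathways
#' with fewer than 30 members yield a `small_positive_set` flag in the
#' report: with so few positives drowned in thousands of negatives,
#' per-pathway prediction is expected to perform poorly.
#'
#' @param network The `igraph` interaction network.
#' @param annotation A `gene_set_annotation` with pathways.
#' @param pathway Pathway name.
#' @param ... Passed to [cross_validate()] (e.g. `n_folds`, `seed`,
#'   `rnr_policy`).
#' @return An `evaluation_report` with an extra `pathway` field and, when
#'   applicable, a `small_positive_set` flag.
#' @export
per_pathway_classifier <- function(network, annotation, pathway, ...) {
  if (is.null(annotation$pathways) || !pathway %in% names(annotation$pathways))
    stop("unknown pathway: ", pathway)
  members <- intersect(annotation$pathways[[pathway]],
                       igraph::V(network)$name)
  sub <- gene_set_annotation(members)
  report <- cross_validate(network, sub, ...)
  report$pathway <- pathway
  if (length(members) < 30L)
    report$pooled$flags <- c(report$pooled$flags, "small_positive_set")
  report
}
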