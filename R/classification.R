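FEATURE_COLS <- c("degree", "k_core", "rnr")

#' Fit a per-feature [-1, 1] scaling map
#'
#' Records the observed min and max of each feature on the fitting data.
#' The affine map `x -> 2 (x - min) / (max - min) - 1` sends the observed
#' min to -1 and max to +1; a constant feature maps to 0. Applying a fitted
#' map to out-of-range test values may exceed `[-1, 1]`; this is the
#' intended consequence of fitting on training data only.
#'
#' @param table A feature table (or any data frame with columns `degree`,
#'   `k_core`, `rnr`).
#' @return An object of class `scaling_params`.
#' @export
fit_scaling <- function(table) {
  if (nrow(table) < 1L) stop("need at least one row to fit scaling")
  p <- lapply(FEATURE_COLS, function(f)
    c(min = min(table[[f]]), max = max(table[[f]])))
  names(p) <- FEATURE_COLS
  structure(p, class = "scaling_params")
}

#' Apply a fitted scaling map
#'
#' @param params A `scaling_params` object from [fit_scaling()].
#' @param table Data frame with the feature columns.
#' @return Numeric matrix of scaled features, one column per feature.
#' @export
apply_scaling <- function(params, table) {
  m <- vapply(FEATURE_COLS, function(f) {
    lo <- params[[f]]["min"]; hi <- params[[f]]["max"]
    x <- as.numeric(table[[f]])
    if (hi > lo) 2 * (x - lo) / (hi - lo) - 1 else rep(0, length(x))
  }, numeric(nrow(table)))
  if (nrow(table) == 1L) m <- matrix(m, nrow = 1L, dimnames = list(NULL, FEATURE_COLS))
  m
}

#' Train a classifier on a labeled feature table
#'
#' Scales features to `[-1, 1]` (fitted on this data) and fits the chosen
#' model. The SVM kinds use LIBSVM (via \pkg{e1071}) at its default cost
#' and gamma; `svm_rbf` is the default, as the radial-basis kernel performs
#' best for this task. Posterior calibration is a sigmoid (Platt) fit on
#' decision values by default; an equal-width binning calibrator is the
#' alternative, and `"none"` disables calibration (posteriors then error).
#'
#' @param table Labeled feature table; both classes must be present.
#' @param kind `"svm_rbf"`, `"svm_poly"`, or `"decision_tree"`.
#' @param seed Integer seed; training is deterministic given it.
#' @param calibration `"sigmoid"` (default), `"binning"`, or `"none"`.
#' @param n_bins Bin count for the binning calibrator.
#' @param ... Passed to the underlying fitting function
#'   ([e1071::svm()] or [rpart::rpart()]), e.g. `cost`, `gamma`,
#'   `class.weights`.
#' @return An object of class `trained_model` embedding the scaling and
#'   calibration parameters.
#' @export
train_model <- function(table, kind = c("svm_rbf", "svm_poly", "decision_tree"),
                        seed = 1L, calibration = c("sigmoid", "binning", "none"),
                        n_bins = 10L, ...) {
  kind <- match.arg(kind)
  calibration <- match.arg(calibration)
  if (nlevels(droplevels(table$label)) < 2L)
    stop("training data must contain both classes")
  scaling <- fit_scaling(table)
  x <- apply_scaling(scaling, table)
  y <- factor(table$label, levels = c("negative", "positive"))
  set.seed(seed)
  model <- list(kind = kind, scaling = scaling, calibration = calibration,
                seed = seed)
  if (kind == "decision_tree") {
    df <- data.frame(x, label = y)
    model$fit <- rpart::rpart(label ~ degree + k_core + rnr, data = df,
                              method = "class", ...)
  } else {
    kernel <- if (kind == "svm_rbf") "radial" else "polynomial"
    model$fit <- e1071::svm(x = x, y = y, kernel = kernel, scale = FALSE,
                            probability = (calibration == "sigmoid"), ...)
    dv <- decision_values(model$fit, x)
    # LIBSVM's decision-value sign depends on class encounter order; store
    # the orientation that scores positives higher
    model$flip <- mean(dv[y == "positive"]) < mean(dv[y == "negative"])
    if (model$flip) dv <- -dv
    if (calibration == "binning")
      model$bins <- fit_binning_calibrator(dv, y == "positive", n_bins)
  }
  structure(model, class = "trained_model")
}

decision_values <- function(fit, x) {
  p <- stats::predict(fit, x, decision.values = TRUE)
  as.numeric(attr(p, "decision.values"))
}

# Equal-width binning calibrator: posterior for a decision value is the
# Laplace-smoothed positive fraction of its training bin.
fit_binning_calibrator <- function(dv, is_pos, n_bins) {
  edges <- seq(min(dv), max(dv), length.out = n_bins + 1L)
  if (edges[1L] == edges[n_bins + 1L]) edges <- edges[1L] + c(-0.5, 0.5)
  idx <- findInterval(dv, edges, rightmost.closed = TRUE, all.inside = TRUE)
  nb <- length(edges) - 1L
  n <- tabulate(idx, nbins = nb)
  npos <- tabulate(idx[is_pos], nbins = nb)
  list(edges = edges, prob = (npos + 1) / (n + 2))
}

#' Posterior probabilities for feature rows
#'
#' Maps rows through the model's stored scaling and returns the calibrated
#' probability of the positive class. The larger the posterior, the more
#' likely the protein belongs to the seed class. For the default sigmoid
#' calibration the posterior is monotone in the SVM decision value.
#'
#' @param model A `trained_model`.
#' @param rows Data frame with the feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
posterior <- function(model, rows) {
  if (model$calibration == "none" && model$kind != "decision_tree")
    stop("model was trained without calibration; posteriors unavailable")
  x <- apply_scaling(model$scaling, rows)
  if (model$kind == "decision_tree") {
    p <- stats::predict(model$fit, data.frame(x), type = "prob")[, "positive"]
    return(as.numeric(p))
  }
  if (model$calibration == "sigmoid") {
    pred <- stats::predict(model$fit, x, probability = TRUE)
    return(as.numeric(attr(pred, "probabilities")[, "positive"]))
  }
  dv <- decision_values(model$fit, x)
  if (isTRUE(model$flip)) dv <- -dv
  idx <- findInterval(dv, model$bins$edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  model$bins$prob[idx]
}

#' Midrank (Mann-Whitney) AUC
#'
#' `AUC = U / (n_pos * n_neg)` with tied scores receiving midranks; equals
#' the fraction of (positive, negative) pairs ranked correctly, counting
#' ties as one half.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical, or factor with level `"positive"`, marking the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_midrank <- function(scores, labels) {
  if (is.factor(labels) || is.character(labels)) labels <- labels == "positive"
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC needs at least one positive and one negative")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision, recall, F1 and AUC from confusion counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. Degenerate cases
#' (no predicted positives, or TP = 0) report 0 with an explicit flag
#' rather than NaN.
#'
#' @param tp,fp,tn,fn Nonnegative confusion counts.
#' @param scores Optional numeric scores for AUC.
#' @param labels Optional labels matching `scores`.
#' @return List with `tp`, `fp`, `tn`, `fn`, `precision`, `recall`, `f1`,
#'   `auc` (NA without scores), and `flags`.
#' @export
compute_metrics <- function(tp, fp, tn, fn, scores = NULL, labels = NULL) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  flags <- character()
  if (tp + fp == 0L) {
    precision <- 0
    flags <- c(flags, "no_predicted_positives")
  } else precision <- tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  if (tp == 0L) {
    f1 <- 0
    flags <- c(flags, "zero_true_positives")
  } else f1 <- 2 * precision * recall / (precision + recall)
  auc <- if (!is.null(scores)) auc_midrank(scores, labels) else NA_real_
  list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
       fn = as.integer(fn), precision = precision, recall = recall,
       f1 = f1, auc = auc, flags = flags)
}

#' Stratified k-fold cross-validation of the candidate classifier
#'
#' Folds are stratified by label so every fold holds positives even with a
#' 1:100 class imbalance. The RNR feature depends on the positive labels,
#' so under the default `rnr_policy = "per_fold"` it is recomputed inside
#' every fold using only training-fold positives (test rows score their
#' neighbors against training-fold positives only) — an honest evaluation
#' with no test-label leakage. `rnr_policy = "global"` computes RNR once
#' from all labels, the protocol a single full-network feature table
#' implies; both policies are recorded in the report.
#'
#' @param network The `igraph` interaction network.
#' @param annotation A `gene_set_annotation`.
#' @param kind Model kind; see [train_model()].
#' @param n_folds Number of folds (default 5, i.e. 20 percent held out per
#'   round).
#' @param seed Integer seed for fold assignment and model training.
#' @param rnr_policy `"per_fold"` (default) or `"global"`.
#' @param threshold Posterior cutoff for confusion counts (default 0.5).
#' @param calibration Passed to [train_model()].
#' @param ... Passed to [train_model()].
#' @return An object of class `evaluation_report`: per-fold confusion
#'   counts and metrics, pooled metrics from summed counts, pooled AUC over
#'   all held-out posteriors, and the seed/policy provenance.
#' @export
cross_validate <- function(network, annotation,
                           kind = c("svm_rbf", "svm_poly", "decision_tree"),
                           n_folds = 5L, seed = 1L,
                           rnr_policy = c("per_fold", "global"),
                           threshold = 0.5, calibration = "sigmoid", ...) {
  kind <- match.arg(kind)
  rnr_policy <- match.arg(rnr_policy)
  nodes <- igraph::V(network)$name
  positives <- intersect(annotation$positives, nodes)
  negatives <- setdiff(nodes, positives)
  if (length(positives) < n_folds || length(negatives) < n_folds)
    stop("need at least n_folds samples of each class for stratified folds")

  set.seed(seed)
  fold_of <- stats::setNames(integer(length(nodes)), nodes)
  fold_of[sample(positives)] <- rep_len(seq_len(n_folds), length(positives))
  fold_of[sample(negatives)] <- rep_len(seq_len(n_folds), length(negatives))

  base <- data.frame(id = nodes,
                     degree = as.integer(compute_degrees(network)),
                     k_core = as.integer(kcore_decomposition(network)),
                     stringsAsFactors = FALSE)
  base$label <- factor(ifelse(base$id %in% positives, "positive", "negative"),
                       levels = c("negative", "positive"))
  if (rnr_policy == "global")
    rnr_global <- compute_rnr(network, positives)

  fold_rows <- vector("list", n_folds)
  rnr_seed_sets <- vector("list", n_folds)
  predictions <- vector("list", n_folds)
  counts <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  for (k in seq_len(n_folds)) {
    test_ids <- nodes[fold_of == k]
    train_pos <- setdiff(positives, test_ids)
    rnr_seed_sets[[k]] <- if (rnr_policy == "per_fold") train_pos else positives
    tab <- base
    tab$rnr <- if (rnr_policy == "global") as.numeric(rnr_global[tab$id])
               else as.numeric(compute_rnr(network, train_pos)[tab$id])
    train_tab <- tab[!(tab$id %in% test_ids), , drop = FALSE]
    test_tab <- tab[tab$id %in% test_ids, , drop = FALSE]
    model <- train_model(train_tab, kind = kind, seed = seed + k,
                         calibration = calibration, ...)
    prob <- posterior(model, test_tab)
    is_pos <- test_tab$label == "positive"
    pred_pos <- prob >= threshold
    tp <- sum(pred_pos & is_pos); fp <- sum(pred_pos & !is_pos)
    tn <- sum(!pred_pos & !is_pos); fn <- sum(!pred_pos & is_pos)
    counts <- counts + c(tp = tp, fp = fp, tn = tn, fn = fn)
    m <- compute_metrics(tp, fp, tn, fn, scores = prob,
                         labels = as.character(test_tab$label))
    fold_rows[[k]] <- data.frame(fold = k, tp = tp, fp = fp, tn = tn, fn = fn,
                                 precision = m$precision, recall = m$recall,
                                 f1 = m$f1, auc = m$auc)
    predictions[[k]] <- data.frame(id = test_tab$id, fold = k,
                                   posterior = prob,
                                   label = as.character(test_tab$label),
                                   stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, predictions)
  pooled <- compute_metrics(counts["tp"], counts["fp"], counts["tn"],
                            counts["fn"], scores = predictions$posterior,
                            labels = predictions$label)
  structure(list(folds = do.call(rbind, fold_rows), pooled = pooled,
                 kind = kind, n_folds = n_folds, seed = seed,
                 rnr_policy = rnr_policy, threshold = threshold,
                 calibration = calibration,
                 fold_assignment = fold_of,
                 rnr_seed_sets = rnr_seed_sets,
                 predictions = predictions),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, model %s, rnr_policy %s, seed %d\n",
              x$n_folds, x$kind, x$rnr_policy, x$seed))
  cat(sprintf("pooled: precision %.3f, recall %.3f, F1 %.3f, AUC %.3f\n",
              x$pooled$precision, x$pooled$recall, x$pooled$f1, x$pooled$auc))
  if (length(x$pooled$flags))
    cat("flags:", paste(x$pooled$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report as JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
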