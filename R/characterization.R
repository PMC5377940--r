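#' Two-sample Kolmogorov-Smirnov test
#'
#' Computes `D`, the supremum over all pooled sample points of the absolute
#' difference of the two empirical CDFs, and an asymptotic p-value from the
#' Kolmogorov distribution evaluated at `sqrt(n_eff) * D` with
#' `n_eff = n1 * n2 / (n1 + n2)`. Evaluating the CDFs at the pooled sorted
#' sample points handles ties exactly; the statistic is symmetric in the
#' two samples. An exact small-sample p-value (tie-free samples only) is
#' available via `exact = TRUE`.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param exact Use the exact null distribution of D (delegates to
#'   [stats::psmirnov()]); default `FALSE`, the asymptotic formula the
#'   large-sample comparisons use.
#' @return An object of class `ks_result`: list with `D`, `p_value`, `n1`,
#'   `n2`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  pooled <- sort(unique(c(x, y)))
  F1 <- stats::ecdf(x)(pooled)
  F2 <- stats::ecdf(y)(pooled)
  D <- max(abs(F1 - F2))
  n1 <- length(x); n2 <- length(y)
  if (exact) {
    p <- 1 - stats::psmirnov(D, sizes = c(n1, n2), two.sided = TRUE)
  } else {
    n_eff <- n1 * n2 / (n1 + n2)
    p <- ks_asymptotic_p(sqrt(n_eff) * D)
  }
  structure(list(D = D, p_value = min(max(p, .Machine$double.xmin), 1),
                 n1 = n1, n2 = n2),
            class = "ks_result")
}

# Complementary CDF of the Kolmogorov distribution,
# Q(lambda) = 2 * sum_{j>=1} (-1)^(j-1) exp(-2 j^2 lambda^2)
ks_asymptotic_p <- function(lambda) {
  if (lambda < 1e-10) return(1)
  j <- seq_len(100L)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.3g (n1 = %d, n2 = %d)\n",
              x$D, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Per-group feature summaries
#'
#' One summary row per pathway, plus rows for the whole positive set and the
#' background. Pathways smaller than `min_group_size` are listed with their
#' size but their means are suppressed (`NA`), mirroring the convention of
#' excluding tiny pathways from averaged comparisons.
#'
#' @param table Feature table from [build_feature_table()].
#' @param annotation A `gene_set_annotation` (pathways optional).
#' @param min_group_size Smallest pathway size whose means are reported
#'   (default 4).
#' @return A `data.frame` with columns `group`, `size`, `mean_degree`,
#'   `mean_kcore`, `mean_rnr`.
#' @export
summarize_groups <- function(table, annotation, min_group_size = 4L) {
  stopifnot(min_group_size >= 1L)
  one <- function(name, ids, suppress_small = TRUE) {
    rows <- table[table$id %in% ids, , drop = FALSE]
    n <- nrow(rows)
    if (n == 0L) return(NULL)
    if (suppress_small && n < min_group_size) {
      data.frame(group = name, size = n, mean_degree = NA_real_,
                 mean_kcore = NA_real_, mean_rnr = NA_real_)
    } else {
      data.frame(group = name, size = n,
                 mean_degree = mean(rows$degree),
                 mean_kcore = mean(rows$k_core),
                 mean_rnr = mean(rows$rnr))
    }
  }
  out <- list()
  if (!is.null(annotation$pathways))
    out <- lapply(names(annotation$pathways),
                  function(p) one(p, annotation$pathways[[p]]))
  pos_ids <- intersect(annotation$positives, table$id)
  neg_ids <- setdiff(table$id, pos_ids)
  out <- c(out, list(one("positives", pos_ids, suppress_small = FALSE),
                     one("negatives", neg_ids, suppress_small = FALSE)))
  res <- do.call(rbind, Filter(Negate(is.null), out))
  rownames(res) <- NULL
  res
}

#' Write a group-summary table as TSV (Class / Size / Degree / K-core / RNR)
#'
#' @param summary Output of [summarize_groups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_summary <- function(summary, path) {
  out <- data.frame(Class = summary$group, Size = summary$size,
                    Degree = ifelse(is.na(summary$mean_degree), "-",
                                    sprintf("%.2f", summary$mean_degree)),
                    K.core = ifelse(is.na(summary$mean_kcore), "-",
                                    sprintf("%.2f", summary$mean_kcore)),
                    RNR = ifelse(is.na(summary$mean_rnr), "-",
                                 sprintf("%.2f", summary$mean_rnr)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Overlap counts among named pathways
#'
#' Counts every region of the inclusion-exclusion partition of the named
#' sets (the regions of a Venn diagram).
#'
#' @param annotation A `gene_set_annotation` with pathways.
#' @param pathway_names Character vector of pathway names to intersect.
#' @return A `data.frame` with one row per non-empty region: a `membership`
#'   string like `"A&B"` and its exclusive `count`.
#' @export
pathway_overlap <- function(annotation, pathway_names) {
  if (is.null(annotation$pathways))
    stop("annotation has no pathway map")
  unknown <- setdiff(pathway_names, names(annotation$pathways))
  if (length(unknown))
    stop("unknown pathway name(s): ", paste(unknown, collapse = ", "))
  sets <- annotation$pathways[pathway_names]
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  keys <- apply(member, 1L, function(m) paste(pathway_names[m], collapse = "&"))
  counts <- table(keys)
  data.frame(membership = names(counts), count = as.integer(counts),
             stringsAsFactors = FALSE)
}

#' Binned frequency distribution summing to 100 percent
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed, so edges
#' covering the data range partition it exactly.
#'
#' @param values Numeric sample.
#' @param bin_edges Strictly increasing numeric vector of edges covering the
#'   range of `values`.
#' @return A `data.frame` with `lo`, `hi`, and `percent` (summing to 100).
#' @export
binned_distribution <- function(values, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly increasing")
  lo <- bin_edges[1L]; hi <- bin_edges[length(bin_edges)]
  if (any(values < lo) || any(values > hi))
    stop("values outside the bin range [", lo, ", ", hi, "]")
  idx <- findInterval(values, bin_edges, rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  data.frame(lo = bin_edges[-length(bin_edges)],
             hi = bin_edges[-1L],
             percent = 100 * counts / length(values))
}
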