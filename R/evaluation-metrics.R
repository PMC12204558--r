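# Performance metrics: AUROC (Mann-Whitney form), the confusion-matrix panel
# (sensitivity, specificity, PPV, NPV, FPR, FNR), cross-fold aggregation with
# normal-approximation confidence intervals, and the cross-fold
# feature-stability summary (times selected, average rank).

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The fraction of (positive, negative) pairs in which the positive outscores
#' the negative, with ties counted one half; equivalently the rank-sum
#' statistic. Invariant under strictly monotone transformations of the
#' scores.
#'
#' @param scores numeric prediction scores (higher = more case-like).
#' @param labels binary labels (1/TRUE = positive).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as.integer(as.logical(labels))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Thresholded confusion-matrix metrics
#'
#' Computes the 2x2 table at `score >= threshold` and derives the panel.
#' Ratios with a zero denominator (e.g. PPV when nothing is predicted
#' positive) are returned as `NA` and are excluded, with a count, when folds
#' are aggregated - never silently substituted.
#'
#' @param scores prediction scores in \[0, 1\].
#' @param labels binary labels (1/TRUE = positive).
#' @param threshold classification cutoff on the score scale (default 0.5).
#' @return Named numeric vector: sensitivity, specificity, ppv, npv, fpr,
#'   fnr, plus tp/fp/fn/tn counts.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  y <- as.integer(as.logical(labels))
  if (length(unique(y)) < 2) stop("both classes must be present")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  c(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn),
    fpr = div(fp, fp + tn), fnr = div(fn, fn + tp),
    tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Aggregate per-fold metrics into a performance report
#'
#' Means across folds with 95% confidence intervals computed by the normal
#' approximation `mean +/- 1.96 * SD / sqrt(n_folds)`. Undefined per-fold
#' values (`NA`) are excluded with their count recorded. Raw CI bounds are
#' retained; a display-clipped copy to \[0, 1\] is also provided.
#'
#' @param fold_metrics data.frame, one row per fold, one column per metric
#'   (e.g. auroc, sensitivity, ...).
#' @param set_label which evaluation set the folds describe
#'   (e.g. `"training"`, `"internal_test"`, `"external"`).
#' @return A `performance_report` data.frame with one row per metric:
#'   mean, ci_low, ci_high, ci_low_clipped, ci_high_clipped, n_folds,
#'   n_undefined, set_label.
#' @export
aggregate_folds <- function(fold_metrics, set_label = "internal_test") {
  stopifnot(is.data.frame(fold_metrics), nrow(fold_metrics) >= 2)
  rows <- lapply(names(fold_metrics), function(m) {
    v <- fold_metrics[[m]]
    ok <- !is.na(v)
    mu <- mean(v[ok])
    half <- if (sum(ok) >= 2) 1.96 * stats::sd(v[ok]) / sqrt(sum(ok)) else NA_real_
    data.frame(metric = m, mean = mu, ci_low = mu - half, ci_high = mu + half,
               ci_low_clipped = max(mu - half, 0),
               ci_high_clipped = min(mu + half, 1),
               n_folds = sum(ok), n_undefined = sum(!ok),
               set_label = set_label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("performance_report", "data.frame")
  out
}

#' Cross-fold feature-stability summary
#'
#' Given the per-iteration selections (SAS traces, or internal-selection
#' reports from the elastic net / random forest), counts how many outer
#' iterations admitted each feature and averages its selection rank over
#' those iterations. Features never selected are absent.
#'
#' @param selections list of data.frames with columns `feature` and `rank`
#'   (a `sas_trace$selected`, or an [internal_selection_report()] restricted
#'   to selected features).
#' @return data.frame: feature, times_selected, average_rank, sorted by
#'   (times_selected desc, average_rank asc).
#' @export
stability_summary <- function(selections) {
  stopifnot(length(selections) >= 1)
  rows <- do.call(rbind, lapply(selections, function(s) {
    if (inherits(s, "sas_trace")) s <- s$selected
    stopifnot(all(c("feature", "rank") %in% names(s)))
    s[, c("feature", "rank")]
  }))
  if (is.null(rows) || !nrow(rows))
    return(data.frame(feature = character(0), times_selected = integer(0),
                      average_rank = numeric(0)))
  agg <- stats::aggregate(rank ~ feature, data = rows,
                          FUN = function(r) c(n = length(r), mean = mean(r)))
  out <- data.frame(feature = agg$feature,
                    times_selected = as.integer(agg$rank[, "n"]),
                    average_rank = agg$rank[, "mean"],
                    stringsAsFactors = FALSE)
  out[order(-out$times_selected, out$average_rank, out$feature), ,
      drop = FALSE]
}

#' Overlap of feature sets across selection methods
#'
#' Computes the pairwise and three-way intersections used to compare the
#' stepwise selector with the internal selections of the elastic net and the
#' random forest.
#'
#' @param sets named list of character vectors of feature ids.
#' @return List with per-set sizes, all pairwise intersection sizes, the
#'   common intersection, and the union size.
#' @export
selection_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  nm <- names(sets)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  list(sizes = vapply(sets, length, integer(1)),
       pairwise = stats::setNames(
         vapply(pairs, function(p) length(intersect(sets[[p[1]]], sets[[p[2]]])),
                integer(1)),
         vapply(pairs, paste, character(1), collapse = " & ")),
       common = Reduce(intersect, sets),
       union_size = length(Reduce(union, sets)))
}
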