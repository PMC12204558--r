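# Per-subject feature space (T1, T2, dT and within-gene interactions) and the
# stepwise additive selection (SAS) algorithm: greedy forward selection of
# logistic-regression features scored by nested cross-validated AUROC with an
# epsilon admission threshold and a patience-based stop.

#' Build the per-subject feature matrix for a set of genes
#'
#' Each gene contributes three base features per subject: the log2 intensity
#' at T1, at T2, and the within-subject trajectory dT = T2 - T1. Interaction
#' candidates are the within-gene pairwise products (T1*T2, T1*dT, T2*dT),
#' flagged `kind = "interaction"`; base and interaction candidates both enter
#' the selection candidate pool, with admissions of interactions capped
#' separately.
#'
#' @param study an [expression_study()].
#' @param genes genes to expand (must be present in the study).
#' @param interactions include within-gene interaction candidates
#'   (default TRUE).
#' @return An object of class `feature_matrix`: `X` (subjects x features),
#'   `feature_meta` (feature, gene, kind, parents), `y` (1 = case, 0 =
#'   control), `subjects`.
#' @export
build_feature_matrix <- function(study, genes, interactions = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  missing <- setdiff(genes, rownames(study$expr))
  if (length(missing))
    stop("gene(s) absent from study: ", paste(missing, collapse = ", "))
  sheet <- study$sample_sheet
  subj <- study_subjects(study)
  i1 <- match(paste(subj$subject_id, "T1"), paste(sheet$subject_id, sheet$timepoint))
  i2 <- match(paste(subj$subject_id, "T2"), paste(sheet$subject_id, sheet$timepoint))
  T1 <- t(study$expr[genes, i1, drop = FALSE])
  T2 <- t(study$expr[genes, i2, drop = FALSE])
  dT <- T2 - T1
  ns <- nrow(subj)
  ng <- length(genes)
  base <- matrix(0, ns, 3L * ng)
  base[, seq(1L, 3L * ng, by = 3L)] <- T1
  base[, seq(2L, 3L * ng, by = 3L)] <- T2
  base[, seq(3L, 3L * ng, by = 3L)] <- dT
  base_names <- as.vector(rbind(paste0(genes, ".T1"), paste0(genes, ".T2"),
                                paste0(genes, ".dT")))
  colnames(base) <- base_names
  meta <- data.frame(
    feature = base_names,
    gene = rep(genes, each = 3L),
    kind = rep(c("T1", "T2", "dT"), ng),
    parents = NA_character_,
    stringsAsFactors = FALSE)
  X <- base
  if (interactions) {
    inter <- matrix(0, ns, 3L * ng)
    inter[, seq(1L, 3L * ng, by = 3L)] <- T1 * T2
    inter[, seq(2L, 3L * ng, by = 3L)] <- T1 * dT
    inter[, seq(3L, 3L * ng, by = 3L)] <- T2 * dT
    inter_names <- as.vector(rbind(paste0(genes, ".T1xT2"),
                                   paste0(genes, ".T1xdT"),
                                   paste0(genes, ".T2xdT")))
    colnames(inter) <- inter_names
    meta <- rbind(meta, data.frame(
      feature = inter_names,
      gene = rep(genes, each = 3L),
      kind = "interaction",
      parents = as.vector(rbind(paste0(genes, ".T1;", genes, ".T2"),
                                paste0(genes, ".T1;", genes, ".dT"),
                                paste0(genes, ".T2;", genes, ".dT"))),
      stringsAsFactors = FALSE))
    X <- cbind(base, inter)
  }
  rownames(X) <- subj$subject_id
  structure(list(X = X, feature_meta = meta,
                 y = as.integer(subj$outcome == "case"),
                 subjects = subj$subject_id),
            class = "feature_matrix")
}

#' Restrict a feature matrix to a subset of subjects
#' @param fm a [build_feature_matrix()] result.
#' @param subjects subject identifiers to keep.
#' @return A `feature_matrix` over the requested subjects.
#' @export
subset_features <- function(fm, subjects) {
  stopifnot(inherits(fm, "feature_matrix"))
  idx <- match(subjects, fm$subjects)
  if (anyNA(idx)) stop("unknown subject(s): ",
                       paste(subjects[is.na(idx)], collapse = ", "))
  structure(list(X = fm$X[idx, , drop = FALSE], feature_meta = fm$feature_meta,
                 y = fm$y[idx], subjects = fm$subjects[idx]),
            class = "feature_matrix")
}

#' Stepwise additive selection settings
#'
#' @param epsilon minimum nested-CV AUROC improvement for admission
#'   (default 0.015).
#' @param patience consecutive non-improving iterations before termination
#'   (default 3).
#' @param max_features cap on selected features (default 30).
#' @param max_interactions cap on admitted interaction terms (default 5).
#' @param inner_folds folds of the nested stratified cross-validation scoring
#'   each candidate (default 5).
#' @param max_candidates scored-candidate cap: when the pool is larger, it is
#'   screened once (on the supplied rows only) to the `max_candidates`
#'   features with the strongest single-feature AUROC before the iterative
#'   search; `Inf` disables screening. A runtime device for array-scale
#'   pools; the greedy search itself is unchanged.
#' @param seed seed for the inner fold draws.
#' @return An object of class `sas_config`.
#' @export
sas_config <- function(epsilon = 0.015, patience = 3, max_features = 30,
                       max_interactions = 5, inner_folds = 5,
                       max_candidates = Inf, seed = 1) {
  stopifnot(epsilon > 0, patience >= 1, max_features >= 1,
            max_interactions >= 0, inner_folds >= 2, max_candidates >= 1)
  max_interactions <- min(max_interactions, max_features)
  structure(list(epsilon = epsilon, patience = as.integer(patience),
                 max_features = as.integer(max_features),
                 max_interactions = as.integer(max_interactions),
                 inner_folds = as.integer(inner_folds),
                 max_candidates = max_candidates, seed = as.integer(seed)),
            class = "sas_config")
}

#' Nested cross-validated AUROC of a candidate feature addition
#'
#' Scores the model "current features + candidate": for each stratified inner
#' fold, an unregularized logistic regression is fitted on the inner-training
#' rows (features standardized with inner-training statistics only) and the
#' AUROC is computed on the inner-validation rows; the fold AUROCs are
#' averaged.
#'
#' @param X_current numeric matrix (possibly zero columns) of the current
#'   model's feature columns.
#' @param candidate numeric vector, the candidate feature column.
#' @param y binary outcome (1 = case).
#' @param fold_ids integer fold assignment (from [stratified_fold_ids()]).
#' @return Mean validation AUROC across the inner folds.
#' @export
inner_cv_auroc <- function(X_current, candidate, y, fold_ids) {
  X <- cbind(X_current, candidate)
  k <- max(fold_ids)
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    val <- fold_ids == f
    if (length(unique(y[!val])) < 2 || length(unique(y[val])) < 2)
      stop("inner fold with a single class; use stratified folds")
    st <- col_stats(X[!val, , drop = FALSE])
    Xtr <- apply_stats(X[!val, , drop = FALSE], st)
    Xva <- apply_stats(X[val, , drop = FALSE], st)
    beta <- fast_logit(Xtr, y[!val])
    aucs[f] <- auroc(fast_logit_predict(beta, Xva), y[val])
  }
  mean(aucs)
}

# Batch scorer used by sas_select: numerically identical to calling
# inner_cv_auroc() per candidate, but standardizes the candidate block once
# per inner fold instead of once per candidate.
score_candidates <- function(X, selected, cand, y, fold_ids) {
  k <- max(fold_ids)
  acc <- numeric(length(cand))
  cols <- c(selected, cand)
  ns <- length(selected)
  for (f in seq_len(k)) {
    val <- fold_ids == f
    st <- col_stats(X[!val, cols, drop = FALSE])
    Ztr <- apply_stats(X[!val, cols, drop = FALSE], st)
    Zva <- apply_stats(X[val, cols, drop = FALSE], st)
    ytr <- y[!val]
    yva <- y[val]
    cur_tr <- Ztr[, seq_len(ns), drop = FALSE]
    cur_va <- Zva[, seq_len(ns), drop = FALSE]
    for (j in seq_along(cand)) {
      beta <- fast_logit(cbind(cur_tr, Ztr[, ns + j]), ytr)
      acc[j] <- acc[j] + auroc(fast_logit_predict(beta, cbind(cur_va, Zva[, ns + j])), yva)
    }
  }
  stats::setNames(acc / k, cand)
}

# Single-feature discrimination screen: |AUROC - 0.5| per column, computed on
# the supplied rows, used only to cap the scored candidate pool.
screen_candidates <- function(X, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  auc <- apply(X, 2, function(col) {
    r <- rank(col)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  })
  abs(auc - 0.5)
}

#' Stepwise additive feature selection
#'
#' Greedy forward selection starting from an empty logistic-regression model
#' (whose AUROC is defined as 0.5). At each iteration every remaining
#' candidate is scored by [inner_cv_auroc()]; the top scorer is admitted iff
#' its score improves on the current model's recorded score by at least
#' `epsilon` (ties broken by higher score then lexicographic feature id).
#' After a non-improving iteration the inner folds are re-drawn (otherwise
#' repeating the evaluation could never change the outcome) and a no-change
#' counter is incremented; selection stops after `patience` consecutive
#' non-improving iterations, when `max_features` features are selected, or
#' when the candidate pool is exhausted. Admissions of interaction terms are
#' capped at `max_interactions`; once the cap is reached interaction
#' candidates are skipped.
#'
#' @param features a [build_feature_matrix()] result (training rows only).
#' @param config a [sas_config()].
#' @return An object of class `sas_trace`: `iterations` (data.frame with
#'   iteration, candidate set size, best candidate, best score, gain,
#'   admitted), `selected` (data.frame with feature, rank, score at
#'   admission), `termination_reason` (`"patience"`, `"max_features"`, or
#'   `"exhausted"`).
#' @export
sas_select <- function(features, config = sas_config()) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(config, "sas_config"))
  y <- features$y
  if (sum(y == 1) < 2 || sum(y == 0) < 2)
    stop("need at least 2 subjects per class")
  X <- features$X
  meta <- features$feature_meta
  pool <- colnames(X)
  if (is.finite(config$max_candidates) &&
      length(pool) > config$max_candidates) {
    sc <- screen_candidates(X, y)
    pool <- pool[order(sc, decreasing = TRUE)][seq_len(config$max_candidates)]
  }
  is_inter <- structure(meta$kind == "interaction", names = meta$feature)
  selected <- character(0)
  sel_scores <- numeric(0)
  current_score <- 0.5
  n_inter <- 0L
  fails <- 0L
  it <- 0L
  fold_draw <- 0L
  fold_ids <- stratified_fold_ids(y, config$inner_folds,
                                  derive_seed(config$seed, "sas_folds_0"))
  iter_rows <- list()
  termination <- NULL
  while (TRUE) {
    cand <- setdiff(pool, selected)
    if (n_inter >= config$max_interactions) cand <- cand[!is_inter[cand]]
    if (!length(cand)) {
      termination <- "exhausted"
      break
    }
    it <- it + 1L
    scores <- score_candidates(X, selected, cand, y, fold_ids)
    # tie-break: higher score, then lexicographic feature id
    ord <- order(-scores, cand)
    best <- cand[ord[1]]
    best_score <- scores[ord[1]]
    gain <- best_score - current_score
    admitted <- gain >= config$epsilon
    iter_rows[[it]] <- data.frame(
      iteration = it, n_candidates = length(cand), best_candidate = best,
      best_score = best_score, gain = gain, admitted = admitted,
      stringsAsFactors = FALSE)
    if (admitted) {
      selected <- c(selected, best)
      sel_scores <- c(sel_scores, best_score)
      current_score <- best_score
      if (is_inter[best]) n_inter <- n_inter + 1L
      fails <- 0L
      if (length(selected) >= config$max_features) {
        termination <- "max_features"
        break
      }
    } else {
      fails <- fails + 1L
      if (fails >= config$patience) {
        termination <- "patience"
        break
      }
      fold_draw <- fold_draw + 1L
      fold_ids <- stratified_fold_ids(
        y, config$inner_folds,
        derive_seed(config$seed, paste0("sas_folds_", fold_draw)))
    }
  }
  iterations <- if (length(iter_rows)) do.call(rbind, iter_rows) else
    data.frame(iteration = integer(0), n_candidates = integer(0),
               best_candidate = character(0), best_score = numeric(0),
               gain = numeric(0), admitted = logical(0))
  structure(list(
    iterations = iterations,
    selected = data.frame(feature = selected,
                          rank = seq_along(selected),
                          score = sel_scores, stringsAsFactors = FALSE),
    termination_reason = termination), class = "sas_trace")
}

#' @export
print.sas_trace <- function(x, ...) {
  cat("sas_trace:", nrow(x$selected), "feature(s) selected in",
      nrow(x$iterations), "iteration(s); termination:",
      x$termination_reason, "\n")
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}
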