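# End-to-end experiment driver: repeated stratified subject-level fold plans,
# leakage-safe vs leakage-prone execution of the filtering / differential
# expression / feature-selection / model-training cascade, the permuted-label
# overfitting control, external validation, and study / report serialization.

#' Repeated stratified fold plan at the subject level
#'
#' Partitions subjects into `k` folds, `repeats` times, stratified by class so
#' every fold's class counts are within one subject of proportional. The
#' default 2 x 5 plan yields ten outer iterations.
#'
#' @param outcomes named character vector (`"case"`/`"control"`), one entry
#'   per subject, names = subject ids; or an [expression_study()].
#' @param repeats number of independent repeats (default 2).
#' @param k folds per repeat (default 5).
#' @param seed seed for the shuffles.
#' @return An object of class `fold_plan`: `assignments` is a list of named
#'   integer vectors (fold index per subject), one per repeat.
#' @export
make_folds <- function(outcomes, repeats = 2, k = 5, seed = 1) {
  if (inherits(outcomes, "expression_study")) {
    subj <- study_subjects(outcomes)
    outcomes <- stats::setNames(subj$outcome, subj$subject_id)
  }
  stopifnot(!is.null(names(outcomes)), k >= 2, repeats >= 1)
  cls_sizes <- table(outcomes)
  if (any(cls_sizes < k))
    stop("class smaller than k: ",
         paste(names(cls_sizes)[cls_sizes < k], collapse = ", "))
  y <- as.integer(outcomes == "case")
  assignments <- lapply(seq_len(repeats), function(r) {
    ids <- stratified_fold_ids(y, k, derive_seed(seed, paste0("foldrep", r)))
    stats::setNames(ids, names(outcomes))
  })
  structure(list(repeats = as.integer(repeats), k = as.integer(k),
                 seed = as.integer(seed), assignments = assignments,
                 outcomes = outcomes),
            class = "fold_plan")
}

# Expand a fold plan into its outer iterations.
plan_iterations <- function(plan) {
  out <- list()
  for (r in seq_len(plan$repeats)) {
    a <- plan$assignments[[r]]
    for (f in seq_len(plan$k)) {
      out[[length(out) + 1L]] <- list(
        rep = r, fold = f,
        train = names(a)[a != f], test = names(a)[a == f])
    }
  }
  out
}

#' Pipeline configuration
#'
#' @param leakage_mode `"safe"` (filtering, DE and gene selection computed on
#'   each training partition only) or `"prone"` (computed once on the full
#'   cohort before splitting, reproducing the leakage failure mode in which
#'   differential expression precedes the train/test split).
#' @param permute if TRUE, subject-level label permutation is applied before
#'   everything (the overfitting control).
#' @param filter a [filter_config()].
#' @param sas a [sas_config()].
#' @param families model families to run, subset of
#'   `c("LR", "LR_reg", "LR_ELN", "RF", "MLP")`.
#' @param sas_families families consuming the stepwise-selected features; the
#'   remaining families consume the post-DE base feature space directly (the
#'   elastic net and random forest have internal feature selection and are
#'   fitted after differential expression but before formal feature
#'   selection).
#' @param alpha DE selection threshold.
#' @param de_criterion `"p_adj"` (BH, default) or `"p"` (lenient raw-p
#'   screen; see [select_de_genes()]).
#' @param prone_scope in prone mode, whether only the DE stage leaks
#'   (`"de_only"`, default) or the stepwise selection is also computed once on
#'   the full cohort (`"de_and_sas"`).
#' @param max_de_features optional cap on the post-DE base feature count
#'   (kept in order of smallest minimum p across contrasts); a runtime device
#'   for model families whose cost grows with feature count.
#' @param model_args named list of extra arguments passed to [model_config()]
#'   per family (e.g. `list(MLP = list(search_budget = 6))`).
#' @param seed root seed; all fold draws, permutations and stochastic fits
#'   derive child streams from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(leakage_mode = c("safe", "prone"),
                            permute = FALSE,
                            filter = filter_config(),
                            sas = sas_config(max_candidates = 60),
                            families = "LR",
                            sas_families = c("LR", "LR_reg", "MLP"),
                            alpha = 0.05,
                            de_criterion = c("p_adj", "p"),
                            prone_scope = c("de_only", "de_and_sas"),
                            max_de_features = Inf,
                            model_args = list(),
                            seed = 1) {
  leakage_mode <- match.arg(leakage_mode)
  de_criterion <- match.arg(de_criterion)
  prone_scope <- match.arg(prone_scope)
  stopifnot(all(families %in% MODEL_FAMILIES), length(families) >= 1,
            inherits(filter, "filter_config"), inherits(sas, "sas_config"))
  structure(list(leakage_mode = leakage_mode, permute = permute,
                 filter = filter, sas = sas, families = families,
                 sas_families = sas_families, alpha = alpha,
                 de_criterion = de_criterion, prone_scope = prone_scope,
                 max_de_features = max_de_features,
                 model_args = model_args, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Order genes by their minimum p across contrasts and cap the base feature
# count at config$max_de_features (3 base features per gene).
cap_de_genes <- function(genes, de_table, max_features) {
  if (!is.finite(max_features) || length(genes) * 3 <= max_features)
    return(genes)
  minp <- tapply(de_table$p, de_table$gene, min)
  genes[order(minp[genes])][seq_len(max(1L, floor(max_features / 3)))]
}

metric_row <- function(scores, y, threshold = 0.5) {
  cm <- confusion_metrics(scores, y, threshold)
  c(auroc = auroc(scores, y), cm[c("sensitivity", "specificity", "ppv",
                                   "npv", "fpr", "fnr")])
}

degenerate_row <- function(y) {
  # constant no-skill classifier: score 0.5 for everyone
  metric_row(rep(0.5, length(y)), y)
}

#' Run the end-to-end cross-validated prediction experiment
#'
#' For every outer iteration of the fold plan the cascade is: gene filtering
#' -> consensus correlation -> moderated differential expression -> gene
#' selection -> per-subject feature construction -> stepwise additive
#' selection -> model training; each trained family is scored on the training
#' partition, the held-out partition, and (when supplied) the external
#' cohort. In `"safe"` mode the entire cascade up to model training sees the
#' training partition only; in `"prone"` mode filtering, differential
#' expression and gene selection are computed once on all subjects (and, with
#' `prone_scope = "de_and_sas"`, the stepwise selection too), after which the
#' same cross-validation loop runs - the only difference is which rows inform
#' preprocessing and selection. Iterations in which no gene or no feature is
#' selected are recorded as degenerate (constant classifier, AUROC 0.5) and
#' the run continues.
#'
#' @param study the paired training cohort ([expression_study()]).
#' @param plan a [make_folds()] plan over the study's subjects.
#' @param config a [pipeline_config()].
#' @param external_study optional external cohort sharing the gene universe.
#' @return An object of class `experiment_report`: aggregated `performance`,
#'   per-iteration `fold_metrics`, `traces` (stepwise selection),
#'   `internal_selection` (elastic net / random forest), `de_summary`, and
#'   `provenance`.
#' @export
run_pipeline <- function(study, plan, config, external_study = NULL) {
  stopifnot(inherits(study, "expression_study"), inherits(plan, "fold_plan"),
            inherits(config, "pipeline_config"))
  if (!is.null(external_study) &&
      !identical(rownames(study$expr), rownames(external_study$expr)))
    stop("external cohort does not share the training cohort's gene universe")
  if (config$permute)
    study <- permute_labels(study, derive_seed(config$seed, "permute"))
  subj <- study_subjects(study)
  y_all <- stats::setNames(as.integer(subj$outcome == "case"),
                           subj$subject_id)
  ext <- NULL
  if (!is.null(external_study)) {
    es <- study_subjects(external_study)
    ext <- list(study = external_study,
                y = as.integer(es$outcome == "case"))
  }
  iters <- plan_iterations(plan)
  de_full <- NULL
  fm_full <- NULL
  sas_full <- NULL
  if (config$leakage_mode == "prone") {
    de_full <- run_de(study, config$filter, config$alpha,
                      criterion = config$de_criterion)
    genes_full <- cap_de_genes(de_full$selected, de_full$table,
                               config$max_de_features)
    de_full$selected <- genes_full
    if (length(genes_full)) {
      fm_full <- build_feature_matrix(study, genes_full)
      if (config$prone_scope == "de_and_sas" &&
          length(intersect(config$families, config$sas_families))) {
        sc <- config$sas
        sc$seed <- derive_seed(config$seed, "sas_full")
        sas_full <- sas_select(fm_full, sc)
      }
    }
  }
  fold_rows <- list()
  traces <- list()
  internal_sel <- list()
  de_summary <- data.frame(rep = integer(0), fold = integer(0),
                           n_filtered = integer(0), n_selected = integer(0),
                           rho_hat = numeric(0))
  for (ii in seq_along(iters)) {
    it <- iters[[ii]]
    tag <- paste0("it", it$rep, "_", it$fold)
    if (config$leakage_mode == "safe") {
      de <- run_de(subset_study(study, it$train), config$filter,
                   config$alpha, criterion = config$de_criterion)
      genes <- cap_de_genes(de$selected, de$table, config$max_de_features)
      fm <- if (length(genes)) build_feature_matrix(study, genes) else NULL
    } else {
      de <- de_full
      genes <- de_full$selected
      fm <- fm_full
    }
    de_summary <- rbind(de_summary, data.frame(
      rep = it$rep, fold = it$fold, n_filtered = length(de$genes_kept),
      n_selected = length(genes), rho_hat = de$rho_hat))
    fm_ext <- NULL
    if (!is.null(ext) && length(genes))
      fm_ext <- build_feature_matrix(ext$study, genes)
    # stepwise selection on the training rows (or the cached full-cohort
    # selection when the prone scope includes it)
    trace <- NULL
    needs_sas <- length(intersect(config$families, config$sas_families)) > 0
    if (needs_sas && length(genes)) {
      if (!is.null(sas_full)) {
        trace <- sas_full
      } else {
        sc <- config$sas
        sc$seed <- derive_seed(config$seed, paste0(tag, "_sas"))
        trace <- sas_select(subset_features(fm, it$train), sc)
      }
    }
    traces[[ii]] <- trace
    base_feats <- if (length(genes))
      fm$feature_meta$feature[fm$feature_meta$kind != "interaction"] else
        character(0)
    for (fam in config$families) {
      use_sas <- fam %in% config$sas_families
      feats <- if (use_sas) {
        if (is.null(trace)) character(0) else trace$selected$feature
      } else base_feats
      sets <- list(training = NULL, internal_test = NULL, external = NULL)
      if (length(feats) == 0) {
        rows <- list(training = degenerate_row(y_all[it$train]),
                     internal_test = degenerate_row(y_all[it$test]))
        if (!is.null(ext)) rows$external <- degenerate_row(ext$y)
        degen <- TRUE
      } else {
        margs <- config$model_args[[fam]] %||% list()
        mc <- do.call(model_config,
                      c(list(family = fam,
                             seed = derive_seed(config$seed,
                                                paste0(tag, "_", fam))),
                        margs))
        Xtr <- fm$X[it$train, feats, drop = FALSE]
        model <- suppressWarnings(train_model(mc, Xtr, y_all[it$train]))
        if (fam %in% c("LR_ELN", "RF")) {
          internal_sel[[paste0(tag, "_", fam)]] <-
            internal_selection_report(model)
        }
        rows <- list(
          training = metric_row(predict_scores(model, fm$X[it$train, ,
                                                           drop = FALSE]),
                                y_all[it$train]),
          internal_test = metric_row(predict_scores(model, fm$X[it$test, ,
                                                                drop = FALSE]),
                                     y_all[it$test]))
        if (!is.null(ext))
          rows$external <- metric_row(predict_scores(model, fm_ext$X), ext$y)
        degen <- FALSE
      }
      for (set_label in names(rows)) {
        if (is.null(rows[[set_label]])) next
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          rep = it$rep, fold = it$fold, family = fam, set_label = set_label,
          degenerate = degen, t(rows[[set_label]]),
          stringsAsFactors = FALSE)
      }
    }
  }
  fold_metrics <- do.call(rbind, fold_rows)
  perf <- list()
  for (fam in config$families) {
    for (set_label in unique(fold_metrics$set_label)) {
      sub <- fold_metrics[fold_metrics$family == fam &
                            fold_metrics$set_label == set_label, ]
      if (nrow(sub) < 2) next
      agg <- aggregate_folds(sub[, c("auroc", "sensitivity", "specificity",
                                     "ppv", "npv", "fpr", "fnr")],
                             set_label = set_label)
      agg$family <- fam
      perf[[length(perf) + 1L]] <- agg
    }
  }
  structure(list(
    performance = do.call(rbind, perf),
    fold_metrics = fold_metrics,
    traces = traces,
    internal_selection = internal_sel,
    de_summary = de_summary,
    provenance = list(seed = config$seed, leakage_mode = config$leakage_mode,
                      permute = config$permute, alpha = config$alpha,
                      de_criterion = config$de_criterion,
                      families = config$families,
                      repeats = plan$repeats, k = plan$k,
                      timestamp = format(Sys.time(), tz = "UTC"))),
    class = "experiment_report")
}

#' Permuted-label overfitting control
#'
#' Scrambles the outcome labels at the subject level and reruns the pipeline,
#' juxtaposing training, held-out and external performance. After permutation
#' no genuine expression-outcome association exists, so training-set
#' performance above chance is pure overfitting. By default every requested
#' family consumes the post-DE feature space directly (`route = "de"`), which
#' isolates estimator-level overfitting at a feature count large enough for
#' flexible models to memorize the training rows; `route = "default"` keeps
#' the standard routing (stepwise selection for LR/LR_reg/MLP).
#'
#' @param study,plan,config,external_study as in [run_pipeline()].
#' @param route `"de"` (default) or `"default"`, see above.
#' @return An `experiment_report` (see [run_pipeline()]).
#' @export
run_permutation_control <- function(study, plan, config,
                                    external_study = NULL,
                                    route = c("de", "default")) {
  route <- match.arg(route)
  config$permute <- TRUE
  if (route == "de") config$sas_families <- character(0)
  run_pipeline(study, plan, config, external_study)
}

#' Leakage audit with a perturbation canary
#'
#' Checks that, for the first outer iteration, every differential-expression
#' statistic is a pure function of the training partition: the held-out
#' subjects' expression values are grossly perturbed and the DE stage is
#' recomputed; in safe mode the result must be bit-identical, while in prone
#' mode the perturbation leaks into the statistics.
#'
#' @param study an [expression_study()].
#' @param plan a [make_folds()] plan.
#' @param config a [pipeline_config()].
#' @return TRUE when preprocessing is leakage-free (statistics unchanged),
#'   FALSE otherwise.
#' @export
leakage_audit <- function(study, plan, config) {
  it <- plan_iterations(plan)[[1]]
  canary <- study
  held <- canary$sample_sheet$subject_id %in% it$test
  canary$expr[, held] <- canary$expr[, held] + 1000
  de_input <- function(s) if (config$leakage_mode == "safe")
    subset_study(s, it$train) else s
  de1 <- run_de(de_input(study), config$filter, config$alpha,
                criterion = config$de_criterion)
  de2 <- run_de(de_input(canary), config$filter, config$alpha,
                criterion = config$de_criterion)
  identical(de1$table, de2$table) && identical(de1$selected, de2$selected)
}

#' Read an expression study from delimited text
#'
#' Expects the two-file layout written by [save_study()]: a genes x samples
#' TSV of log2 intensities (first column = gene ids) and a sample sheet TSV
#' with columns `sample_id`, `subject_id`, `timepoint`, `outcome` - the shape
#' of a GEO series-matrix-derived table, so real cohort exports can be
#' slotted in. Subjects present at a single timepoint (deliveries occurring
#' before the T2 collection, or missing samples) are removed with a message;
#' unknown timepoint tokens, duplicate sample ids, sheet/matrix mismatches
#' and missing values are errors naming the offenders.
#'
#' @param expr_path path to the expression TSV.
#' @param sheet_path path to the sample sheet TSV.
#' @return An [expression_study()].
#' @export
load_study <- function(expr_path, sheet_path) {
  expr <- as.matrix(utils::read.delim(expr_path, row.names = 1,
                                      check.names = FALSE))
  sheet <- utils::read.delim(sheet_path, colClasses = "character")
  need <- c("sample_id", "subject_id", "timepoint", "outcome")
  if (!all(need %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  missing_cols <- setdiff(colnames(expr), sheet$sample_id)
  extra_rows <- setdiff(sheet$sample_id, colnames(expr))
  if (length(missing_cols) || length(extra_rows))
    stop("sample sheet and expression matrix disagree; ",
         if (length(missing_cols)) paste("columns without sheet rows:",
                                         paste(missing_cols, collapse = ", ")),
         if (length(extra_rows)) paste(" sheet rows without columns:",
                                       paste(extra_rows, collapse = ", ")))
  tp_per_subj <- table(sheet$subject_id)
  incomplete <- names(tp_per_subj)[tp_per_subj != 2L]
  if (length(incomplete)) {
    message("removed ", length(incomplete), " subject(s) with a single ",
            "timepoint (delivery before the T2 collection, or missing ",
            "sample): ", paste(incomplete, collapse = ", "))
    keep <- !(sheet$subject_id %in% incomplete)
    sheet <- sheet[keep, ]
    expr <- expr[, sheet$sample_id, drop = FALSE]
  }
  expression_study(expr, sheet)
}

#' Write an expression study as a pair of TSV files
#'
#' @param study an [expression_study()].
#' @param expr_path,sheet_path output paths.
#' @return Invisibly, the two paths.
#' @export
save_study <- function(study, expr_path, sheet_path) {
  stopifnot(inherits(study, "expression_study"))
  df <- data.frame(gene = rownames(study$expr), study$expr,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$sample_sheet, sheet_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(expr_path, sheet_path))
}

#' Write an experiment report to a directory
#'
#' Writes the aggregated performance table and per-iteration metrics as TSV,
#' the stepwise-selection stability summary (times selected, average rank)
#' as TSV, and the provenance as JSON.
#'
#' @param report an `experiment_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
save_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$performance, file.path(dir, "performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$fold_metrics, file.path(dir, "fold_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- Filter(function(tr) !is.null(tr) && nrow(tr$selected) > 0,
                report$traces)
  if (length(sel)) {
    utils::write.table(stability_summary(sel),
                       file.path(dir, "sas_stability.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$provenance$leakage_mode, "mode,",
      if (x$provenance$permute) "permuted labels," else "original labels,",
      x$provenance$repeats, "x", x$provenance$k, "folds\n")
  au <- x$performance[x$performance$metric == "auroc", ]
  if (!is.null(au) && nrow(au))
    print(au[, c("family", "set_label", "mean", "ci_low", "ci_high")],
          row.names = FALSE)
  invisible(x)
}
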