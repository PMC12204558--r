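#' Describe a planted class-difference signal
#'
#' A signal specification plants a known expression difference between cases
#' (spontaneous preterm birth, sPTB) and controls (term delivery) in a set of
#' genes, mirroring the three outcome-related comparisons a two-timepoint
#' case-control design supports: a difference at the first sampling timepoint
#' (T1, 17-23 weeks), at the second (T2, 28-33 weeks), or in the within-subject
#' trajectory dT = T2 - T1.
#'
#' @param contrast_kind one of `"T1_diff"`, `"T2_diff"`, `"trajectory_diff"`.
#' @param n_genes number of genes carrying this signal.
#' @param effect_size additive shift applied to case samples. Interpreted in
#'   log2 units when `units = "log2"`, or as a multiple of each signal gene's
#'   own noise SD when `units = "sd"`.
#' @param units `"log2"` (absolute shift) or `"sd"` (shift relative to the
#'   gene's residual SD).
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(contrast_kind = c("T1_diff", "T2_diff", "trajectory_diff"),
                        n_genes, effect_size, units = c("log2", "sd")) {
  contrast_kind <- match.arg(contrast_kind)
  units <- match.arg(units)
  stopifnot(is.numeric(n_genes), length(n_genes) == 1L, n_genes >= 0,
            n_genes == round(n_genes),
            is.numeric(effect_size), length(effect_size) == 1L,
            is.finite(effect_size))
  structure(list(contrast_kind = contrast_kind, n_genes = as.integer(n_genes),
                 effect_size = effect_size, units = units),
            class = "signal_spec")
}

#' Configuration for the synthetic two-timepoint cohort generator
#'
#' Defaults emulate the structure of the Calgary discovery cohort: 49 sPTB
#' cases and 114 term controls, each with one T1 and one T2 maternal blood
#' sample, log2 RMA-like intensities, and within-subject correlation of the
#' paired residuals. A minority of genes is generated with near-zero variance,
#' inflated variance, or low expression so the filtering stage has work to do.
#' The gene count defaults to 5,000 (scaled down from array scale for desk
#' runtime).
#'
#' @param n_cases,n_controls subject counts per class.
#' @param n_genes total number of genes.
#' @param baseline_mean_range range (log2 units) for per-gene baseline means.
#' @param gene_sd_range range (log2 units) for per-gene residual SDs.
#' @param frac_low_variance,frac_high_variance,frac_low_expression proportions
#'   of genes generated with SD < 0.001, SD > 3, and baseline below the
#'   conventional expression floor of 5, respectively.
#' @param rho_within within-subject correlation of the (T1, T2) residual pair,
#'   in \[0, 1).
#' @param signals list of [signal_spec()] objects; signal gene sets are
#'   disjoint and drawn from the well-behaved (unflagged) genes.
#' @param seed root seed; all generator randomness flows from derived child
#'   streams so e.g. adding genes does not perturb labels.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 49, n_controls = 114, n_genes = 5000,
                       baseline_mean_range = c(3, 12),
                       gene_sd_range = c(0.2, 1.2),
                       frac_low_variance = 0.02, frac_high_variance = 0.02,
                       frac_low_expression = 0.05, rho_within = 0.5,
                       signals = list(), seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_genes >= 1,
            length(baseline_mean_range) == 2L,
            baseline_mean_range[1] <= baseline_mean_range[2],
            length(gene_sd_range) == 2L, gene_sd_range[1] <= gene_sd_range[2],
            gene_sd_range[1] > 0,
            frac_low_variance >= 0, frac_high_variance >= 0,
            frac_low_expression >= 0,
            frac_low_variance + frac_high_variance + frac_low_expression <= 1,
            rho_within >= 0, rho_within < 1)
  if (length(signals) > 0) {
    stopifnot(all(vapply(signals, inherits, logical(1), "signal_spec")))
    n_sig <- sum(vapply(signals, `[[`, integer(1), "n_genes"))
    n_flagged <- round(n_genes * (frac_low_variance + frac_high_variance +
                                    frac_low_expression))
    if (n_sig > n_genes - n_flagged)
      stop("more signal genes requested than well-behaved genes available")
  }
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_genes = as.integer(n_genes),
                 baseline_mean_range = as.numeric(baseline_mean_range),
                 gene_sd_range = as.numeric(gene_sd_range),
                 frac_low_variance = frac_low_variance,
                 frac_high_variance = frac_high_variance,
                 frac_low_expression = frac_low_expression,
                 rho_within = rho_within, signals = signals,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Construct and validate a two-timepoint expression study
#'
#' The container flowing through every stage: a genes x samples matrix of log2
#' intensities plus a sample sheet mapping samples to subject, timepoint and
#' birth outcome. Subjects delivering before the T2 collection cannot
#' contribute a pair, so every subject must be present at exactly both
#' timepoints; incomplete subjects are rejected at ingestion ([load_study()]).
#'
#' @param expr numeric matrix, genes x samples, with dimnames.
#' @param sample_sheet data.frame with columns `sample_id`, `subject_id`,
#'   `timepoint` (`"T1"`/`"T2"`), `outcome` (`"case"`/`"control"`).
#' @param truth optional data.frame recording planted signal genes
#'   (`gene`, `contrast_kind`, `effect_size`), or `NULL`.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(expr, sample_sheet, truth = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr),
            !is.null(rownames(expr)), !is.null(colnames(expr)),
            is.data.frame(sample_sheet),
            all(c("sample_id", "subject_id", "timepoint", "outcome") %in%
                  names(sample_sheet)))
  if (anyNA(expr)) stop("expression matrix contains missing values")
  sheet <- sample_sheet[, c("sample_id", "subject_id", "timepoint", "outcome")]
  sheet[] <- lapply(sheet, as.character)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  bad_tp <- setdiff(unique(sheet$timepoint), c("T1", "T2"))
  if (length(bad_tp))
    stop("unknown timepoint token(s): ", paste(bad_tp, collapse = ", "))
  bad_out <- setdiff(unique(sheet$outcome), c("case", "control"))
  if (length(bad_out))
    stop("unknown outcome token(s): ", paste(bad_out, collapse = ", "))
  if (!setequal(colnames(expr), sheet$sample_id))
    stop("sample sheet and expression matrix columns disagree")
  sheet <- sheet[match(colnames(expr), sheet$sample_id), ]
  rownames(sheet) <- NULL
  key <- paste(sheet$subject_id, sheet$timepoint)
  if (anyDuplicated(key))
    stop("duplicate (subject, timepoint) pairs: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  tp_count <- table(sheet$subject_id)
  incomplete <- names(tp_count)[tp_count != 2L]
  if (length(incomplete))
    stop("subject(s) without both timepoints (delivery before the T2 ",
         "collection, or missing sample): ",
         paste(incomplete, collapse = ", "))
  out_by_subj <- tapply(sheet$outcome, sheet$subject_id,
                        function(x) length(unique(x)))
  if (any(out_by_subj != 1L))
    stop("subject(s) with inconsistent outcome labels across timepoints")
  structure(list(expr = expr, sample_sheet = sheet, truth = truth),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  subj <- study_subjects(x)
  cat("expression_study:", nrow(x$expr), "genes x", ncol(x$expr), "samples;",
      nrow(subj), "subjects (", sum(subj$outcome == "case"), "case /",
      sum(subj$outcome == "control"), "control );",
      if (is.null(x$truth)) "no ground truth" else
        paste(nrow(x$truth), "planted signal genes"), "\n")
  invisible(x)
}

#' One row per subject (subject_id, outcome), in first-appearance order
#' @param study an [expression_study()].
#' @return data.frame with columns `subject_id` and `outcome`.
#' @export
study_subjects <- function(study) {
  sheet <- study$sample_sheet
  keep <- !duplicated(sheet$subject_id)
  data.frame(subject_id = sheet$subject_id[keep],
             outcome = sheet$outcome[keep], stringsAsFactors = FALSE)
}

# Gene-level generative parameters, a pure function of the config (shared by
# the paired cohort and any external cohort over the same gene universe).
gene_params <- function(config) {
  G <- config$n_genes
  with_seed(derive_seed(config$seed, "genes"), {
    genes <- sprintf("G%05d", seq_len(G))
    n_lv <- round(G * config$frac_low_variance)
    n_hv <- round(G * config$frac_high_variance)
    n_le <- round(G * config$frac_low_expression)
    flag <- rep("regular", G)
    idx <- sample.int(G, n_lv + n_hv + n_le)
    flag[idx[seq_len(n_lv)]] <- "low_variance"
    if (n_hv) flag[idx[n_lv + seq_len(n_hv)]] <- "high_variance"
    if (n_le) flag[idx[n_lv + n_hv + seq_len(n_le)]] <- "low_expression"
    mu <- stats::runif(G, config$baseline_mean_range[1],
                       config$baseline_mean_range[2])
    mu[flag == "low_expression"] <- stats::runif(sum(flag == "low_expression"),
                                                 0.5, 4.5)
    sigma <- stats::runif(G, config$gene_sd_range[1], config$gene_sd_range[2])
    sigma[flag == "low_variance"] <- stats::runif(sum(flag == "low_variance"),
                                                  1e-4, 9e-4)
    sigma[flag == "high_variance"] <- stats::runif(sum(flag == "high_variance"),
                                                   3.05, 4)
    # assign disjoint signal gene sets among the well-behaved genes
    truth <- NULL
    shift_T1 <- numeric(G)
    shift_T2 <- numeric(G)
    if (length(config$signals)) {
      # plant signals preferentially in well-expressed genes (clear of the
      # conventional expression floor of 5), so a planted biomarker is not
      # deleted by the low-expression filter before it can be tested; fall
      # back to the remaining regular genes when the baseline range is low
      n_sig_total <- sum(vapply(config$signals, `[[`, integer(1), "n_genes"))
      clear <- which(flag == "regular" & mu > 6)
      pool <- clear[sample.int(length(clear))]
      if (length(pool) < n_sig_total) {
        rest <- setdiff(which(flag == "regular"), clear)
        pool <- c(pool, rest[sample.int(length(rest))])
      }
      used <- 0L
      rows <- list()
      for (sg in config$signals) {
        if (sg$n_genes == 0L) next
        take <- pool[used + seq_len(sg$n_genes)]
        used <- used + sg$n_genes
        eff <- if (sg$units == "sd") sg$effect_size * sigma[take] else
          rep(sg$effect_size, length(take))
        if (sg$contrast_kind == "T1_diff") {
          shift_T1[take] <- shift_T1[take] + eff
        } else {
          # T2_diff and trajectory_diff both realize as a T2 shift in cases;
          # trajectory_diff is the simplest differential-trajectory model
          shift_T2[take] <- shift_T2[take] + eff
        }
        rows[[length(rows) + 1L]] <-
          data.frame(gene = genes[take], contrast_kind = sg$contrast_kind,
                     effect_size = eff, stringsAsFactors = FALSE)
      }
      if (length(rows)) truth <- do.call(rbind, rows)
    }
    list(genes = genes, mu = mu, sigma = sigma, flag = flag,
         shift_T1 = shift_T1, shift_T2 = shift_T2, truth = truth)
  })
}

# Shared sampling core: builds a paired cohort from gene parameters.
sample_cohort <- function(config, gp, n_cases, n_controls, noise_seed,
                          subject_prefix = "", extra_shift = NULL) {
  if (any(gp$mu + gp$shift_T1 < 0) || any(gp$mu + gp$shift_T2 < 0))
    stop("planted effect sizes would push mean log2 intensity below zero; ",
         "clamping is not performed - reduce |effect_size| or raise baselines")
  n_subj <- n_cases + n_controls
  G <- config$n_genes
  rho <- config$rho_within
  subj <- c(sprintf("%sCASE%03d", subject_prefix, seq_len(n_cases)),
            sprintf("%sCTRL%03d", subject_prefix, seq_len(n_controls)))
  outcome <- rep(c("case", "control"), c(n_cases, n_controls))
  t1_ids <- paste0(subj, "_T1")
  t2_ids <- paste0(subj, "_T2")
  expr <- with_seed(noise_seed, {
    U <- matrix(stats::rnorm(G * n_subj), G, n_subj)
    E1 <- matrix(stats::rnorm(G * n_subj), G, n_subj)
    E2 <- matrix(stats::rnorm(G * n_subj), G, n_subj)
    Z1 <- sqrt(rho) * U + sqrt(1 - rho) * E1
    Z2 <- sqrt(rho) * U + sqrt(1 - rho) * E2
    base <- gp$mu + (extra_shift %||% 0)
    X1 <- base + gp$sigma * Z1
    X2 <- base + gp$sigma * Z2
    case_cols <- seq_len(n_cases)
    X1[, case_cols] <- X1[, case_cols] + gp$shift_T1
    X2[, case_cols] <- X2[, case_cols] + gp$shift_T2
    # interleave T1/T2 per subject (subject-major column order)
    out <- matrix(0, G, 2L * n_subj,
                  dimnames = list(gp$genes,
                                  as.vector(rbind(t1_ids, t2_ids))))
    out[, seq(1L, 2L * n_subj, by = 2L)] <- X1
    out[, seq(2L, 2L * n_subj, by = 2L)] <- X2
    out
  })
  sheet <- data.frame(
    sample_id = as.vector(rbind(t1_ids, t2_ids)),
    subject_id = rep(subj, each = 2L),
    timepoint = rep(c("T1", "T2"), n_subj),
    outcome = rep(outcome, each = 2L),
    stringsAsFactors = FALSE)
  expression_study(expr, sheet, truth = gp$truth)
}

#' Simulate a paired two-timepoint case-control cohort
#'
#' Generates log2 RMA-like intensities for every subject at both timepoints.
#' Per gene, a baseline mean and residual SD are drawn from the configured
#' ranges (with designated near-constant, hyper-variable and lowly expressed
#' fractions); the (T1, T2) residual pair of each subject is bivariate normal
#' with correlation `rho_within`; planted signals are added to case samples;
#' the ground truth is recorded in `$truth`. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return An [expression_study()] with 2 x (n_cases + n_controls) samples.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gp <- gene_params(config)
  sample_cohort(config, gp, config$n_cases, config$n_controls,
                noise_seed = derive_seed(config$seed, "noise"))
}

#' Simulate a distribution-shifted external validation cohort
#'
#' Shares the gene universe and the planted ground truth of the paired cohort
#' defined by `config`, but draws new subjects and offsets every gene's
#' baseline by an independent normal location shift (a batch/population
#' effect), emulating an external cohort from a different site. Defaults match
#' the structure of the Detroit validation cohort (34 sPTB cases, 64 term
#' controls; 196 samples).
#'
#' @param config the [sim_config()] of the training cohort (defines the gene
#'   universe, gene parameters and signals).
#' @param shift_sd SD (log2 units) of the per-gene location offset between
#'   cohorts; `0` gives a cohort distributionally identical to
#'   [simulate_cohort()] (up to sampling noise).
#' @param n_cases,n_controls external subject counts.
#' @return An [expression_study()].
#' @export
simulate_external_cohort <- function(config, shift_sd = 0, n_cases = 34,
                                     n_controls = 64) {
  stopifnot(inherits(config, "sim_config"), shift_sd >= 0)
  gp <- gene_params(config)
  shift <- with_seed(derive_seed(config$seed, "external_shift"),
                     stats::rnorm(config$n_genes, 0, shift_sd))
  sample_cohort(config, gp, n_cases, n_controls,
                noise_seed = derive_seed(config$seed, "external_noise"),
                subject_prefix = "EXT", extra_shift = shift)
}

#' Permute outcome labels at the subject level
#'
#' Randomly scrambles the sPTB/term labels across subjects while keeping both
#' timepoint samples of a subject under one common label, preserving the class
#' counts, and leaving the expression matrix untouched. Used by the
#' overfitting control: after permutation no genuine association between
#' expression and outcome remains, so any residual training-set performance is
#' overfitting. Any recorded ground truth is cleared.
#'
#' @param study an [expression_study()].
#' @param seed integer seed for the permutation.
#' @return An [expression_study()] with permuted labels and `truth = NULL`.
#' @export
permute_labels <- function(study, seed) {
  stopifnot(inherits(study, "expression_study"))
  subj <- study_subjects(study)
  perm <- with_seed(derive_seed(seed, "label_permutation"),
                    sample.int(nrow(subj)))
  new_outcome <- subj$outcome[perm]
  names(new_outcome) <- subj$subject_id
  sheet <- study$sample_sheet
  sheet$outcome <- unname(new_outcome[sheet$subject_id])
  expression_study(study$expr, sheet, truth = NULL)
}
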