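# Shared fixtures: all data is generated in code at test time.

# A feature_matrix object built directly from a matrix (bypassing a study),
# for exercising the selector on constructed instances.
make_fm <- function(X, y, kind = "T1") {
  stopifnot(!is.null(colnames(X)))
  structure(list(
    X = X,
    feature_meta = data.frame(feature = colnames(X),
                              gene = colnames(X),
                              kind = rep_len(kind, ncol(X)),
                              parents = NA_character_,
                              stringsAsFactors = FALSE),
    y = as.integer(y),
    subjects = rownames(X) %||% paste0("S", seq_len(nrow(X)))),
    class = "feature_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny paired study constructed by hand around the filter thresholds.
toy_filter_study <- function() {
  n_subj <- 120  # 240 samples
  subj <- sprintf("S%03d", seq_len(n_subj))
  sheet <- data.frame(
    sample_id = as.vector(rbind(paste0(subj, "_T1"), paste0(subj, "_T2"))),
    subject_id = rep(subj, each = 2),
    timepoint = rep(c("T1", "T2"), n_subj),
    outcome = rep(rep(c("case", "control"), each = 2), length.out = 2 * n_subj),
    stringsAsFactors = FALSE)
  n <- 2 * n_subj
  set.seed(99)
  base <- 8 + stats::rnorm(n, 0, 0.8)
  A <- rep(7, n)                      # constant: SD 0 < 0.001 -> removed
  B <- 8 + stats::rnorm(n)
  B <- 8 + (B - mean(B)) * 3.5 / stats::sd(B)  # SD exactly 3.5 > 3 -> removed
  C <- base                            # SD ~0.8, all >= 5 -> kept
  C[C < 5] <- 5.1
  D <- base
  D[D < 5] <- 5.1
  D[1:36] <- 4.0                       # 36 of 240 samples below 5 -> removed
  expr <- rbind(A = A, B = B, C = C, D = D)
  colnames(expr) <- sheet$sample_id
  expression_study(expr, sheet)
}

# Row-wise two-sample Welch t-test p-values (vectorized oracle used for
# generator calibration checks).
row_t_pvals <- function(X, group) {
  g1 <- X[, group == 1, drop = FALSE]
  g0 <- X[, group == 0, drop = FALSE]
  n1 <- ncol(g1); n0 <- ncol(g0)
  m1 <- rowMeans(g1); m0 <- rowMeans(g0)
  v1 <- rowSums((g1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((g0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  2 * stats::pt(-abs(tt), df)
}

# Brute-force AUROC by explicit pair counting (independent oracle).
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Brute-force BH by the step-up definition (independent oracle).
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Generic numeric GLS oracle for the cell-means model under compound
# symmetry: explicit design matrix, explicit block-diagonal correlation,
# solved with dense linear algebra.
gls_oracle <- function(study, gene, rho) {
  sheet <- study$sample_sheet
  y <- study$expr[gene, ]
  cell <- factor(paste(sheet$outcome, sheet$timepoint, sep = "_"),
                 levels = c("control_T1", "control_T2", "case_T1", "case_T2"))
  X <- stats::model.matrix(~ 0 + cell)
  n <- length(y)
  V <- diag(n)
  for (s in unique(sheet$subject_id)) {
    idx <- which(sheet$subject_id == s)
    V[idx[1], idx[2]] <- rho
    V[idx[2], idx[1]] <- rho
  }
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  A <- solve(XtVi %*% X)
  beta <- drop(A %*% XtVi %*% y)
  names(beta) <- c("control_T1", "control_T2", "case_T1", "case_T2")
  r <- y - drop(X %*% beta)
  s2 <- drop(t(r) %*% Vi %*% r) / (n - 4)
  contr <- rbind(
    case_vs_control_T1 = c(-1, 0, 1, 0),
    case_vs_control_T2 = c(0, -1, 0, 1),
    T2_vs_T1_case = c(0, 0, -1, 1),
    T2_vs_T1_control = c(-1, 1, 0, 0),
    trajectory_case_vs_control = c(1, -1, -1, 1))
  list(beta = beta, s2 = s2,
       effects = drop(contr %*% beta),
       unscaled_var = diag(contr %*% A %*% t(contr)))
}
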