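test_that("feature matrix expands genes to T1/T2/dT plus interactions", {
  cfg <- sim_config(n_genes = 20, n_cases = 6, n_controls = 8, seed = 2)
  st <- simulate_cohort(cfg)
  genes <- rownames(st$expr)[1:10]
  fm <- build_feature_matrix(st, genes)
  expect_equal(ncol(fm$X), 6 * 10)          # 3 base + 3 interactions per gene
  expect_equal(sum(fm$feature_meta$kind != "interaction"), 3 * 10)
  expect_equal(nrow(fm$X), 14)              # one row per subject
  # dT is exactly T2 - T1
  g <- genes[3]
  expect_equal(fm$X[, paste0(g, ".dT")],
               fm$X[, paste0(g, ".T2")] - fm$X[, paste0(g, ".T1")])
  # interaction columns are elementwise products of their parents
  expect_equal(fm$X[, paste0(g, ".T1xdT")],
               fm$X[, paste0(g, ".T1")] * fm$X[, paste0(g, ".dT")])
  expect_equal(fm$X[, paste0(g, ".T1xT2")],
               fm$X[, paste0(g, ".T1")] * fm$X[, paste0(g, ".T2")])
  # y aligns with the sample sheet outcome
  subj <- study_subjects(st)
  expect_equal(fm$y, as.integer(subj$outcome == "case"))
  # absent gene errors by name
  expect_error(build_feature_matrix(st, c(genes[1], "NOPE")), "NOPE")
})

test_that("a gene with T2 == T1 yields an identically zero dT column", {
  cfg <- sim_config(n_genes = 4, n_cases = 4, n_controls = 4, seed = 3)
  st <- simulate_cohort(cfg)
  t1 <- which(st$sample_sheet$timepoint == "T1")
  t2 <- which(st$sample_sheet$timepoint == "T2")
  st$expr[2, t2] <- st$expr[2, t1]
  fm <- build_feature_matrix(st, rownames(st$expr))
  expect_true(all(fm$X[, paste0(rownames(st$expr)[2], ".dT")] == 0))
})

test_that("inner CV AUROC behaves at the extremes and under the null", {
  set.seed(11)
  n <- 100
  y <- rep(c(1, 0), c(40, 60))
  folds <- sptbcv:::stratified_fold_ids(y, 5, 7)
  # perfect separator
  sep <- ifelse(y == 1, 5, -5) + stats::rnorm(n, 0, 0.01)
  expect_equal(inner_cv_auroc(NULL, sep, y, folds), 1.0)
  # pure noise, empty model: near 0.5 per run, tight around 0.5 on average
  aucs <- vapply(1:50, function(i) {
    noise <- stats::rnorm(n)
    inner_cv_auroc(NULL, noise, y, folds)
  }, numeric(1))
  expect_true(all(aucs > 0.3 & aucs < 0.7))
  expect_gt(mean(aucs), 0.46)
  expect_lt(mean(aucs), 0.54)
})

test_that("duplicating an in-model feature adds less than epsilon", {
  set.seed(21)
  n <- 120
  y <- rep(c(1, 0), c(48, 72))
  x1 <- y * 1.5 + stats::rnorm(n)
  worse <- 0
  for (i in 1:10) {
    folds <- sptbcv:::stratified_fold_ids(y, 5, 100 + i)
    base_score <- inner_cv_auroc(NULL, x1, y, folds)
    dup_score <- inner_cv_auroc(matrix(x1, ncol = 1), x1 + stats::rnorm(n, 0, 1e-8),
                                y, folds)
    if (dup_score - base_score >= 0.015) worse <- worse + 1
  }
  expect_lte(worse, 1)  # collinearity adds no ranking power
})

test_that("a strongly separating feature is admitted first with rank 1", {
  set.seed(5)
  n <- 120
  y <- rep(c(1, 0), c(40, 80))
  X <- matrix(stats::rnorm(n * 30), n, 30,
              dimnames = list(NULL, sprintf("noise%02d", 1:30)))
  X <- cbind(X, planted = y * 3 + stats::rnorm(n))  # 3-SD class separation
  fm <- make_fm(X, y)
  tr <- sas_select(fm, sas_config(seed = 9))
  expect_equal(tr$selected$feature[1], "planted")
  expect_equal(tr$selected$rank[1], 1)
  expect_gt(tr$selected$score[1], 0.9)   # ~Phi(3/sqrt(2)) = 0.983
})

test_that("patience stops selection after exactly 3 consecutive failures", {
  set.seed(6)
  n <- 200
  y <- rep(c(1, 0), each = 100)
  X <- matrix(stats::rnorm(n * 8), n, 8,
              dimnames = list(NULL, paste0("f", 1:8)))
  fm <- make_fm(X, y)
  tr <- sas_select(fm, sas_config(seed = 3))
  expect_equal(tr$termination_reason, "patience")
  it <- tr$iterations
  last3 <- utils::tail(it$admitted, 3)
  expect_equal(sum(last3), 0)
  # the failure streak is exactly the patience (any earlier iteration in the
  # streak window was an admission)
  if (nrow(it) > 3) expect_true(it$admitted[nrow(it) - 3])
})

test_that("selection respects max_features and the admission-gain contract", {
  set.seed(7)
  n <- 160
  y <- rep(c(1, 0), each = 80)
  # moderately informative so that a second feature still clears epsilon
  strong <- sapply(1:3, function(i) y * 0.9 + stats::rnorm(n))
  colnames(strong) <- paste0("strong", 1:3)
  noise <- matrix(stats::rnorm(n * 5), n, 5,
                  dimnames = list(NULL, paste0("noise", 1:5)))
  fm <- make_fm(cbind(strong, noise), y)
  tr <- sas_select(fm, sas_config(max_features = 2, seed = 4))
  expect_equal(nrow(tr$selected), 2)
  expect_equal(tr$termination_reason, "max_features")
  # recorded scores strictly increase by >= epsilon along admissions
  adm <- tr$iterations[tr$iterations$admitted, ]
  expect_true(all(adm$gain >= 0.015))
  expect_true(all(diff(adm$best_score) > 0))
  # selected list is duplicate-free and ordered by admission
  expect_false(anyDuplicated(tr$selected$feature) > 0)
  expect_equal(tr$selected$rank, seq_len(nrow(tr$selected)))
})

test_that("interaction admissions are capped at max_interactions", {
  # outcome driven by a product structure: the interaction is the only
  # informative candidate
  set.seed(8)
  n <- 200
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  y <- as.integer(z1 * z2 + stats::rnorm(n, 0, 0.3) > 0)
  if (sum(y) < 2 || sum(1 - y) < 2) y[1:2] <- c(0, 1)
  X <- cbind(a = z1, b = z2, ab = z1 * z2)
  fm <- make_fm(X, y, kind = c("T1", "T2", "interaction"))
  cfg0 <- sas_config(max_interactions = 0, seed = 2)
  tr0 <- sas_select(fm, cfg0)
  expect_false("ab" %in% tr0$selected$feature)
  tr1 <- sas_select(fm, sas_config(max_interactions = 1, seed = 2))
  expect_true("ab" %in% tr1$selected$feature)
  n_inter <- sum(fm$feature_meta$kind[match(tr1$selected$feature,
                                            fm$feature_meta$feature)] ==
                   "interaction")
  expect_lte(n_inter, 1)
})

test_that("selection is deterministic given (features, config, seed)", {
  set.seed(9)
  n <- 100
  y <- rep(c(1, 0), each = 50)
  X <- matrix(stats::rnorm(n * 20), n, 20,
              dimnames = list(NULL, paste0("f", sprintf("%02d", 1:20))))
  X[, 1] <- X[, 1] + y * 1.2
  fm <- make_fm(X, y)
  t1 <- sas_select(fm, sas_config(seed = 31))
  t2 <- sas_select(fm, sas_config(seed = 31))
  expect_identical(t1, t2)
})

test_that("ties between equal candidates break lexicographically", {
  set.seed(10)
  n <- 120
  y <- rep(c(1, 0), each = 60)
  x <- y * 2 + stats::rnorm(n)
  # two byte-identical candidates; the lexicographically smaller id wins
  X <- cbind(bbb = x, aaa = x)
  fm <- make_fm(X, y)
  tr <- sas_select(fm, sas_config(max_features = 1, seed = 5))
  expect_equal(tr$selected$feature[1], "aaa")
})

test_that("an empty candidate pool terminates as exhausted", {
  set.seed(12)
  n <- 80
  y <- rep(c(1, 0), each = 40)
  X <- matrix(stats::rnorm(n), n, 1, dimnames = list(NULL, "only"))
  X[, 1] <- X[, 1] + y * 3
  fm <- make_fm(X, y)
  tr <- sas_select(fm, sas_config(seed = 6))
  expect_equal(tr$termination_reason, "exhausted")
  expect_equal(nrow(tr$selected), 1)
})

test_that("under the null SAS admits a small, typically nonzero, number of noise features", {
  # the mechanism behind optimistic training performance: with many candidates
  # the best-looking noise feature clears the admission threshold
  n_admit <- vapply(1:20, function(i) {
    set.seed(4000 + i)
    n <- 120
    y <- rep(c(1, 0), c(40, 80))
    X <- matrix(stats::rnorm(n * 500), n, 500,
                dimnames = list(NULL, sprintf("f%03d", 1:500)))
    fm <- make_fm(X, y)
    nrow(sas_select(fm, sas_config(max_candidates = 40,
                                   seed = 4000 + i))$selected)
  }, numeric(1))
  expect_gt(mean(n_admit), 0)       # noise is admitted...
  expect_lt(mean(n_admit), 15)      # ...but selection does not run away
  expect_gt(mean(n_admit > 0), 0.5) # typically nonzero
})

test_that("batch candidate scoring equals per-candidate inner_cv_auroc", {
  set.seed(13)
  n <- 90
  y <- rep(c(1, 0), c(30, 60))
  X <- matrix(stats::rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  folds <- sptbcv:::stratified_fold_ids(y, 5, 3)
  batch <- sptbcv:::score_candidates(X, "f1", paste0("f", 2:6), y, folds)
  single <- vapply(paste0("f", 2:6), function(f)
    inner_cv_auroc(X[, "f1", drop = FALSE], X[, f], y, folds), numeric(1))
  expect_equal(batch, single, tolerance = 1e-12)
})
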