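test_that("filter_genes applies both rules on the constructed toy matrix", {
  st <- toy_filter_study()
  expect_equal(filter_genes(st, filter_config()), "C")
  # loosening the low-expression cap to 36 readmits D
  expect_setequal(filter_genes(st, filter_config(max_low_samples = 36)),
                  c("C", "D"))
  # the fraction-equivalent cap: 35/240 of samples
  expect_equal(filter_genes(st, filter_config(max_low_fraction = 35 / 240)),
               "C")
  # identical well-behaved genes are all kept
  st2 <- st
  st2$expr <- st$expr[c("C", "C", "C"), ]
  rownames(st2$expr) <- c("C1", "C2", "C3")
  expect_equal(filter_genes(st2, filter_config()), c("C1", "C2", "C3"))
  # empty survivor set warns rather than errors
  st3 <- st
  st3$expr <- st$expr["A", , drop = FALSE]
  expect_warning(out <- filter_genes(st3, filter_config()), "no genes")
  expect_length(out, 0)
})

test_that("shipped filter defaults are the conventional array thresholds", {
  fc <- filter_config()
  expect_equal(fc$sd_low, 0.001)
  expect_equal(fc$sd_high, 3)
  expect_equal(fc$expr_floor, 5)
  expect_equal(fc$max_low_samples, 35)
})

test_that("consensus correlation handles degenerate and null inputs", {
  cfg <- sim_config(n_genes = 400, n_cases = 30, n_controls = 60,
                    rho_within = 0,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 31)
  st <- simulate_cohort(cfg)
  r0 <- estimate_consensus_correlation(st, rownames(st$expr))
  expect_gte(r0, 0)      # clipped at zero
  expect_lt(r0, 0.07)
  # T2 identical to T1 for every subject: perfect correlation, clipped at 0.99
  st2 <- st
  t1 <- st$sample_sheet$timepoint == "T1"
  t2 <- st$sample_sheet$timepoint == "T2"
  st2$expr[, which(t2)] <- st$expr[, which(t1)]
  expect_equal(estimate_consensus_correlation(st2, rownames(st2$expr)), 0.99)
  # too few subjects
  tiny <- subset_study(st, study_subjects(st)$subject_id[1:2])
  expect_error(estimate_consensus_correlation(tiny, rownames(st$expr)),
               "fewer than 3")
})

test_that("GLS fits agree with the generic numeric GLS oracle to 1e-10", {
  cfg <- sim_config(n_genes = 6, n_cases = 8, n_controls = 12,
                    rho_within = 0.5,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 8)
  st <- simulate_cohort(cfg)
  for (rho in c(0, 0.5, 0.8)) {
    fits <- fit_gene_models(st, rownames(st$expr), rho)
    for (g in rownames(st$expr)[c(1, 4)]) {
      oracle <- gls_oracle(st, g, rho)
      i <- match(g, fits$genes)
      expect_equal(unname(fits$cell_means[i, c("control_T1", "control_T2",
                                               "case_T1", "case_T2")]),
                   unname(oracle$beta), tolerance = 1e-10)
      expect_equal(unname(fits$effects[i, ]), unname(oracle$effects),
                   tolerance = 1e-10)
      expect_equal(unname(fits$unscaled_var), unname(oracle$unscaled_var),
                   tolerance = 1e-10)
      expect_equal(fits$s2[[i]], oracle$s2, tolerance = 1e-10)
    }
  }
})

test_that("trajectory contrast variance equals the paired-difference oracle", {
  # on a balanced paired design, the GLS sampling variance of the trajectory
  # contrast must equal Var(mean case dT - mean control dT) with
  # Var(dT) = 2 sigma^2 (1 - rho): an algebraic identity
  cfg <- sim_config(n_genes = 3, n_cases = 10, n_controls = 10,
                    rho_within = 0.5,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 12)
  st <- simulate_cohort(cfg)
  rho <- 0.5
  fits <- fit_gene_models(st, rownames(st$expr), rho)
  nc <- 10; nt <- 10
  expect_equal(unname(fits$unscaled_var["trajectory_case_vs_control"]),
               2 * (1 - rho) * (1 / nc + 1 / nt), tolerance = 1e-12)
  # and the trajectory effect equals the difference of mean per-subject dT
  sheet <- st$sample_sheet
  subj <- study_subjects(st)
  i1 <- match(paste(subj$subject_id, "T1"), paste(sheet$subject_id, sheet$timepoint))
  i2 <- match(paste(subj$subject_id, "T2"), paste(sheet$subject_id, sheet$timepoint))
  for (g in rownames(st$expr)) {
    dT <- st$expr[g, i2] - st$expr[g, i1]
    oracle_eff <- mean(dT[subj$outcome == "case"]) -
      mean(dT[subj$outcome == "control"])
    expect_equal(unname(fits$effects[g, "trajectory_case_vs_control"]),
                 oracle_eff, tolerance = 1e-12)
  }
})

test_that("with rho = 0 the GLS reduces to ordinary cell means and OLS t", {
  cfg <- sim_config(n_genes = 5, n_cases = 6, n_controls = 9,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 14)
  st <- simulate_cohort(cfg)
  fits <- fit_gene_models(st, rownames(st$expr), 0)
  sheet <- st$sample_sheet
  for (g in rownames(st$expr)) {
    m_caseT1 <- mean(st$expr[g, sheet$outcome == "case" & sheet$timepoint == "T1"])
    m_ctrlT1 <- mean(st$expr[g, sheet$outcome == "control" & sheet$timepoint == "T1"])
    expect_equal(unname(fits$effects[g, "case_vs_control_T1"]),
                 m_caseT1 - m_ctrlT1, tolerance = 1e-12)
  }
  # unmoderated t (d0 = 0) equals the GLS t exactly
  mod0 <- list(d0 = 0, s0_sq = NA_real_, s2_post = fits$s2,
               df_total = fits$df)
  tab <- test_contrasts(fits, mod0)
  t_manual <- fits$effects[, "case_vs_control_T1"] /
    sqrt(fits$s2 * fits$unscaled_var["case_vs_control_T1"])
  got <- tab$moderated_t[tab$contrast == "case_vs_control_T1"]
  expect_equal(got, unname(t_manual), tolerance = 1e-10)
})

test_that("an empty design cell raises an error naming the cell", {
  cfg <- sim_config(n_genes = 4, n_cases = 3, n_controls = 4, seed = 6)
  st <- simulate_cohort(cfg)
  sheet <- st$sample_sheet
  drop_subj <- study_subjects(st)$subject_id[study_subjects(st)$outcome == "case"]
  st2 <- subset_study(st, setdiff(study_subjects(st)$subject_id, drop_subj))
  expect_error(fit_gene_models(st2, rownames(st2$expr), 0.3), "case_T1")
})

test_that("variance moderation: limits and parameter recovery", {
  # d0 = 0 limit: posterior variances are the observed variances
  s2 <- c(0.5, 1, 2, 4)
  mod <- list(d0 = 0, s0_sq = 1, s2_post = s2, df_total = 10)
  expect_equal(mod$s2_post, s2)
  # all variances identical: d0 capped and s2_post equals the common value
  m <- moderate_variances(rep(2, 100), 10)
  expect_equal(m$d0, 1e6)
  expect_equal(m$s0_sq, 2)
  expect_equal(m$s2_post, rep(2, 100), tolerance = 1e-4)
  # recovery: s2 ~ scaled-inv-chi2(d0 = 4, s0 = 1) observed with d = 10
  set.seed(202)
  d0 <- 4; s0sq <- 1; d <- 10; G <- 5000
  sigma2 <- d0 * s0sq / stats::rchisq(G, d0)
  s2 <- sigma2 * stats::rchisq(G, d) / d
  fit <- moderate_variances(s2, d)
  expect_gt(fit$d0, 3); expect_lt(fit$d0, 5)
  expect_gt(fit$s0_sq, 0.9); expect_lt(fit$s0_sq, 1.1)
})

test_that("moderated null p-values are uniform and planted effects found", {
  cfg <- sim_config(n_genes = 4000, n_cases = 30, n_controls = 60,
                    rho_within = 0.5,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 55)
  st <- simulate_cohort(cfg)
  de <- run_de(st)
  p_null <- de$table$p[de$table$contrast == "case_vs_control_T1"]
  expect_gt(stats::ks.test(p_null, "punif")$p.value, 0.01)
  # FDR control sanity under the null
  frac_sig <- mean(de$table$p_adj < 0.05)
  expect_lt(frac_sig, 0.05 + 0.01)
  # zero-effect gene with positive variance gives p ~= 1
  fits <- fit_gene_models(st, rownames(st$expr)[1:5], 0.5)
  fits$effects[,] <- 0
  mod <- moderate_variances(fits$s2, fits$df)
  tab0 <- test_contrasts(fits, mod)
  expect_true(all(abs(tab0$p - 1) < 1e-12))
  # a strongly planted gene is recovered at BH 0.05
  cfg2 <- sim_config(n_genes = 2000, n_cases = 49, n_controls = 114,
                     gene_sd_range = c(0.5, 0.5), rho_within = 0.5,
                     frac_low_variance = 0, frac_high_variance = 0,
                     frac_low_expression = 0,
                     signals = list(signal_spec("T1_diff", 1, 2)), seed = 56)
  st2 <- simulate_cohort(cfg2)
  de2 <- run_de(st2)
  g <- st2$truth$gene[1]
  expect_true(g %in% de2$selected)
  t1row <- de2$table[de2$table$gene == g &
                       de2$table$contrast == "case_vs_control_T1", ]
  expect_lt(t1row$p_adj, 0.05)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1, 0.9)), c(0.015, 0.15, 0.9))
  set.seed(7)
  for (i in seq_len(1000)) {
    p <- stats::runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_bruteforce(p))
  }
  # p_adj >= p and p_adj <= 1 always
  p <- stats::runif(500)
  expect_true(all(bh_adjust(p) >= p) && all(bh_adjust(p) <= 1))
})

test_that("moderated statistics agree with limma's pipeline as a cross-check", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_genes = 300, n_cases = 15, n_controls = 25,
                    rho_within = 0.4,
                    frac_low_variance = 0, frac_high_variance = 0,
                    frac_low_expression = 0, seed = 123)
  st <- simulate_cohort(cfg)
  genes <- rownames(st$expr)
  rho <- estimate_consensus_correlation(st, genes)
  fits <- fit_gene_models(st, genes, rho)
  sheet <- st$sample_sheet
  cell <- factor(paste(sheet$outcome, sheet$timepoint, sep = "_"),
                 levels = c("control_T1", "control_T2", "case_T1", "case_T2"))
  design <- stats::model.matrix(~ 0 + cell)
  colnames(design) <- levels(cell)
  fit <- limma::lmFit(st$expr, design, block = sheet$subject_id,
                      correlation = rho)
  cm <- limma::makeContrasts(case_T1 - control_T1, levels = design)
  fit2 <- limma::contrasts.fit(fit, cm)
  # same rho given to both: effect estimates must agree closely
  expect_equal(unname(fits$effects[, "case_vs_control_T1"]),
               unname(fit2$coefficients[, 1]), tolerance = 1e-8)
  # and our consensus correlation is close to duplicateCorrelation's
  dc <- limma::duplicateCorrelation(st$expr, design,
                                    block = sheet$subject_id)
  expect_lt(abs(rho - dc$consensus.correlation), 0.05)
})

test_that("DE is a pure function of the supplied samples (leakage contract)", {
  cfg <- sim_config(n_genes = 300, n_cases = 12, n_controls = 20, seed = 17)
  st <- simulate_cohort(cfg)
  subj <- study_subjects(st)$subject_id
  train <- subj[1:24]
  de1 <- run_de(subset_study(st, train))
  # grossly perturb the held-out subjects and recompute
  st2 <- st
  held_cols <- !(st$sample_sheet$subject_id %in% train)
  st2$expr[, held_cols] <- st2$expr[, held_cols] + 500
  de2 <- run_de(subset_study(st2, train))
  expect_identical(de1$table, de2$table)
  expect_identical(de1$selected, de2$selected)
})

test_that("select_de_genes honors criterion and short-circuits gracefully", {
  cfg <- sim_config(n_genes = 500, n_cases = 15, n_controls = 30, seed = 19)
  st <- simulate_cohort(cfg)
  de <- run_de(st)
  expect_true(length(de$selected) <= length(unique(de$table$gene)))
  raw <- select_de_genes(de$table, criterion = "p")
  adj <- select_de_genes(de$table, criterion = "p_adj")
  expect_true(all(adj %in% raw))
  # the base-feature expansion is 3 per selected gene
  if (length(raw) > 0) {
    fm <- build_feature_matrix(st, raw, interactions = FALSE)
    expect_equal(ncol(fm$X), 3 * length(raw))
  }
})
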