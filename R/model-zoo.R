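# The five prediction model families behind one training/prediction
# contract: unregularized logistic regression (LR), L2-regularized logistic
# regression (LR_reg), elastic-net logistic regression (LR_ELN), random
# forest (RF), and the two-hidden-layer multilayer perceptron (MLP).
# Regularization strengths, the elastic-net mixing parameter and the random
# forest grid are tuned by nested stratified cross-validated AUROC; the MLP
# is tuned by successive halving. All families except the (scale-invariant)
# random forest consume features standardized with training-row statistics.

MODEL_FAMILIES <- c("LR", "LR_reg", "LR_ELN", "RF", "MLP")

#' Model family configuration
#'
#' @param family one of `"LR"`, `"LR_reg"`, `"LR_ELN"`, `"RF"`, `"MLP"`.
#' @param tuning_folds folds of the nested stratified CV used for
#'   hyperparameter tuning (default 5).
#' @param search_budget MLP hyperparameter configurations explored by
#'   successive halving (default 20; `paper_scale = TRUE` restores 500).
#' @param max_epochs MLP epoch cap (default 250).
#' @param reduction_factor successive-halving reduction factor (default 4).
#' @param eln_alpha_grid elastic-net mixing parameters searched.
#' @param rf_grid optional data.frame (`ntree`, `mtry_frac`, `nodesize`)
#'   overriding the default random-forest grid; `mtry_frac` is a fraction of
#'   the feature count (`"sqrt"` is also accepted).
#' @param paper_scale if TRUE, use the full-scale MLP search budget of 500
#'   configurations.
#' @param seed seed governing tuning fold draws and stochastic fits.
#' @return An object of class `model_config`.
#' @export
model_config <- function(family = c("LR", "LR_reg", "LR_ELN", "RF", "MLP"),
                         tuning_folds = 5, search_budget = 20,
                         max_epochs = 250, reduction_factor = 4,
                         eln_alpha_grid = c(0.2, 0.5, 0.8),
                         rf_grid = NULL, paper_scale = FALSE, seed = 1) {
  family <- match.arg(family)
  stopifnot(tuning_folds >= 2, search_budget >= 1, reduction_factor >= 2,
            max_epochs >= 1)
  if (paper_scale) search_budget <- 500
  structure(list(family = family, tuning_folds = as.integer(tuning_folds),
                 search_budget = as.integer(search_budget),
                 max_epochs = as.integer(max_epochs),
                 reduction_factor = as.integer(reduction_factor),
                 eln_alpha_grid = eln_alpha_grid, rf_grid = rf_grid,
                 seed = as.integer(seed)),
            class = "model_config")
}

default_rf_grid <- function(p) {
  mtrys <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
  expand.grid(ntree = 300L, mtry = mtrys, nodesize = c(1L, 5L))
}

#' Train one model family
#'
#' Fits the requested family on `X` (subjects x features) and binary `y`
#' (1 = case). Constant columns are dropped with a warning before
#' standardization. Tuning protocols: LR is a plain maximum-likelihood fit
#' (iteration cap 10,000); LR_reg tunes the ridge penalty and LR_ELN the
#' (mixing, strength) pair by nested stratified k-fold AUROC on a glmnet
#' path; RF tunes its grid by nested stratified k-fold AUROC; the MLP runs a
#' successive-halving search over (l1, l2, p1, p2, learning rate, weight
#' decay, batch size) with the configured reduction factor and epoch cap,
#' selecting the highest validation AUROC with lower loss as tie-break.
#'
#' @param config a [model_config()].
#' @param X numeric matrix, subjects x features, with column names.
#' @param y binary outcome vector (1/TRUE = case).
#' @return An object of class `fitted_ptb_model` whose `predict_scores()`
#'   output is a pure function of `X`.
#' @export
train_model <- function(config, X, y) {
  stopifnot(inherits(config, "model_config"), is.matrix(X))
  if (ncol(X) == 0) stop("empty feature matrix")
  stopifnot(!is.null(colnames(X)))
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) stop("need both classes to train")
  sds <- apply(X, 2, stats::sd)
  const <- !is.finite(sds) | sds < 1e-12
  if (all(const)) stop("all feature columns are constant")
  if (any(const)) {
    warning("dropping ", sum(const), " constant feature column(s): ",
            paste(utils::head(colnames(X)[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ..." else "")
    X <- X[, !const, drop = FALSE]
  }
  st <- col_stats(X)
  Xs <- apply_stats(X, st)
  foldid <- stratified_fold_ids(y, config$tuning_folds,
                                derive_seed(config$seed, "tuning_folds"))
  fit <- switch(
    config$family,
    LR = {
      df <- data.frame(y = y, Xs)
      m <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial(),
                                       control = stats::glm.control(maxit = 10000)))
      if (!m$converged) warning("LR did not converge; returning best iterate")
      list(glm = m)
    },
    LR_reg = {
      cv <- glmnet_cv_auc(Xs, y, alpha = 0, foldid = foldid)
      list(glmnet = cv$fit, lambda = cv$lambda, alpha = 0, cv_auc = cv$auc)
    },
    LR_ELN = {
      best <- NULL
      for (a in config$eln_alpha_grid) {
        cv <- glmnet_cv_auc(Xs, y, alpha = a, foldid = foldid)
        if (is.null(best) || cv$auc > best$cv_auc)
          best <- list(glmnet = cv$fit, lambda = cv$lambda, alpha = a,
                       cv_auc = cv$auc)
      }
      best
    },
    RF = {
      grid <- config$rf_grid %||% default_rf_grid(ncol(X))
      best <- NULL
      if (nrow(grid) > 1) {
        for (gi in seq_len(nrow(grid))) {
          aucs <- numeric(config$tuning_folds)
          for (f in seq_len(config$tuning_folds)) {
            val <- foldid == f
            m <- with_seed(derive_seed(config$seed, paste0("rf", gi, "f", f)),
              randomForest::randomForest(
                x = X[!val, , drop = FALSE], y = factor(y[!val], c(0, 1)),
                ntree = grid$ntree[gi], mtry = min(grid$mtry[gi], ncol(X)),
                nodesize = grid$nodesize[gi]))
            pr <- stats::predict(m, X[val, , drop = FALSE], type = "prob")[, "1"]
            aucs[f] <- auroc(pr, y[val])
          }
          if (is.null(best) || mean(aucs) > best$cv_auc)
            best <- list(row = gi, cv_auc = mean(aucs))
        }
      } else best <- list(row = 1L, cv_auc = NA_real_)
      g <- grid[best$row, ]
      m <- with_seed(derive_seed(config$seed, "rf_final"),
        randomForest::randomForest(
          x = X, y = factor(y, c(0, 1)), ntree = g$ntree,
          mtry = min(g$mtry, ncol(X)), nodesize = g$nodesize,
          importance = FALSE))
      list(rf = m, grid_row = g, cv_auc = best$cv_auc)
    },
    MLP = {
      m <- with_seed(derive_seed(config$seed, "mlp"),
                     mlp_train(Xs, y, search_budget = config$search_budget,
                               tuning_folds = config$tuning_folds,
                               max_epochs = config$max_epochs,
                               reduction_factor = config$reduction_factor,
                               seed = config$seed))
      m
    })
  model <- structure(list(family = config$family, fit = fit,
                          features = colnames(X), center = st$center,
                          scale = st$scale, config = config),
                     class = "fitted_ptb_model")
  model$train_auroc <- auroc(predict_scores(model, X), y)
  model
}

# Stratified-fold glmnet tuning on validation AUROC; returns the full path
# fit, the winning lambda and its CV AUROC.
glmnet_cv_auc <- function(Xs, y, alpha, foldid) {
  Xg <- if (ncol(Xs) == 1) cbind(Xs, .zero = 0) else Xs
  cv <- glmnet::cv.glmnet(Xg, y, family = "binomial", alpha = alpha,
                          type.measure = "auc", foldid = foldid,
                          standardize = FALSE, nlambda = 50)
  list(fit = cv$glmnet.fit, lambda = cv$lambda.min,
       auc = max(cv$cvm))
}

#' Predict case probabilities
#'
#' @param model a [train_model()] result.
#' @param X subjects x features matrix carrying (at least) the model's
#'   feature columns; standardization uses the statistics stored at training.
#' @return Numeric vector of scores in \[0, 1\], one per row of `X`.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "fitted_ptb_model"), is.matrix(X))
  missing <- setdiff(model$features, colnames(X))
  if (length(missing))
    stop("feature mismatch; missing from newdata: ",
         paste(missing, collapse = ", "))
  X <- X[, model$features, drop = FALSE]
  Xs <- apply_stats(X, list(center = model$center, scale = model$scale))
  out <- switch(
    model$family,
    LR = {
      df <- as.data.frame(Xs)
      unname(stats::predict(model$fit$glm, newdata = df, type = "response"))
    },
    LR_reg = ,
    LR_ELN = {
      Xg <- if (ncol(Xs) == 1) cbind(Xs, .zero = 0) else Xs
      drop(stats::predict(model$fit$glmnet, newx = Xg,
                          s = model$fit$lambda, type = "response"))
    },
    RF = unname(stats::predict(model$fit$rf, X, type = "prob")[, "1"]),
    MLP = mlp_predict_state(model$fit$state, Xs))
  unname(out)
}

#' Internal feature selection report (elastic net / random forest)
#'
#' The elastic net selects a feature when its coefficient at the tuned
#' (mixing, strength) pair is nonzero, ranked by decreasing absolute
#' coefficient; the random forest ranks features by decreasing impurity
#' importance and marks a feature selected when its share of total importance
#' exceeds the uniform share `1/p`. Ranks start at 1 (highest).
#'
#' @param model a [train_model()] result with family `"LR_ELN"` or `"RF"`.
#' @return data.frame: feature, weight (|coefficient| or importance),
#'   selected (logical), rank (1 = strongest; NA when not selected).
#' @export
internal_selection_report <- function(model) {
  stopifnot(inherits(model, "fitted_ptb_model"))
  if (!model$family %in% c("LR_ELN", "RF"))
    stop("internal selection is only defined for LR_ELN and RF (got ",
         model$family, ")")
  if (model$family == "LR_ELN") {
    co <- stats::coef(model$fit$glmnet, s = model$fit$lambda)
    co <- co[setdiff(rownames(co), c("(Intercept)", ".zero")), 1]
    w <- abs(co)
    selected <- w > 0
  } else {
    imp <- model$fit$rf$importance[, "MeanDecreaseGini"]
    w <- imp[model$features]
    total <- sum(w)
    selected <- if (total > 0) (w / total) > (1 / length(w)) else
      rep(FALSE, length(w))
  }
  rk <- rank(-w, ties.method = "first")
  out <- data.frame(feature = model$features, weight = unname(w),
                    selected = unname(selected),
                    rank = ifelse(unname(selected), rk, NA_integer_),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.fitted_ptb_model <- function(x, ...) {
  cat("fitted_ptb_model:", x$family, "on", length(x$features),
      "feature(s); training AUROC", round(x$train_auroc, 3), "\n")
  invisible(x)
}
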