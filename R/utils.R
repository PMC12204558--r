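# Internal utilities: deterministic seed streams, RNG sandboxing, stratified
# folds and a lightweight IRLS logistic fitter used in the selection loops.

# Derive a child seed (< 2^31) from a root seed and a stream label, so that
# independent subsystems (gene parameters, noise, labels, fold draws, ...)
# consume independent streams and adding genes does not perturb labels.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1
  h <- (seed %% m + 1)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 31 + ch) %% m
  }
  # one extra multiplicative mix to decorrelate nearby roots
  as.integer((h * 48271) %% m)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# Stratified k-fold assignment. Returns an integer vector of fold indices
# (1..k) aligned with `y`; within each class, fold sizes differ by at most one.
stratified_fold_ids <- function(y, k, seed) {
  y <- as.integer(y)
  n <- length(y)
  ids <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      ids[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  ids
}

# Minimal IRLS logistic regression. X: numeric matrix WITHOUT intercept
# column; returns coefficients c(intercept, beta). Built for speed inside the
# stepwise selection inner loop (thousands of tiny fits); quasi-separation is
# tolerated by capping iterations and the linear predictor.
fast_logit <- function(X, y, maxit = 15L, tol = 1e-7) {
  Xd <- cbind(1, X)
  p <- ncol(Xd)
  beta <- numeric(p)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6))
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(Xd %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t.default(Xd * w)
    A <- XtW %*% Xd
    b <- XtW %*% z
    new_beta <- tryCatch(drop(solve(A, b)), error = function(e) {
      drop(solve(A + diag(1e-8, p), b))
    })
    if (any(!is.finite(new_beta))) break
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    if (delta < tol) break
  }
  beta
}

# Linear predictor -> probability for fast_logit coefficients.
fast_logit_predict <- function(beta, X) {
  stats::plogis(pmin(pmax(drop(cbind(1, X) %*% beta), -30), 30))
}

# Column standardization helpers: statistics from training rows only.
col_stats <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

apply_stats <- function(X, st) {
  sweep(sweep(X, 2, st$center, "-"), 2, st$scale, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
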