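# A small feed-forward binary classifier written on base-R matrix algebra:
# input -> dense(l1) -> batchnorm -> leaky ReLU -> dropout(p1)
#       -> dense(l2) -> batchnorm -> leaky ReLU -> dropout(p2)
#       -> dense(1) -> sigmoid,
# trained with minibatch Adam on binary cross-entropy, with decoupled L2
# weight decay on the dense weights. Hyperparameters (l1, l2, p1, p2,
# learning rate, weight decay, batch size) are searched by successive halving
# with a configurable reduction factor, scoring configurations by stratified
# k-fold validation AUROC (ties broken by lower validation loss).

LEAKY_SLOPE <- 0.01
BN_EPS <- 1e-5

mlp_init <- function(p, l1, l2) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / nin)),
                                   nin, nout)
  list(W1 = he(p, l1), b1 = numeric(l1),
       g1 = rep(1, l1), be1 = numeric(l1),
       rm1 = numeric(l1), rv1 = rep(1, l1),
       W2 = he(l1, l2), b2 = numeric(l2),
       g2 = rep(1, l2), be2 = numeric(l2),
       rm2 = numeric(l2), rv2 = rep(1, l2),
       W3 = he(l2, 1), b3 = 0)
}

bn_forward <- function(Z, g, be, training, rm, rv, momentum = 0.1) {
  if (training) {
    mu <- colMeans(Z)
    v <- colMeans(sweep(Z, 2, mu)^2)
    rm_new <- (1 - momentum) * rm + momentum * mu
    rv_new <- (1 - momentum) * rv + momentum * v
  } else {
    mu <- rm; v <- rv; rm_new <- rm; rv_new <- rv
  }
  sd_inv <- 1 / sqrt(v + BN_EPS)
  xhat <- sweep(sweep(Z, 2, mu), 2, sd_inv, "*")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, be, "+")
  list(out = out, xhat = xhat, sd_inv = sd_inv, rm = rm_new, rv = rv_new)
}

bn_backward <- function(dOut, cache, g) {
  n <- nrow(dOut)
  xhat <- cache$xhat
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2, g, "*")
  t1 <- sweep(dxhat, 2, colSums(dxhat) / n)
  t2 <- sweep(xhat, 2, colSums(dxhat * xhat) / n, "*")
  dZ <- sweep(t1 - t2, 2, cache$sd_inv, "*")
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

mlp_forward_train <- function(st, X, p1, p2) {
  Z1 <- sweep(X %*% st$W1, 2, st$b1, "+")
  bn1 <- bn_forward(Z1, st$g1, st$be1, TRUE, st$rm1, st$rv1)
  A1 <- pmax(bn1$out, 0) + LEAKY_SLOPE * pmin(bn1$out, 0)
  M1 <- if (p1 > 0) matrix(stats::rbinom(length(A1), 1, 1 - p1) / (1 - p1),
                           nrow(A1), ncol(A1)) else NULL
  D1 <- if (is.null(M1)) A1 else A1 * M1
  Z2 <- sweep(D1 %*% st$W2, 2, st$b2, "+")
  bn2 <- bn_forward(Z2, st$g2, st$be2, TRUE, st$rm2, st$rv2)
  A2 <- pmax(bn2$out, 0) + LEAKY_SLOPE * pmin(bn2$out, 0)
  M2 <- if (p2 > 0) matrix(stats::rbinom(length(A2), 1, 1 - p2) / (1 - p2),
                           nrow(A2), ncol(A2)) else NULL
  D2 <- if (is.null(M2)) A2 else A2 * M2
  logit <- drop(D2 %*% st$W3) + st$b3
  list(Z1 = Z1, bn1 = bn1, A1 = A1, M1 = M1, D1 = D1,
       Z2 = Z2, bn2 = bn2, A2 = A2, M2 = M2, D2 = D2, logit = logit)
}

mlp_predict_state <- function(st, X) {
  Z1 <- sweep(X %*% st$W1, 2, st$b1, "+")
  H1 <- bn_forward(Z1, st$g1, st$be1, FALSE, st$rm1, st$rv1)$out
  A1 <- pmax(H1, 0) + LEAKY_SLOPE * pmin(H1, 0)
  Z2 <- sweep(A1 %*% st$W2, 2, st$b2, "+")
  H2 <- bn_forward(Z2, st$g2, st$be2, FALSE, st$rm2, st$rv2)$out
  A2 <- pmax(H2, 0) + LEAKY_SLOPE * pmin(H2, 0)
  stats::plogis(pmin(pmax(drop(A2 %*% st$W3) + st$b3, -30), 30))
}

adam_new <- function(st) {
  par <- c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2", "W3", "b3")
  list(m = lapply(st[par], function(x) x * 0),
       v = lapply(st[par], function(x) x * 0), t = 0L)
}

adam_step <- function(st, grads, opt, lr) {
  opt$t <- opt$t + 1L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^opt$t
  corr2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * g
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * g^2
    st[[nm]] <- st[[nm]] - lr * (opt$m[[nm]] / corr1) /
      (sqrt(opt$v[[nm]] / corr2) + eps)
  }
  list(st = st, opt = opt)
}

# One training run of `epochs` epochs; X already standardized.
mlp_fit_core <- function(X, y, hyper, epochs) {
  n <- nrow(X)
  st <- mlp_init(ncol(X), hyper$l1, hyper$l2)
  opt <- adam_new(st)
  bs <- max(2L, min(hyper$batch, n))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    for (s in starts) {
      idx <- ord[s:min(s + bs - 1L, n)]
      if (length(idx) < 2L) next  # batchnorm needs >= 2 rows
      Xb <- X[idx, , drop = FALSE]
      yb <- y[idx]
      fw <- mlp_forward_train(st, Xb, hyper$p1, hyper$p2)
      st$rm1 <- fw$bn1$rm; st$rv1 <- fw$bn1$rv
      st$rm2 <- fw$bn2$rm; st$rv2 <- fw$bn2$rv
      prob <- stats::plogis(pmin(pmax(fw$logit, -30), 30))
      dlogit <- matrix((prob - yb) / length(yb), ncol = 1)
      gW3 <- t(fw$D2) %*% dlogit + hyper$wd * st$W3
      gb3 <- sum(dlogit)
      dD2 <- dlogit %*% t(st$W3)
      if (!is.null(fw$M2)) dD2 <- dD2 * fw$M2
      dA2pre <- dD2 * ifelse(fw$bn2$out > 0, 1, LEAKY_SLOPE)
      bb2 <- bn_backward(dA2pre, fw$bn2, st$g2)
      gW2 <- t(fw$D1) %*% bb2$dZ + hyper$wd * st$W2
      gb2 <- colSums(bb2$dZ)
      dD1 <- bb2$dZ %*% t(st$W2)
      if (!is.null(fw$M1)) dD1 <- dD1 * fw$M1
      dA1pre <- dD1 * ifelse(fw$bn1$out > 0, 1, LEAKY_SLOPE)
      bb1 <- bn_backward(dA1pre, fw$bn1, st$g1)
      gW1 <- t(Xb) %*% bb1$dZ + hyper$wd * st$W1
      gb1 <- colSums(bb1$dZ)
      grads <- list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
                    W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
                    W3 = gW3, b3 = gb3)
      upd <- adam_step(st, grads, opt, hyper$lr)
      st <- upd$st
      opt <- upd$opt
    }
  }
  st
}

bce_loss <- function(prob, y) {
  p <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Sample `n` hyperparameter configurations from the search ranges.
mlp_sample_configs <- function(n) {
  lapply(seq_len(n), function(i) {
    list(l1 = 2^sample(4:8, 1), l2 = 2^sample(4:8, 1),
         p1 = stats::runif(1, 0, 0.5), p2 = stats::runif(1, 0, 0.5),
         lr = 10^stats::runif(1, -4, -2), wd = 10^stats::runif(1, -6, -3),
         batch = sample(c(16L, 32L, 64L), 1))
  })
}

# Evaluate one configuration at a given epoch budget by stratified k-fold
# validation; returns mean validation AUROC and loss.
mlp_eval_config <- function(X, y, hyper, epochs, k, seed) {
  ids <- stratified_fold_ids(y, k, derive_seed(seed, "mlp_eval_folds"))
  aucs <- numeric(k)
  losses <- numeric(k)
  for (f in seq_len(k)) {
    val <- ids == f
    st <- with_seed(derive_seed(seed, paste0("mlp_fit_", f)),
                    mlp_fit_core(X[!val, , drop = FALSE], y[!val], hyper,
                                 epochs))
    prob <- mlp_predict_state(st, X[val, , drop = FALSE])
    aucs[f] <- auroc(prob, y[val])
    losses[f] <- bce_loss(prob, y[val])
  }
  list(auroc = mean(aucs), loss = mean(losses))
}

# Successive-halving hyperparameter search + final fit on all rows.
# X must already be standardized; y in {0, 1}.
mlp_train <- function(X, y, search_budget = 20L, tuning_folds = 5L,
                      max_epochs = 250L, reduction_factor = 4L, seed = 1L) {
  stopifnot(search_budget >= 1, reduction_factor >= 2)
  configs <- with_seed(derive_seed(seed, "mlp_configs"),
                       mlp_sample_configs(search_budget))
  eta <- reduction_factor
  n_rungs <- max(1L, floor(log(length(configs), eta)) + 1L)
  epochs_at <- pmax(1L, round(max_epochs / eta^(rev(seq_len(n_rungs)) - 1L)))
  alive <- seq_along(configs)
  scores <- rep(NA_real_, length(configs))
  losses <- rep(NA_real_, length(configs))
  for (r in seq_len(n_rungs)) {
    for (i in alive) {
      ev <- mlp_eval_config(X, y, configs[[i]], epochs_at[r], tuning_folds,
                            derive_seed(seed, paste0("cfg", i, "r", r)))
      scores[i] <- ev$auroc
      losses[i] <- ev$loss
    }
    if (r < n_rungs) {
      keep_n <- max(1L, floor(length(alive) / eta))
      ord <- alive[order(-scores[alive], losses[alive])]
      alive <- ord[seq_len(keep_n)]
    }
  }
  winner <- alive[order(-scores[alive], losses[alive])][1]
  hyper <- configs[[winner]]
  st <- with_seed(derive_seed(seed, "mlp_final"),
                  mlp_fit_core(X, y, hyper, max_epochs))
  list(state = st, hyper = hyper, val_auroc = scores[winner],
       val_loss = losses[winner])
}
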