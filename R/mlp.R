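## Minibatch-Adam multilayer perceptron, the package's fixed measuring
## instrument for group separability. One hidden ReLU layer, single logit
## output, logistic cross-entropy with L2 penalty. Kept internal: the
## classifier is not tuned per dataset, only seeded.

mlp_init <- function(d, hidden) {
  list(W1 = matrix(stats::rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
       b1 = numeric(hidden),
       W2 = matrix(stats::rnorm(hidden, sd = sqrt(2 / hidden)), hidden, 1L),
       b2 = 0)
}

mlp_train <- function(X, y, hidden = 100L, max_iter = 500L,
                      learning_rate = 1e-2, batch_size = 200L,
                      l2 = 1, tol = 1e-4, n_iter_no_change = 20L,
                      seed = 1L) {
  set.seed(seed %% .Machine$integer.max)
  n <- nrow(X); d <- ncol(X)
  par <- mlp_init(d, hidden)
  mom <- lapply(par, function(p) p * 0)   # Adam first moment
  vel <- lapply(par, function(p) p * 0)   # Adam second moment
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  batch_size <- min(batch_size, n)
  best <- Inf; stall <- 0L

  for (epoch in seq_len(max_iter)) {
    idx <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1L, n, by = batch_size)) {
      bi <- idx[start:min(start + batch_size - 1L, n)]
      Xb <- X[bi, , drop = FALSE]; yb <- y[bi]; nb <- length(bi)

      H <- Xb %*% par$W1
      H <- H + rep(par$b1, each = nb)
      A <- H * (H > 0)
      z <- drop(A %*% par$W2) + par$b2
      p <- 1 / (1 + exp(-z))
      # numerically stable logistic cross-entropy:
      # per-sample loss = max(z,0) - z*y + log(1 + exp(-|z|)).
      # convergence is monitored on the data term alone so the slow decay
      # of the L2 penalty cannot mask a fitted model
      loss <- mean(pmax(z, 0) - z * yb + log1p(exp(-abs(z))))
      losses <- c(losses, loss)

      dz <- (p - yb) / nb
      gW2 <- crossprod(A, dz) + l2 * par$W2 / nb
      gb2 <- sum(dz)
      dA <- (matrix(dz, ncol = 1L) %*% t(par$W2)) * (H > 0)
      gW1 <- crossprod(Xb, dA) + l2 * par$W1 / nb
      gb1 <- colSums(dA)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)

      t <- t + 1L
      for (nm in names(par)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * grads[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^t)
        vhat <- vel[[nm]] / (1 - b2^t)
        par[[nm]] <- par[[nm]] - learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    epoch_loss <- mean(losses)
    if (epoch_loss > best - tol) stall <- stall + 1L else stall <- 0L
    if (epoch_loss < best) best <- epoch_loss
    if (stall >= n_iter_no_change) break
  }
  par
}

mlp_predict <- function(par, X) {
  H <- X %*% par$W1
  H <- H + rep(par$b1, each = nrow(X))
  A <- H * (H > 0)
  z <- drop(A %*% par$W2) + par$b2
  as.integer(z > 0)
}
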