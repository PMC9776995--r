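# Feed-forward neural network: one hidden tanh layer, softmax output,
# cross-entropy cost, full-batch gradient descent with adaptive step sizes
# (Adam), early stopping on a stratified validation holdout. Inputs are
# standardized internally (the six moment features span wildly different
# magnitudes).

fit_mlp <- function(X, y, K, hidden = 12L, max_iter = 3000L,
                    learning_rate = 0.01, early_stopping = TRUE,
                    validation_fraction = 0.1, patience = 25L, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  set.seed(derive_seed(seed, 202L))
  mu <- colMeans(X)
  sigma <- apply(X, 2, sd)
  sigma[sigma == 0 | !is.finite(sigma)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  val_idx <- integer(0)
  if (early_stopping) {
    for (k in seq_len(K)) {
      rows <- which(y == k)
      n_val <- floor(length(rows) * validation_fraction)
      if (n_val >= 1) val_idx <- c(val_idx, sample(rows, n_val))
    }
    if (length(val_idx) < 2) val_idx <- integer(0)
  }
  tr <- setdiff(seq_len(n), val_idx)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y)] <- 1
  W1 <- matrix(rnorm(p * hidden, sd = 0.5), p, hidden)
  b1 <- numeric(hidden)
  W2 <- matrix(rnorm(hidden * K, sd = 0.5), hidden, K)
  b2 <- numeric(K)
  adam <- list(); for (nm in c("W1", "b1", "W2", "b2")) {
    adam[[nm]] <- list(m = 0, v = 0)
  }
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  forward <- function(Xin) {
    H <- tanh(sweep(Xin %*% W1, 2, b1, "+"))
    P <- .softmax(sweep(H %*% W2, 2, b2, "+"))
    list(H = H, P = P)
  }
  history <- data.frame(iteration = integer(0), train_loss = double(0),
                        val_loss = double(0))
  best <- list(loss = Inf, iter = 0L, W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  stall <- 0L
  for (it in seq_len(max_iter)) {
    fw <- forward(Xs[tr, , drop = FALSE])
    delta2 <- (fw$P - Y[tr, , drop = FALSE]) / length(tr)
    gW2 <- t(fw$H) %*% delta2
    gb2 <- colSums(delta2)
    delta1 <- (delta2 %*% t(W2)) * (1 - fw$H^2)
    gW1 <- t(Xs[tr, , drop = FALSE]) %*% delta1
    gb1 <- colSums(delta1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
    for (nm in names(grads)) {
      adam[[nm]]$m <- beta1 * adam[[nm]]$m + (1 - beta1) * grads[[nm]]
      adam[[nm]]$v <- beta2 * adam[[nm]]$v + (1 - beta2) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - beta1^it)
      vhat <- adam[[nm]]$v / (1 - beta2^it)
      step <- learning_rate * mhat / (sqrt(vhat) + eps)
      if (nm == "W1") W1 <- W1 - step
      if (nm == "b1") b1 <- b1 - step
      if (nm == "W2") W2 <- W2 - step
      if (nm == "b2") b2 <- b2 - step
    }
    P_all <- forward(Xs)$P
    tr_loss <- .logloss(P_all[tr, , drop = FALSE], y[tr])
    va_loss <- if (length(val_idx) > 0)
      .logloss(P_all[val_idx, , drop = FALSE], y[val_idx]) else NA_real_
    history <- rbind(history, data.frame(iteration = it, train_loss = tr_loss,
                                         val_loss = va_loss))
    monitor <- if (length(val_idx) > 0) va_loss else tr_loss
    if (monitor < best$loss - 1e-6) {
      best <- list(loss = monitor, iter = it, W1 = W1, b1 = b1,
                   W2 = W2, b2 = b2)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (early_stopping && stall >= patience) break
    }
  }
  list(W1 = best$W1, b1 = best$b1, W2 = best$W2, b2 = best$b2,
       mu = mu, sigma = sigma, K = K, history = history,
       n_iter = best$iter)
}

predict_mlp <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sigma, "/")
  H <- tanh(sweep(Xs %*% fit$W1, 2, fit$b1, "+"))
  .softmax(sweep(H %*% fit$W2, 2, fit$b2, "+"))
}

# Gaussian naive Bayes on the six continuous features, with sklearn-style
# variance smoothing for numerically degenerate columns.
fit_gnb <- function(X, y, K) {
  p <- ncol(X)
  mu <- matrix(0, K, p); va <- matrix(1, K, p)
  prior <- pmax(tabulate(y, nbins = K), 0) / length(y)
  for (k in seq_len(K)) {
    rows <- which(y == k)
    if (length(rows) == 0) next
    mu[k, ] <- colMeans(X[rows, , drop = FALSE])
    va[k, ] <- apply(X[rows, , drop = FALSE], 2, function(v) {
      mean((v - mean(v))^2)
    })
  }
  smoothing <- 1e-9 * max(apply(X, 2, function(v) mean((v - mean(v))^2)), 1e-12)
  va <- va + smoothing
  list(mu = mu, va = va, log_prior = log(pmax(prior, 1e-15)), K = K)
}

predict_gnb <- function(fit, X) {
  n <- nrow(X)
  LL <- matrix(0, n, fit$K)
  for (k in seq_len(fit$K)) {
    LL[, k] <- fit$log_prior[k] + rowSums(
      -0.5 * log(2 * pi * matrix(fit$va[k, ], n, ncol(X), byrow = TRUE)) -
        0.5 * sweep(X, 2, fit$mu[k, ])^2 /
          matrix(fit$va[k, ], n, ncol(X), byrow = TRUE))
  }
  .softmax(LL)
}
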