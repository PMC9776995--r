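# Multiclass gradient boosting with second-order (Newton) leaf values and
# histogram-binned split search — the engine behind both the
# "hist_gradient_boosting" final model and the plain "gradient_boosting"
# comparison entry (which uses enough bins to make splits effectively
# exact on these sample sizes). One regression tree per class per
# iteration on the softmax gradient.

# Quantile binning: per feature, cut points (bin upper edges) plus the
# binned integer matrix. Values above the last cut share the top bin.
.bin_features <- function(X, max_bins) {
  p <- ncol(X)
  cuts <- vector("list", p)
  B <- matrix(1L, nrow = nrow(X), ncol = p)
  for (j in seq_len(p)) {
    u <- sort(unique(X[, j]))
    if (length(u) > max_bins) {
      qs <- quantile(X[, j], probs = seq(0, 1, length.out = max_bins + 1),
                     names = FALSE, type = 7)
      edges <- unique(qs[-c(1, length(qs))])
    } else {
      edges <- if (length(u) > 1) (u[-length(u)] + u[-1]) / 2 else numeric(0)
    }
    cuts[[j]] <- edges
    # right-closed bins: bin b holds x with edges[b-1] < x <= edges[b], so
    # "bin <= b" is exactly "x <= edges[b]" and the raw-value thresholds
    # used at predict time reproduce the training partition.
    B[, j] <- findInterval(X[, j], edges, left.open = TRUE) + 1L
  }
  # dense one-hot indicators per feature: histogram accumulation per node
  # becomes one crossprod (no sorting), cheap at these sample sizes
  onehot <- lapply(seq_len(p), function(j) {
    nb <- length(cuts[[j]]) + 1L
    D <- matrix(0, nrow(X), nb)
    D[cbind(seq_len(nrow(X)), B[, j])] <- 1
    D
  })
  list(cuts = cuts, bins = B, onehot = onehot)
}

# Grow one regression tree on gradients/hessians of the training rows and,
# as a by-product, produce fitted values for ALL rows (train + any
# held-out validation rows ride along through the same partitions).
.grow_boost_tree <- function(binned, g, h, train_idx, all_idx,
                             max_depth, min_leaf, lambda) {
  B <- binned$bins
  cuts <- binned$cuts
  fitted <- numeric(max(all_idx))
  ghw <- cbind(g, h, 1)
  grow <- function(tr_rows, al_rows, depth) {
    G <- sum(g[tr_rows]); H <- sum(h[tr_rows])
    value <- -G / (H + lambda)
    if (depth >= max_depth || length(tr_rows) < 2 * min_leaf) {
      fitted[al_rows] <<- value
      return(list(leaf = TRUE, value = value))
    }
    best <- NULL
    node_ghw <- ghw[tr_rows, , drop = FALSE]
    for (j in seq_len(ncol(B))) {
      nb <- length(cuts[[j]]) + 1L
      if (nb < 2) next
      agg <- crossprod(binned$onehot[[j]][tr_rows, , drop = FALSE], node_ghw)
      cg <- cumsum(agg[, 1]); ch <- cumsum(agg[, 2]); cn <- cumsum(agg[, 3])
      m <- nb
      i <- seq_len(m - 1)
      ok <- cn[i] >= min_leaf & (cn[m] - cn[i]) >= min_leaf
      if (!any(ok)) next
      gain <- cg[i]^2 / (ch[i] + lambda) +
        (cg[m] - cg[i])^2 / (ch[m] - ch[i] + lambda) -
        cg[m]^2 / (ch[m] + lambda)
      gain[!ok] <- -Inf
      t <- which.max(gain)
      if (gain[t] > 1e-12 && (is.null(best) || gain[t] > best$gain)) {
        best <- list(gain = gain[t], feature = j, bin = t)
      }
    }
    if (is.null(best)) {
      fitted[al_rows] <<- value
      return(list(leaf = TRUE, value = value))
    }
    edges <- cuts[[best$feature]]
    thr <- if (best$bin <= length(edges)) edges[best$bin] else Inf
    tl <- B[tr_rows, best$feature] <= best$bin
    al <- B[al_rows, best$feature] <= best$bin
    list(leaf = FALSE, feature = best$feature, threshold = thr,
         left = grow(tr_rows[tl], al_rows[al], depth + 1L),
         right = grow(tr_rows[!tl], al_rows[!al], depth + 1L))
  }
  tree <- grow(train_idx, all_idx, 0L)
  list(tree = tree, fitted = fitted)
}

.predict_boost_tree <- function(node, X) {
  out <- numeric(nrow(X))
  recurse <- function(node, rows) {
    if (length(rows) == 0) return(invisible(NULL))
    if (node$leaf) {
      out[rows] <<- node$value
      return(invisible(NULL))
    }
    go_left <- X[rows, node$feature] <= node$threshold
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
  }
  recurse(node, seq_len(nrow(X)))
  out
}

.softmax <- function(F) {
  F <- F - apply(F, 1, max)
  E <- exp(F)
  E / rowSums(E)
}

.logloss <- function(P, y) {
  mean(-log(pmax(P[cbind(seq_along(y), y)], 1e-15)))
}

# y: integer 1..K over all rows of X. val_idx rows are excluded from tree
# statistics and used for early stopping.
fit_gboost <- function(X, y, K, max_iter = 100L, learning_rate = 0.1,
                       max_depth = 4L, min_leaf = 5L, max_bins = 64L,
                       lambda = 1e-3, early_stopping = TRUE,
                       validation_fraction = 0.1, patience = 10L,
                       seed = 1L) {
  n <- nrow(X)
  set.seed(derive_seed(seed, 101L))
  val_idx <- integer(0)
  if (early_stopping) {
    for (k in seq_len(K)) {
      rows <- which(y == k)
      n_val <- floor(length(rows) * validation_fraction)
      if (n_val >= 1) val_idx <- c(val_idx, sample(rows, n_val))
    }
    if (length(val_idx) < 2) val_idx <- integer(0)  # too small: disable
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  binned <- .bin_features(X, max_bins)
  priors <- pmax(tabulate(y[train_idx], nbins = K) / length(train_idx), 1e-12)
  F0 <- log(priors)
  F <- matrix(F0, nrow = n, ncol = K, byrow = TRUE)
  trees <- vector("list", max_iter)
  history <- data.frame(iteration = integer(0), train_loss = double(0),
                        val_loss = double(0))
  best_loss <- Inf; best_iter <- 0L; stall <- 0L
  for (it in seq_len(max_iter)) {
    P <- .softmax(F)
    iter_trees <- vector("list", K)
    for (k in seq_len(K)) {
      g <- P[, k] - as.numeric(y == k)
      h <- pmax(P[, k] * (1 - P[, k]), 1e-12)
      res <- .grow_boost_tree(binned, g, h, train_idx, seq_len(n),
                              max_depth, min_leaf, lambda)
      iter_trees[[k]] <- res$tree
      F[, k] <- F[, k] + learning_rate * res$fitted
    }
    trees[[it]] <- iter_trees
    P <- .softmax(F)
    tr_loss <- .logloss(P[train_idx, , drop = FALSE], y[train_idx])
    va_loss <- if (length(val_idx) > 0)
      .logloss(P[val_idx, , drop = FALSE], y[val_idx]) else NA_real_
    history <- rbind(history, data.frame(iteration = it, train_loss = tr_loss,
                                         val_loss = va_loss))
    monitor <- if (length(val_idx) > 0) va_loss else tr_loss
    if (monitor < best_loss - 1e-7) {
      best_loss <- monitor; best_iter <- it; stall <- 0L
    } else {
      stall <- stall + 1L
      if (early_stopping && stall >= patience) break
    }
    if (tr_loss < 1e-8) break  # fully fitted; further trees are no-ops
  }
  n_used <- if (early_stopping && best_iter > 0) best_iter else
    max(history$iteration)
  list(trees = trees[seq_len(n_used)], F0 = F0, learning_rate = learning_rate,
       K = K, n_iter = n_used, history = history)
}

predict_gboost <- function(fit, X) {
  n <- nrow(X)
  F <- matrix(fit$F0, nrow = n, ncol = fit$K, byrow = TRUE)
  for (iter_trees in fit$trees) {
    for (k in seq_len(fit$K)) {
      F[, k] <- F[, k] + fit$learning_rate *
        .predict_boost_tree(iter_trees[[k]], X)
    }
  }
  .softmax(F)
}
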