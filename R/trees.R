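# Classification trees (CART, Gini impurity, exact threshold splits) and
# bootstrap-aggregated forests. Pure R: the feature space here is tiny
# (6 columns) and sample sets are small, so vectorized split search is fast.

# Best split of one node. Returns NULL when no admissible split exists.
.best_gini_split <- function(X, y, K, idx, min_leaf, feat_cand) {
  n <- length(idx)
  best <- NULL
  base_counts <- tabulate(y[idx], nbins = K)
  for (j in feat_cand) {
    xj <- X[idx, j]
    ord <- order(xj)
    xs <- xj[ord]
    ys <- y[idx][ord]
    cum <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(n))
    if (n == 1) next
    i <- seq_len(n - 1)
    valid <- xs[i] < xs[i + 1] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    nl <- i
    nr <- n - i
    left <- cum[i, , drop = FALSE]
    right <- matrix(base_counts, nrow = n - 1, ncol = K, byrow = TRUE) - left
    gini_l <- 1 - rowSums((left / nl)^2)
    gini_r <- 1 - rowSums((right / nr)^2)
    score <- (nl * gini_l + nr * gini_r) / n
    score[!valid] <- Inf
    m <- which.min(score)
    if (is.finite(score[m]) && (is.null(best) || score[m] < best$score)) {
      best <- list(score = score[m], feature = j,
                   threshold = (xs[m] + xs[m + 1]) / 2)
    }
  }
  best
}

# Grow a CART tree; nested-list representation.
# mtry = 0 means all features at every node (plain decision tree).
fit_cart <- function(X, y, K, max_depth = 20L, min_leaf = 1L, mtry = 0L) {
  p <- ncol(X)
  grow <- function(idx, depth) {
    counts <- tabulate(y[idx], nbins = K)
    prob <- counts / length(idx)
    pure <- max(counts) == length(idx)
    if (depth >= max_depth || pure || length(idx) < 2 * min_leaf) {
      return(list(leaf = TRUE, prob = prob))
    }
    feat_cand <- if (mtry > 0 && mtry < p) sample.int(p, mtry) else seq_len(p)
    sp <- .best_gini_split(X, y, K, idx, min_leaf, feat_cand)
    if (is.null(sp)) return(list(leaf = TRUE, prob = prob))
    go_left <- X[idx, sp$feature] <= sp$threshold
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = grow(idx[go_left], depth + 1L),
         right = grow(idx[!go_left], depth + 1L))
  }
  grow(seq_len(nrow(X)), 0L)
}

# Per-sample class-probability matrix from one tree.
predict_cart <- function(tree, X) {
  n <- nrow(X)
  K <- length(.find_first_leaf(tree)$prob)
  out <- matrix(0, nrow = n, ncol = K)
  recurse <- function(node, rows) {
    if (length(rows) == 0) return(invisible(NULL))
    if (node$leaf) {
      out[rows, ] <<- matrix(node$prob, nrow = length(rows), ncol = K,
                             byrow = TRUE)
      return(invisible(NULL))
    }
    go_left <- X[rows, node$feature] <= node$threshold
    recurse(node$left, rows[go_left])
    recurse(node$right, rows[!go_left])
  }
  recurse(tree, seq_len(n))
  out
}

.find_first_leaf <- function(node) {
  while (!node$leaf) node <- node$left
  node
}

# Bagged forest of CART trees with per-node feature subsampling.
fit_forest <- function(X, y, K, n_trees = 100L, mtry = NULL,
                       max_depth = 20L, min_leaf = 1L) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  lapply(seq_len(n_trees), function(b) {
    boot <- sample.int(n, n, replace = TRUE)
    fit_cart(X[boot, , drop = FALSE], y[boot], K,
             max_depth = max_depth, min_leaf = min_leaf, mtry = mtry)
  })
}

predict_forest <- function(trees, X) {
  acc <- predict_cart(trees[[1]], X)
  for (t in trees[-1]) acc <- acc + predict_cart(t, X)
  acc / length(trees)
}
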