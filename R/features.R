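# Two-layer moment feature extraction.
#
# Layer 1 embeds the encoded sequence into the smallest square matrix that
# holds it (row-major, zero-padded) and computes three families of 2-D
# moments up to combined order 3: raw moments R_ab, central moments C_ab
# (about the mass centroid), and discrete orthogonal Hahn moments H_ab.
# Layer 2 pools the 30 layer-1 values into six summary features:
# mean, 2nd/3rd/4th central summary moments, minimum, maximum.

#' Encode a DNA sequence as small integers
#'
#' A=1, C=2, G=3, T=4; every other character (N and other ambiguity codes,
#' padding) maps to 0 and contributes no mass to the moments.
#'
#' @param sequence non-empty DNA string (case-insensitive).
#' @return integer vector, one value per input character.
#' @export
encode_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    stop("sequence must be a single non-empty string")
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  out <- unname(codes[chars])
  out[is.na(out)] <- 0L
  out
}

#' Embed a sequence in a square matrix
#'
#' Side length n = ceiling(sqrt(L)); the encoded sequence fills the matrix
#' row-major and the n^2 - L trailing cells are zero.
#'
#' @param sequence non-empty DNA string.
#' @return n x n integer matrix.
#' @export
sequence_to_matrix <- function(sequence) {
  enc <- encode_sequence(sequence)
  n <- ceiling(sqrt(length(enc)))
  padded <- c(enc, integer(n * n - length(enc)))
  matrix(padded, nrow = n, ncol = n, byrow = TRUE)
}

# (a, b) order pairs with a + b <= max_order, lexicographic.
.moment_orders <- function(max_order = 3L) {
  grid <- expand.grid(b = 0:max_order, a = 0:max_order)[, c("a", "b")]
  grid <- grid[grid$a + grid$b <= max_order, , drop = FALSE]
  grid[order(grid$a, grid$b), , drop = FALSE]
}

#' Raw geometric moments of a square matrix
#'
#' R_ab = sum_x sum_y x^a y^b beta_xy with 1-based row index x and column
#' index y, for all a + b <= max_order.
#'
#' @param mat numeric square matrix.
#' @param max_order maximum combined order (default 3).
#' @return named numeric vector `R00, R01, ..., R30` in lexicographic
#'   (a, b) order.
#' @export
raw_moments <- function(mat, max_order = 3L) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  x <- seq_len(n)
  orders <- .moment_orders(max_order)
  vals <- apply(orders, 1, function(o) {
    sum((x^o[["a"]]) %o% (x^o[["b"]]) * mat)
  })
  names(vals) <- paste0("R", orders$a, orders$b)
  vals
}

#' Central moments of a square matrix
#'
#' C_ab = sum_x sum_y (x - xbar)^a (y - ybar)^b beta_xy, where the centroid
#' (xbar, ybar) = (R10/R00, R01/R00). A zero-mass matrix yields centroid
#' (0, 0) and all C_ab = 0 by convention.
#'
#' @inheritParams raw_moments
#' @return list with `centroid` (length-2 numeric) and `central` (named
#'   vector `C00..C30` in lexicographic (a, b) order).
#' @export
central_moments <- function(mat, max_order = 3L) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  x <- seq_len(n)
  mass <- sum(mat)
  orders <- .moment_orders(max_order)
  if (mass <= 0) {
    vals <- rep(0, nrow(orders))
  } else {
    xbar <- sum(x * rowSums(mat)) / mass
    ybar <- sum(x * colSums(mat)) / mass
    vals <- apply(orders, 1, function(o) {
      sum(((x - xbar)^o[["a"]]) %o% ((x - ybar)^o[["b"]]) * mat)
    })
  }
  names(vals) <- paste0("C", orders$a, orders$b)
  list(centroid = if (mass > 0) c(xbar = sum(x * rowSums(mat)) / mass,
                                  ybar = sum(x * colSums(mat)) / mass)
                  else c(xbar = 0, ybar = 0),
       central = vals)
}

#' Weighted-normalized discrete Hahn polynomial basis
#'
#' Builds the orthonormal Hahn basis on the grid x = 0..N-1 by the standard
#' three-term recurrence in the degree, then normalizes each polynomial by
#' its weighted norm: hhat_q(x) = h_q(x) * sqrt(rho(x) / d_q^2). With the
#' default parameters alpha = beta = 0 the weight rho is uniform and the
#' family reduces to the discrete Chebyshev polynomials. Rows satisfy
#' sum_x hhat_p(x) hhat_q(x) = delta_pq.
#'
#' @param N grid size (matrix side), N >= 1.
#' @param alpha_param,beta_param Hahn parameters, each > -1 (default 0).
#' @param max_order highest degree computed (capped at N - 1).
#' @return list with `N`, `alpha_param`, `beta_param`, and `values`: a
#'   (max_order + 1) x N matrix whose row q+1 holds hhat_q(x) for x=0..N-1.
#'   Degrees above N - 1 are not representable and are returned as zero rows.
#' @export
hahn_basis <- function(N, alpha_param = 0, beta_param = 0, max_order = 3L) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != round(N)) {
    stop("N must be a positive integer")
  }
  stopifnot(alpha_param > -1, beta_param > -1)
  N <- as.integer(N)
  x <- 0:(N - 1)
  a <- alpha_param; b <- beta_param
  qmax <- min(max_order, N - 1L)
  # Monic-free recurrence for Hahn polynomials Q_n(x; a, b, N-1)
  # (Q_{n+1} from x Q_n, Q_n, Q_{n-1}); numerically fine for the low
  # degrees used here.
  Q <- matrix(0, nrow = max_order + 1L, ncol = N)
  Q[1, ] <- 1
  if (qmax >= 1) {
    NK <- N - 1
    Qprev <- rep(1, N)
    Qcur <- 1 - ((a + b + 2) * x) / ((a + 1) * NK)  # Q_1
    Q[2, ] <- Qcur
    if (qmax >= 2) {
      for (n in 1:(qmax - 1)) {
        An <- (n + a + b + 1) * (n + a + 1) * (NK - n) /
          ((2 * n + a + b + 1) * (2 * n + a + b + 2))
        Cn <- n * (n + a + b + NK + 1) * (n + b) /
          ((2 * n + a + b) * (2 * n + a + b + 1))
        Qnext <- ((An + Cn - x) * Qcur - Cn * Qprev) / An
        Q[n + 2, ] <- Qnext
        Qprev <- Qcur
        Qcur <- Qnext
      }
    }
  }
  rho <- choose(a + x, x) * choose(b + N - 1 - x, N - 1 - x)
  vals <- matrix(0, nrow = max_order + 1L, ncol = N)
  for (q in 0:qmax) {
    d2 <- sum(Q[q + 1, ]^2 * rho)
    vals[q + 1, ] <- Q[q + 1, ] * sqrt(rho / d2)
  }
  list(N = N, alpha_param = alpha_param, beta_param = beta_param, values = vals)
}

#' Hahn moments of a square matrix
#'
#' H_ab = sum_x sum_y hhat_a(x) hhat_b(y) beta_{x+1, y+1} over the 0-based
#' polynomial grid. Orders above N - 1 are reported as 0.
#'
#' @param mat numeric square matrix.
#' @param basis optional basis from [hahn_basis()] (built on demand).
#' @param max_order maximum combined order (default 3).
#' @return named numeric vector `H00..H30` in lexicographic (a, b) order.
#' @export
hahn_moments <- function(mat, basis = NULL, max_order = 3L) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  if (is.null(basis)) basis <- hahn_basis(n, max_order = max_order)
  stopifnot(basis$N == n)
  H <- basis$values %*% mat %*% t(basis$values)  # H[a+1, b+1]
  orders <- .moment_orders(max_order)
  vals <- H[cbind(orders$a + 1L, orders$b + 1L)]
  names(vals) <- paste0("H", orders$a, orders$b)
  vals
}

#' Layer-1 moment set: raw, central, and Hahn families
#'
#' @param mat square matrix from [sequence_to_matrix()].
#' @return named numeric vector of 30 values: `R00..R30`, `C00..C30`,
#'   `H00..H30` (each family lexicographic in (a, b)).
#' @export
layer1 <- function(mat) {
  c(raw_moments(mat), central_moments(mat)$central, hahn_moments(mat))
}

#' Layer-2 summary: six-feature vector from pooled layer-1 values
#'
#' With hbar = mean(values): M1 = hbar, and M_p = mean((v - hbar)^p) for
#' p = 2, 3, 4 (plain central summary moments, not standardized), plus the
#' minimum and maximum.
#'
#' @param values non-empty numeric vector (the 30 layer-1 values in the
#'   default pipeline).
#' @return named numeric vector `M1, M2, M3, M4, Min, Max`.
#' @export
layer2 <- function(values) {
  if (length(values) == 0) stop("layer2 requires a non-empty value vector")
  m <- mean(values)
  d <- values - m
  c(M1 = m, M2 = mean(d^2), M3 = mean(d^3), M4 = mean(d^4),
    Min = min(values), Max = max(values))
}

#' Extract the six-value feature vector of a sequence
#'
#' layer2(layer1(sequence_to_matrix(sequence))): the pipeline's complete
#' per-sample feature extraction.
#'
#' @param sequence non-empty DNA string.
#' @return named numeric vector `M1, M2, M3, M4, Min, Max`.
#' @export
extract_features <- function(sequence) {
  layer2(layer1(sequence_to_matrix(sequence)))
}

#' Extract features for a whole sample set
#'
#' @param samples data.frame with `sample_id`, `sequence`, and optionally
#'   `label`.
#' @return feature table data.frame (`sample_id`, `M1..Max`, `label`)
#'   matching the [write_feature_table()] schema.
#' @export
extract_feature_table <- function(samples) {
  stopifnot(all(c("sample_id", "sequence") %in% names(samples)))
  feats <- t(vapply(samples$sequence, extract_features, numeric(6),
                    USE.NAMES = FALSE))
  out <- data.frame(sample_id = samples$sample_id, feats,
                    stringsAsFactors = FALSE)
  names(out) <- c("sample_id", .feature_cols)
  out$label <- if ("label" %in% names(samples)) samples$label else NA_character_
  out
}
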