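# Independent oracles kept deliberately naive: brute-force double loops for
# the 2-D moments and direct hypergeometric-series evaluation for the Hahn
# polynomials. They never share code with the implementation they check.

oracle_raw_moment <- function(mat, a, b) {
  n <- nrow(mat)
  acc <- 0
  for (x in seq_len(n)) for (y in seq_len(n)) {
    acc <- acc + x^a * y^b * mat[x, y]
  }
  acc
}

oracle_central_moment <- function(mat, a, b) {
  n <- nrow(mat)
  mass <- oracle_raw_moment(mat, 0, 0)
  if (mass <= 0) return(0)
  xbar <- oracle_raw_moment(mat, 1, 0) / mass
  ybar <- oracle_raw_moment(mat, 0, 1) / mass
  acc <- 0
  for (x in seq_len(n)) for (y in seq_len(n)) {
    acc <- acc + (x - xbar)^a * (y - ybar)^b * mat[x, y]
  }
  acc
}

poch <- function(a, k) if (k == 0) 1 else prod(a + 0:(k - 1))

# Hahn polynomial Q_q(x; alpha, beta, N-1) as a terminating 3F2 sum.
oracle_hahn_Q <- function(q, x, N, alpha = 0, beta = 0) {
  acc <- 0
  for (k in 0:q) {
    acc <- acc + poch(-q, k) * poch(q + alpha + beta + 1, k) * poch(-x, k) /
      (poch(alpha + 1, k) * poch(-(N - 1), k) * factorial(k))
  }
  acc
}

# Weighted-normalized row q of the basis, from the series definition.
oracle_hahn_row <- function(q, N, alpha = 0, beta = 0) {
  xs <- 0:(N - 1)
  Q <- vapply(xs, function(x) oracle_hahn_Q(q, x, N, alpha, beta), 0)
  rho <- choose(alpha + xs, xs) * choose(beta + N - 1 - xs, N - 1 - xs)
  Q * sqrt(rho / sum(Q^2 * rho))
}

random_square_matrix <- function(n) {
  matrix(sample(0:4, n * n, replace = TRUE), n, n)
}
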