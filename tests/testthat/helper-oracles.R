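# Independent oracles, deliberately naive: these never call the package's
# own solver paths.

# random stable matrix with negative diagonal
rand_stable <- function(n, seed, density = 0.6, margin = 0.3) {
  set.seed(seed)
  A <- matrix(rnorm(n * n) * (runif(n * n) < density), n, n)
  A <- A - diag(max(Re(eigen(A)$values)) + margin, n)
  A
}

# brute-force quadrature of the Gramian integrand int e^{At} B B' e^{A't} dt
# (composite Simpson; steps must be even)
quad_gramian <- function(A, B, t_max = 200, steps = 20000) {
  dt <- t_max / steps
  Phi <- as.matrix(Matrix::expm(Matrix::Matrix(A * dt)))
  G <- B
  W <- G %*% t(G)
  for (k in seq_len(steps)) {
    G <- Phi %*% G
    w <- if (k == steps) 1 else if (k %% 2 == 1) 4 else 2
    W <- W + w * G %*% t(G)
  }
  W * dt / 3
}

# dense Kronecker (vec-trick) solve of A W + W A' + Q = 0
kron_lyap <- function(A, Q) {
  n <- nrow(A)
  K <- kronecker(diag(n), A) + kronecker(A, diag(n))
  matrix(solve(K, -as.vector(Q)), n, n)
}

# all-pairs shortest paths, Floyd-Warshall on the influence graph
fw_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] != 0) D[j, i] <- 1 / abs(A[i, j])  # edge j -> i
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# truncated Taylor series matrix exponential
taylor_expm <- function(A, terms = 30) {
  n <- nrow(A)
  S <- diag(n); P <- diag(n)
  for (k in seq_len(terms)) {
    P <- P %*% A / k
    S <- S + P
  }
  S
}

# two-sided Fisher exact p by exhaustive enumeration over tables with the
# observed margins (hypergeometric weights)
fisher_enum <- function(n1, n2, n3, n4) {
  r1 <- n1 + n2; c1 <- n1 + n3; N <- n1 + n2 + n3 + n4
  ks <- max(0, r1 + c1 - N):min(r1, c1)
  probs <- vapply(ks, function(k) dhyper(k, c1, N - c1, r1), numeric(1))
  p_obs <- dhyper(n1, c1, N - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# dense eigen-solve of the Google matrix (PageRank oracle)
pagerank_eigen <- function(A, damping = 0.85) {
  n <- nrow(A)
  Adj <- (A != 0) * 1; diag(Adj) <- 0
  outdeg <- colSums(Adj)
  T <- sweep(Adj, 2, pmax(outdeg, 1), "/")
  T[, outdeg == 0] <- 1 / n
  G <- damping * T + (1 - damping) / n
  ev <- eigen(G)
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v / sum(v)
}

expect_rel_equal <- function(object, expected, tol = 1e-6) {
  expect_lt(norm(object - expected, "F") / max(norm(expected, "F"), 1e-300), tol)
}
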