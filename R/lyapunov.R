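# Continuous Lyapunov solver: A W + W A' + Q = 0 for Hurwitz A.
#
# Two routes behind one interface:
#  - eigen path: A = V D V^-1, solve elementwise in the eigenbasis; O(n^3)
#    per solve after one factorization, and the factorization is reused
#    across the n single-driver solves a pairwise-energy computation needs.
#  - Schur path (Bartels-Stewart on the real Schur form): used when the
#    eigenvector basis is missing or ill conditioned (defective or nearly
#    defective A, e.g. Jordan-like chains), at the cost of an R-level block
#    back-substitution.
# The eigen path is validated once per factorization with a probe solve.

lyap_factor <- function(A) {
  assert_square(A)
  n <- nrow(A)
  fact <- list(A = A, n = n)
  ev <- tryCatch(eigen(A), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(ev)) {
    Vinv <- tryCatch(solve(ev$vectors), error = function(e) NULL)
    if (!is.null(Vinv)) {
      condV <- sqrt(sum(Mod(ev$vectors)^2)) * sqrt(sum(Mod(Vinv)^2))
      if (is.finite(condV) && condV < 1e7) {
        fact$values <- ev$values
        fact$V <- ev$vectors
        fact$Vinv <- Vinv
        fact$S <- outer(ev$values, ev$values, `+`)
        # probe: residual of the solve for Q = I must be small
        W <- lyap_eigen(fact, diag(n))
        res <- norm(A %*% W + W %*% t(A) + diag(n), "F") / sqrt(n)
        ok <- is.finite(res) && res < 1e-7
      }
    }
  }
  fact$mode <- if (ok) "eigen" else "schur"
  if (!ok) {
    sc <- Matrix::Schur(Matrix::Matrix(A, sparse = FALSE))
    fact$U <- as.matrix(sc@Q)
    fact$T <- as.matrix(sc@T)
  }
  fact
}

lyap_eigen <- function(fact, Q) {
  Qt <- fact$Vinv %*% Q %*% t(fact$Vinv)
  X <- -Qt / fact$S
  W <- Re(fact$V %*% X %*% t(fact$V))
  (W + t(W)) / 2
}

# Bartels-Stewart back-substitution for T Y + Y T' = -Qt, T quasi-upper-triangular
lyap_schur <- function(fact, Q) {
  U <- fact$U; Tm <- fact$T
  n <- fact$n
  Qt <- t(U) %*% Q %*% U
  # block partition: 2x2 blocks where the subdiagonal of T is nonzero
  starts <- integer(0)
  i <- 1L
  while (i <= n) {
    starts <- c(starts, i)
    if (i < n && abs(Tm[i + 1L, i]) > 1e-12) i <- i + 2L else i <- i + 1L
  }
  nb <- length(starts)
  ends <- c(starts[-1L] - 1L, n)
  Y <- matrix(0, n, n)
  for (bi in nb:1) {
    I <- starts[bi]:ends[bi]
    for (bj in nb:1) {
      J <- starts[bj]:ends[bj]
      R <- -Qt[I, J, drop = FALSE]
      if (ends[bi] < n) {
        K <- (ends[bi] + 1L):n
        R <- R - Tm[I, K, drop = FALSE] %*% Y[K, J, drop = FALSE]
      }
      if (ends[bj] < n) {
        L <- (ends[bj] + 1L):n
        R <- R - Y[I, L, drop = FALSE] %*% t(Tm[J, L, drop = FALSE])
      }
      # small Sylvester: T_II Y_IJ + Y_IJ T_JJ' = R  (<= 2x2 blocks)
      Tii <- Tm[I, I, drop = FALSE]; Tjj <- Tm[J, J, drop = FALSE]
      K2 <- kronecker(diag(length(J)), Tii) + kronecker(Tjj, diag(length(I)))
      Y[I, J] <- matrix(solve(K2, as.vector(R)), length(I), length(J))
    }
  }
  W <- U %*% Y %*% t(U)
  (W + t(W)) / 2
}

#' Solve the continuous Lyapunov equation
#'
#' Solves `A W + W A' + Q = 0` for symmetric `W`, the infinite-horizon
#' Gramian-type equation of a stable linear system. `A` must be Hurwitz.
#'
#' @param A square Hurwitz matrix.
#' @param Q symmetric right-hand side.
#' @param fact optional factorization from an earlier solve with the same
#'   `A` (internal reuse).
#' @return Symmetric matrix `W`.
#' @export
lyap_solve <- function(A, Q, fact = NULL) {
  assert_square(A)
  if (spectral_abscissa(A) >= -1e-9)
    stop_tc("A must be Hurwitz for the infinite-horizon Lyapunov equation",
            class = "tc_stability_error")
  if (is.null(fact)) fact <- lyap_factor(A)
  if (fact$mode == "eigen") lyap_eigen(fact, Q) else lyap_schur(fact, Q)
}

# diagonal entries W^{(i)}_jj of every single-driver Gramian, as a matrix
# G[i, j]; also the building block for pairwise energies and p-centrality.
# weights: per-driver accessibility beta_i (scales G[i, ] by beta_i^2).
single_driver_gramian_diags <- function(A, fact = NULL, weights = NULL) {
  n <- nrow(A)
  if (is.null(fact)) fact <- lyap_factor(A)
  G <- matrix(0, n, n)
  if (fact$mode == "eigen") {
    V <- fact$V; S <- fact$S
    for (i in seq_len(n)) {
      b <- fact$Vinv[, i]
      X <- -(b %o% b) / S
      G[i, ] <- pmax(Re(rowSums((V %*% X) * V)), 0)
    }
  } else {
    for (i in seq_len(n)) {
      Q <- matrix(0, n, n); Q[i, i] <- 1
      G[i, ] <- pmax(diag(lyap_schur(fact, Q)), 0)
    }
  }
  if (!is.null(weights)) G <- G * weights^2
  G
}
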