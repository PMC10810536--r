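# Free dynamics of the linear model: stationary covariance / model FC,
# perturbation propagation and response peak times.

#' Stationary functional connectivity of a stable linear model
#'
#' For `dx/dt = A x + noise` with white state noise of covariance
#' `sigma2 * I`, the stationary covariance solves
#' `A Sigma + Sigma A' + sigma2 I = 0`; the model functional connectivity is
#' its correlation matrix. Correlations do not depend on `sigma2`.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param sigma2 state-noise variance (> 0).
#' @return A list of class `tc_fc` with fields `F` (correlations, unit
#'   diagonal) and `sigma` (stationary covariance).
#' @export
stationary_fc <- function(ec, sigma2 = 1) {
  ec <- as_ec(ec)
  assert_scalar_num(sigma2, "sigma2", 0, strict_lower = TRUE)
  n <- nrow(ec$A)
  Sigma <- lyap_solve(ec$A, diag(sigma2, n))
  F <- stats::cov2cor(Sigma)
  F <- (F + t(F)) / 2
  diag(F) <- 1
  F[F > 1] <- 1; F[F < -1] <- -1
  structure(list(F = F, sigma = Sigma), class = "tc_fc")
}

#' Free response to a unit perturbation of one node
#'
#' Evolves `dx/dt = A x` from `x(0) = e_source` on a uniform grid, i.e.
#' returns `exp(A t) e_source` at each grid time. For stable dynamics the
#' response decays to zero.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param source node index (1-based) receiving the initial unit perturbation.
#' @param t_max,dt grid extent and step (TR units), `0 < dt < t_max`.
#' @return Matrix with one row per grid time (attribute `time`) and one
#'   column per node.
#' @export
simulate_free_response <- function(ec, source, t_max = 100, dt = 0.1) {
  ec <- as_ec(ec)
  n <- nrow(ec$A)
  if (!is.numeric(source) || length(source) != 1L || source < 1 || source > n)
    stop_tc("source index out of range", class = "tc_index_error")
  if (dt <= 0 || dt >= t_max)
    stop_tc("need 0 < dt < t_max", class = "tc_param_error")
  times <- seq(0, t_max, by = dt)
  Phi <- expm_d(ec$A * dt)
  X <- matrix(0, length(times), n)
  x <- numeric(n); x[source] <- 1
  X[1, ] <- x
  for (k in 2:length(times)) {
    x <- Phi %*% x
    X[k, ] <- x
  }
  attr(X, "time") <- times
  X
}

#' Peak times of pairwise perturbation responses
#'
#' For every ordered pair (source i, responder j != i), the grid time at
#' which `|[exp(A t)]_{ji}|` is maximal. Pairs whose response never exceeds
#' `tol` are `NaN` (no propagation); the mean over defined entries is
#' attached as attribute `mean_peak_time` together with the `NaN` count.
#'
#' @inheritParams simulate_free_response
#' @param tol responses below this absolute value never count as peaks.
#' @return `n x n` matrix `P` with `P[j, i]` the peak time of node `j`'s
#'   response to a perturbation at node `i`; diagonal `NaN`.
#' @export
peak_response_times <- function(ec, t_max = 100, dt = 0.1, tol = 1e-12) {
  ec <- as_ec(ec)
  n <- nrow(ec$A)
  if (dt <= 0 || dt >= t_max)
    stop_tc("need 0 < dt < t_max", class = "tc_param_error")
  times <- seq(0, t_max, by = dt)
  Phi <- expm_d(ec$A * dt)
  M <- diag(n)
  best <- matrix(0, n, n)    # running max of |[e^{At}]_{ji}|
  argt <- matrix(NaN, n, n)
  for (k in 2:length(times)) {
    M <- Phi %*% M
    upd <- abs(M) > best & abs(M) > tol
    if (any(upd)) {
      best[upd] <- abs(M)[upd]
      argt[upd] <- times[k]
    }
  }
  diag(argt) <- NaN
  n_nan <- sum(is.nan(argt)) - n
  attr(argt, "mean_peak_time") <- mean(argt[!is.nan(argt)])
  attr(argt, "n_undefined") <- n_nan
  argt
}

#' Propagator coupling at a fixed horizon
#'
#' The matrix exponential `exp(A T)`: entry `[j, i]` integrates the direct
#' and indirect influence of node `i` on node `j` over a timescale `T`
#' (TR units), and is the coupling score that best explains pairwise control
#' energies.
#'
#' @param ec a `tc_ec` (or square matrix).
#' @param T horizon in TR units (> 0); 10 TR by default, the timescale over
#'   which a local perturbation fully propagates in this model class.
#' @return The `n x n` matrix `exp(A T)`.
#' @export
propagator_coupling <- function(ec, T = 10) {
  A <- ec_matrix(ec)
  assert_scalar_num(T, "T", 0, strict_lower = TRUE)
  expm_d(A * T)
}
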