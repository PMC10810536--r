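# Controllability machinery: Gramians, worst-case and pairwise energies,
# minimum-energy input synthesis and controlled simulation.

#' Driver set
#'
#' @param indices distinct node indices (1-based) receiving external input;
#'   each defines one column of the input matrix `B`.
#' @param weights optional per-driver accessibility values in `(0, 1]`
#'   (entries of `B`); default all 1.
#' @return A list of class `tc_drivers`.
#' @export
driver_set <- function(indices, weights = NULL) {
  indices <- as.integer(indices)
  if (length(indices) == 0)
    stop_tc("driver set must be non-empty", class = "tc_param_error")
  if (anyDuplicated(indices))
    stop_tc("driver indices must be distinct", class = "tc_param_error")
  if (is.null(weights)) weights <- rep(1, length(indices))
  if (length(weights) != length(indices) || any(weights <= 0) || any(weights > 1))
    stop_tc("weights must lie in (0, 1], one per driver", class = "tc_param_error")
  structure(list(indices = indices, weights = as.numeric(weights)),
            class = "tc_drivers")
}

#' Target set
#'
#' @param indices distinct node indices (1-based) whose activity is to be
#'   controlled (rows of the output selector `C`).
#' @return A list of class `tc_targets`.
#' @export
target_set <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0)
    stop_tc("target set must be non-empty", class = "tc_param_error")
  if (anyDuplicated(indices))
    stop_tc("target indices must be distinct", class = "tc_param_error")
  structure(list(indices = indices), class = "tc_targets")
}

as_drivers <- function(x) if (inherits(x, "tc_drivers")) x else driver_set(x)
as_targets <- function(x) if (inherits(x, "tc_targets")) x else target_set(x)

check_indices <- function(idx, n, what) {
  if (any(idx < 1L | idx > n))
    stop_tc("%s index out of range [1, %d]", what, n, class = "tc_index_error")
}

driver_matrix <- function(drivers, n) {
  B <- matrix(0, n, length(drivers$indices))
  B[cbind(drivers$indices, seq_along(drivers$indices))] <- drivers$weights
  B
}

new_gramian <- function(kind, W, epsilon = 1e-12, method = "lyapunov",
                        horizon = Inf) {
  W <- (W + t(W)) / 2
  ev <- sort(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  lmin <- ev[1]
  structure(list(kind = kind, W = W, eigenvalues = ev, lambda_min = lmin,
                 practically_controllable = lmin > epsilon, epsilon = epsilon,
                 method = method, horizon = horizon),
            class = "tc_gramian")
}

#' @export
print.tc_gramian <- function(x, ...) {
  cat(sprintf("<tc_gramian> %s (%s, horizon %s): %dx%d, lambda_min = %.3g, practically controllable: %s\n",
              x$kind, x$method, if (is.finite(x$horizon)) format(x$horizon) else "Inf",
              nrow(x$W), ncol(x$W), x$lambda_min, x$practically_controllable))
  invisible(x)
}

check_stable_for_gramian <- function(A) {
  if (spectral_abscissa(A) >= -1e-6)
    stop_tc("infinite-horizon Gramian undefined: A is not stable (spectral abscissa >= -1e-6)",
            class = "tc_stability_error")
}

#' Infinite-horizon controllability Gramian
#'
#' Solves `A W + W A' + B B' = 0`, the Lyapunov form of
#' `W = integral exp(A t) B B' exp(A' t) dt`. `B` has one column per driver
#' with its accessibility weight at the driver's row. Practical
#' controllability requires `lambda_min(W) > epsilon`.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param drivers a [driver_set()] or plain index vector. Passing a full
#'   `n x r` matrix as `drivers` uses it directly as `B` (e.g. an all-ones
#'   broadcast column).
#' @param epsilon numerical zero threshold for the minimum eigenvalue.
#' @param fact internal: reused Lyapunov factorization.
#' @return A `tc_gramian` (kind `"controllability"`).
#' @export
controllability_gramian <- function(ec, drivers, epsilon = 1e-12, fact = NULL) {
  ec <- as_ec(ec)
  check_stable_for_gramian(ec$A)
  n <- nrow(ec$A)
  if (is.matrix(drivers)) {
    if (nrow(drivers) != n) stop_tc("B has wrong row count", class = "tc_shape_error")
    B <- drivers
  } else {
    drivers <- as_drivers(drivers)
    check_indices(drivers$indices, n, "driver")
    B <- driver_matrix(drivers, n)
  }
  W <- lyap_solve(ec$A, B %*% t(B), fact = fact)
  new_gramian("controllability", W, epsilon)
}

#' Infinite-horizon observability Gramian
#'
#' Solves `A' M + M A + C' C = 0` with `C` the 0/1 target selector; by
#' duality this is the controllability Gramian of the transposed system.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param targets a [target_set()] or plain index vector.
#' @param epsilon numerical zero threshold.
#' @return A `tc_gramian` (kind `"observability"`).
#' @export
observability_gramian <- function(ec, targets, epsilon = 1e-12) {
  ec <- as_ec(ec)
  check_stable_for_gramian(ec$A)
  n <- nrow(ec$A)
  targets <- as_targets(targets)
  check_indices(targets$indices, n, "target")
  CtC <- matrix(0, n, n)
  CtC[cbind(targets$indices, targets$indices)] <- 1
  M <- lyap_solve(t(ec$A), CtC)
  g <- new_gramian("observability", M, epsilon)
  g
}

#' Target (output) controllability Gramian
#'
#' Projects a full controllability Gramian onto a target set:
#' `W_C = C W C'`, the principal submatrix of `W` on the target indices.
#'
#' @param full a `tc_gramian` of kind `"controllability"`.
#' @param targets a [target_set()] or plain index vector.
#' @return A `tc_gramian` (kind `"target"`).
#' @export
target_gramian <- function(full, targets) {
  stopifnot(inherits(full, "tc_gramian"))
  if (full$kind != "controllability")
    stop_tc("target_gramian needs a controllability Gramian", class = "tc_param_error")
  targets <- as_targets(targets)
  check_indices(targets$indices, nrow(full$W), "target")
  Wc <- full$W[targets$indices, targets$indices, drop = FALSE]
  g <- new_gramian("target", Wc, full$epsilon, full$method, full$horizon)
  g
}

#' Worst-case control energy from a Gramian
#'
#' The energy needed to steer along the least controllable eigendirection:
#' `1 / lambda_min(W)` for unit-norm boundary states, or `+Inf` when the
#' minimum eigenvalue is at or below the numerical-zero threshold (not
#' practically controllable).
#'
#' @param g a `tc_gramian`.
#' @return A list of class `tc_energy` with `energy`, `log10_energy`,
#'   `n_drivers`/`n_targets` (when known) and `basis = "worst_case"`.
#' @export
worst_case_energy <- function(g) {
  stopifnot(inherits(g, "tc_gramian"))
  e <- if (g$lambda_min > g$epsilon) 1 / g$lambda_min else Inf
  structure(list(energy = e, log10_energy = log10(e),
                 n_drivers = NA_integer_, n_targets = nrow(g$W),
                 basis = "worst_case"),
            class = "tc_energy")
}

#' @export
print.tc_energy <- function(x, ...) {
  cat(sprintf("<tc_energy> %s: E = %.4g (log10 = %.3f)\n",
              x$basis, x$energy, x$log10_energy))
  invisible(x)
}

# worst-case target energy for one (drivers, targets) pair; fact reusable
target_control_energy <- function(ec, drivers, targets, fact = NULL,
                                  epsilon = 1e-12) {
  g <- controllability_gramian(ec, drivers, epsilon = epsilon, fact = fact)
  gt <- target_gramian(g, targets)
  worst_case_energy(gt)$energy
}

#' All single-driver single-target control energies
#'
#' `E[i, j]` is the minimum energy to steer target node `j` with driver
#' node `i` alone: `E_{i->j} = 1 / W^{(i)}_{jj}` where `W^{(i)}` is the
#' single-driver Gramian of node `i` -- equivalently
#' `1 / integral [exp(A t)]_{ji}^2 dt`. One Lyapunov factorization serves
#' all `n` drivers. Entries with numerically zero denominator are `+Inf`
#' (no propagation from `i` to `j`).
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param weights optional accessibility vector `beta` (length `n`); driver
#'   `i`'s energies scale exactly by `1 / beta_i^2`.
#' @return `n x n` numeric matrix of energies (possibly `+Inf`).
#' @export
pairwise_energies <- function(ec, weights = NULL) {
  ec <- as_ec(ec)
  check_stable_for_gramian(ec$A)
  G <- single_driver_gramian_diags(ec$A, weights = weights)
  E <- ifelse(G <= 1e-300, Inf, 1 / G)
  dimnames(E) <- list(driver = NULL, target = NULL)
  E
}

#' Finite-horizon controllability Gramian
#'
#' `W(t_f) = integral_0^{t_f} exp(A t) B B' exp(A' t) dt` by composite
#' trapezoid on a uniform grid, with the propagator advanced by exact
#' exponential stepping. Monotone non-decreasing in `t_f` (Loewner order)
#' and convergent to the Lyapunov solution for stable `A`.
#'
#' @inheritParams controllability_gramian
#' @param t_f horizon (> 0), TR units.
#' @param dt grid step (0 < dt < t_f).
#' @return A `tc_gramian` (kind `"controllability"`, method `"finite_horizon"`).
#' @export
finite_horizon_gramian <- function(ec, drivers, t_f, dt = t_f / 1000,
                                   epsilon = 1e-12) {
  ec <- as_ec(ec, require_stable = FALSE)
  n <- nrow(ec$A)
  if (!is.numeric(t_f) || t_f <= 0 || dt <= 0 || dt >= t_f)
    stop_tc("need 0 < dt < t_f", class = "tc_param_error")
  if (is.matrix(drivers)) B <- drivers else {
    drivers <- as_drivers(drivers)
    check_indices(drivers$indices, n, "driver")
    B <- driver_matrix(drivers, n)
  }
  times <- seq(0, t_f, by = dt)
  Phi <- expm_d(ec$A * dt)
  G <- B                      # exp(A t_k) B
  W <- 0.5 * (G %*% t(G))     # trapezoid end weight at t = 0
  for (k in 2:length(times)) {
    G <- Phi %*% G
    w <- if (k == length(times)) 0.5 else 1
    W <- W + w * (G %*% t(G))
  }
  new_gramian("controllability", W * dt, epsilon,
              method = "finite_horizon", horizon = t_f)
}

#' Minimum-energy control input for a target steering problem
#'
#' Synthesizes the classical minimum-energy open-loop input
#' `u*(t) = B' exp(A' (t_f - t)) C' [C W(t_f) C']^{-1} (y_f - C exp(A t_f) x_0)`
#' on a uniform grid, steering the target outputs `y = C x` from the free
#' evolution of `x_0` to `y_f` at time `t_f`. Its realized energy (trapezoid
#' of `||u||^2`) equals the quadratic form of the target-Gramian inverse up
#' to discretization.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param drivers,targets driver and target sets (or index vectors).
#' @param x0 initial full state (length `n`).
#' @param yf desired target outputs (length `n_t`).
#' @param t_f control horizon, TR units (default 50).
#' @param dt grid step (default `t_f / 5000`).
#' @param max_condition reject problems whose finite-horizon target Gramian
#'   has a larger condition number (not target controllable in practice).
#' @return A list of class `tc_control_input`: `time_grid`, `u`
#'   (grid x drivers), `realized_energy`, `quadratic_form_energy`, `x0`,
#'   `yf`, plus the drivers/targets used.
#' @export
min_energy_input <- function(ec, drivers, targets, x0, yf, t_f = 50,
                             dt = t_f / 5000, max_condition = 1e12) {
  ec <- as_ec(ec)
  n <- nrow(ec$A)
  drivers <- as_drivers(drivers); targets <- as_targets(targets)
  check_indices(drivers$indices, n, "driver")
  check_indices(targets$indices, n, "target")
  if (length(x0) != n) stop_tc("x0 has wrong length", class = "tc_shape_error")
  if (length(yf) != length(targets$indices))
    stop_tc("yf must have one entry per target", class = "tc_shape_error")
  B <- driver_matrix(drivers, n)
  tix <- targets$indices
  Wg <- finite_horizon_gramian(ec, drivers, t_f = t_f, dt = dt)
  Wc <- Wg$W[tix, tix, drop = FALSE]
  evc <- eigen(Wc, symmetric = TRUE, only.values = TRUE)$values
  if (min(evc) <= 0 || max(evc) / min(evc) > max_condition)
    stop_tc("target set not practically controllable from these drivers: lambda_min(C W C') = %.3g",
            min(evc), class = "tc_controllability_error")
  times <- seq(0, t_f, by = dt)
  K <- length(times)
  eAtf_x0 <- drop(expm_d(ec$A * t_f) %*% x0)
  eta <- solve(Wc, yf - eAtf_x0[tix])
  # Z_k = exp(A'(t_f - t_k)) C' eta, iterated backwards from t = t_f
  PhiT <- expm_d(t(ec$A) * dt)
  z <- numeric(n); z[tix] <- eta
  U <- matrix(0, K, ncol(B))
  U[K, ] <- drop(t(B) %*% z)
  for (k in (K - 1):1) {
    z <- PhiT %*% z
    U[k, ] <- drop(t(B) %*% z)
  }
  sq <- rowSums(U^2)
  realized <- sum((sq[-1] + sq[-K]) / 2) * dt
  structure(list(time_grid = times, u = U, realized_energy = realized,
                 quadratic_form_energy = drop(crossprod(yf - eAtf_x0[tix],
                                                        solve(Wc, yf - eAtf_x0[tix]))),
                 x0 = x0, yf = yf, drivers = drivers, targets = targets),
            class = "tc_control_input")
}

#' Simulate the controlled system
#'
#' Integrates `dx/dt = A x + B u` on the input's grid using exact
#' exponential stepping with piecewise-linear interpolation of `u` (Van
#' Loan block-matrix discretization), so the only error is the linear
#' interpolation of the input between grid points.
#'
#' @param ec a `tc_ec` (or square matrix).
#' @param drivers driver set matching the input's columns.
#' @param input a `tc_control_input`, or a list with `time_grid` (uniform)
#'   and `u` (grid x drivers matrix).
#' @param x0 initial state.
#' @return Matrix of states, one row per grid time (attribute `time`).
#' @export
simulate_controlled <- function(ec, drivers, input, x0) {
  ec <- as_ec(ec, require_stable = FALSE)
  n <- nrow(ec$A)
  drivers <- as_drivers(drivers)
  check_indices(drivers$indices, n, "driver")
  B <- driver_matrix(drivers, n)
  times <- input$time_grid
  U <- input$u
  r <- ncol(B)
  if (!is.matrix(U) || ncol(U) != r || nrow(U) != length(times))
    stop_tc("input grid/driver mismatch", class = "tc_shape_error")
  if (length(x0) != n) stop_tc("x0 has wrong length", class = "tc_shape_error")
  dt <- times[2] - times[1]
  # exp of the Van Loan block [[A, B, 0], [0, 0, I], [0, 0, 0]] * dt gives
  # Phi, G1 = int e^{A(dt-s)} B ds, and G2 for the input slope term
  Mb <- matrix(0, n + 2 * r, n + 2 * r)
  Mb[1:n, 1:n] <- ec$A
  Mb[1:n, n + (1:r)] <- B
  Mb[n + (1:r), n + r + (1:r)] <- diag(r)
  Eb <- expm_d(Mb * dt)
  Phi <- Eb[1:n, 1:n, drop = FALSE]
  G1 <- Eb[1:n, n + (1:r), drop = FALSE]
  G2 <- Eb[1:n, n + r + (1:r), drop = FALSE]
  K <- length(times)
  X <- matrix(0, K, n)
  x <- as.numeric(x0)
  X[1, ] <- x
  for (k in 1:(K - 1)) {
    slope <- (U[k + 1, ] - U[k, ]) / dt
    x <- drop(Phi %*% x + G1 %*% U[k, ] + G2 %*% slope)
    X[k + 1, ] <- x
  }
  attr(X, "time") <- times
  X
}
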