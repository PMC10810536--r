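# Gramians, energies, minimum-energy inputs, controlled simulation

test_that("Lyapunov Gramians match quadrature and Kronecker oracles", {
  for (n in 3:8) {
    A <- rand_stable(n, seed = n)
    B <- matrix(0, n, 2); B[1, 1] <- 1; B[min(3, n), 2] <- 1
    W <- controllability_gramian(A, driver_set(c(1, min(3, n))))$W
    expect_rel_equal(W, quad_gramian(A, B), tol = 1e-6)
    expect_rel_equal(W, kron_lyap(A, B %*% t(B)), tol = 1e-8)
  }
  # Schur fallback on a defective matrix agrees with Kronecker
  A <- matrix(c(-1, 2, 0, -1), 2, 2)
  expect_rel_equal(lyap_solve(A, diag(2)), kron_lyap(A, diag(2)), tol = 1e-10)
  expect_error(controllability_gramian(diag(2), driver_set(1)),
               class = "tc_stability_error")
  expect_error(driver_set(integer(0)), class = "tc_param_error")
})

test_that("scalar closed forms hold", {
  g <- controllability_gramian(matrix(-0.5), driver_set(1))
  expect_equal(g$W, matrix(1), tolerance = 1e-12)   # int exp(-t) dt = 1
  expect_true(g$practically_controllable)
  expect_equal(worst_case_energy(g)$energy, 1, tolerance = 1e-12)
  m <- observability_gramian(matrix(-0.5), target_set(1))
  expect_equal(m$W, matrix(1), tolerance = 1e-12)
})

test_that("observability duality and quadrature agreement", {
  A <- rand_stable(5, seed = 21)
  for (i in 1:3) {
    M <- observability_gramian(A, target_set(i))$W
    Wdual <- controllability_gramian(t(A), driver_set(i))$W
    expect_equal(M, Wdual, tolerance = 1e-12)
    C <- matrix(0, 5, 1); C[i] <- 1
    expect_rel_equal(M, quad_gramian(t(A), C), tol = 1e-6)
  }
})

test_that("target Gramian is the principal submatrix; eigen-interlacing holds", {
  A <- rand_stable(6, seed = 30)
  g <- controllability_gramian(A, driver_set(c(1, 4)))
  expect_equal(target_gramian(g, target_set(1:6))$W, g$W)
  expect_equal(target_gramian(g, target_set(3))$W, g$W[3, 3, drop = FALSE])
  for (seed in 1:20) {
    A <- rand_stable(6, seed = 100 + seed)
    g <- controllability_gramian(A, driver_set(sample(6, 2)))
    tix <- sort(sample(6, 3))
    expect_gte(target_gramian(g, tix)$lambda_min, g$lambda_min - 1e-12)
  }
  expect_error(target_gramian(g, target_set(9)), class = "tc_index_error")
})

test_that("worst-case energy is 1/lambda_min with epsilon thresholding and driver monotonicity", {
  g <- controllability_gramian(matrix(-0.5), driver_set(1))
  expect_equal(worst_case_energy(g)$energy, 1)
  fake <- g; fake$lambda_min <- 1e-13
  e <- worst_case_energy(fake)
  expect_identical(e$energy, Inf)
  expect_identical(e$log10_energy, Inf)
  # adding a driver never increases worst-case energy
  for (seed in 1:25) {
    A <- rand_stable(7, seed = 300 + seed)
    d1 <- sample(7, 2)
    extra <- sample(setdiff(1:7, d1), 1)
    e1 <- worst_case_energy(controllability_gramian(A, driver_set(d1)))$energy
    e2 <- worst_case_energy(controllability_gramian(A, driver_set(c(d1, extra))))$energy
    expect_lte(e2, e1 * (1 + 1e-8))
  }
})

test_that("pairwise energies: closed forms, Gramian-path equivalence, accessibility scaling", {
  # decoupled: only self-control possible, E_ii = 2a
  E <- pairwise_energies(-0.5 * diag(4))
  expect_equal(diag(E), rep(1, 4), tolerance = 1e-10)
  expect_true(all(is.infinite(E[row(E) != col(E)])))
  # chain closed form: E_{1->2} = 4 / c^2
  for (c_ in c(0.5, 2, 3)) {
    A <- matrix(c(-1, c_, 0, -1), 2, 2)
    expect_equal(pairwise_energies(A)[1, 2], 4 / c_^2, tolerance = 1e-8)
  }
  # equivalence with the general Gramian path on random pairs
  A <- rand_stable(8, seed = 77)
  E <- pairwise_energies(A)
  set.seed(1)
  for (k in 1:30) {
    i <- sample(8, 1); j <- sample(8, 1)
    g <- target_gramian(controllability_gramian(A, driver_set(i)), target_set(j))
    expect_equal(E[i, j], 1 / g$W[1, 1], tolerance = 1e-8 * abs(E[i, j]))
  }
  # beta scaling: E multiplies by beta^-2 exactly
  beta <- seq(0.2, 0.9, length.out = 8)
  Eb <- pairwise_energies(A, weights = beta)
  expect_equal(Eb, E / beta^2, tolerance = 1e-10)
})

test_that("finite-horizon Gramian converges to the Lyapunov solution monotonically", {
  expect_equal(finite_horizon_gramian(matrix(-0.5), driver_set(1), t_f = 20,
                                      dt = 0.002)$W[1, 1],
               1 - exp(-20), tolerance = 1e-5)
  A <- rand_stable(4, seed = 50)
  Winf <- controllability_gramian(A, driver_set(c(1, 2)))$W
  errs <- vapply(c(10, 20, 50), function(tf)
    norm(finite_horizon_gramian(A, driver_set(c(1, 2)), t_f = tf,
                                dt = 0.01)$W - Winf, "F"), numeric(1))
  expect_true(all(diff(errs) < 0))
  # doubling the horizon never decreases any eigenvalue (PSD increment)
  W1 <- finite_horizon_gramian(A, driver_set(1), t_f = 5, dt = 0.01)$W
  W2 <- finite_horizon_gramian(A, driver_set(1), t_f = 10, dt = 0.01)$W
  expect_gte(min(eigen(W2 - W1, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(finite_horizon_gramian(A, driver_set(1), t_f = 1, dt = 2),
               class = "tc_param_error")
})

test_that("minimum-energy input steers the target outputs and matches the energy bound", {
  # nothing to steer
  A <- rand_stable(4, seed = 60, density = 1)
  z <- min_energy_input(A, driver_set(1:2), target_set(3), x0 = rep(0, 4), yf = 0,
                        t_f = 10, dt = 0.01)
  expect_equal(max(abs(z$u)), 0)
  expect_equal(z$realized_energy, 0)
  # forward-simulation verification + quadratic-form identity + Eq-14 bound
  set.seed(8)
  for (rep in 1:5) {
    A <- rand_stable(6, seed = 600 + rep, density = 1, margin = 0.4)
    dr <- driver_set(sort(sample(6, 2)))
    tg <- target_set(sort(sample(6, 2)))
    yf <- rnorm(2); yf <- yf / sqrt(sum(yf^2))
    inp <- min_energy_input(A, dr, tg, x0 = rep(0, 6), yf = yf,
                            t_f = 30, dt = 30 / 10000)
    X <- simulate_controlled(A, dr, inp, rep(0, 6))
    expect_lt(sqrt(sum((X[nrow(X), tg$indices] - yf)^2)), 1e-4)
    expect_lt(abs(inp$realized_energy / inp$quadratic_form_energy - 1), 0.01)
    Wc <- finite_horizon_gramian(A, dr, t_f = 30, dt = 30 / 10000)$W[tg$indices, tg$indices]
    bound <- 1 / min(eigen(Wc, symmetric = TRUE, only.values = TRUE)$values)
    expect_lte(inp$realized_energy, bound * 1.01)
  }
})

test_that("controlled simulation reproduces free response and the scalar closed form", {
  A <- rand_stable(5, seed = 70)
  grid <- seq(0, 5, by = 0.01)
  inp <- list(time_grid = grid, u = matrix(0, length(grid), 1))
  x0 <- rnorm(5)
  X <- simulate_controlled(A, driver_set(2), inp, x0)
  free <- t(vapply(grid, function(t)
    drop(as.matrix(Matrix::expm(Matrix::Matrix(A * t))) %*% x0), numeric(5)))
  expect_lt(max(abs(X - free)), 1e-8)
  # scalar A = -1, constant u = 1: x(t) = x0 e^-t + 1 - e^-t
  inp1 <- list(time_grid = grid, u = matrix(1, length(grid), 1))
  X1 <- simulate_controlled(matrix(-1), driver_set(1), inp1, 2)
  expect_equal(X1[, 1], 2 * exp(-grid) + 1 - exp(-grid), tolerance = 1e-9)
  expect_error(simulate_controlled(A, driver_set(1:2), inp1, rnorm(5)),
               class = "tc_shape_error")
})
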