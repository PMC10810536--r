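# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tc_error")))
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_tc("`%s` must be a single finite number", name, class = "tc_param_error")
  if ((strict_lower && x <= lower) || (!strict_lower && x < lower) || x > upper)
    stop_tc("`%s` = %g is out of range", name, x, class = "tc_param_error")
  invisible(x)
}

assert_square <- function(A, name = "A") {
  if (!is.matrix(A) || nrow(A) != ncol(A) || !is.numeric(A))
    stop_tc("`%s` must be a square numeric matrix", name, class = "tc_shape_error")
  if (any(!is.finite(A)))
    stop_tc("`%s` contains non-finite entries", name, class = "tc_param_error")
  invisible(A)
}

# dense matrix exponential (Matrix::expm, scaling-and-squaring)
expm_d <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A, sparse = FALSE)))
}

#' Spectral abscissa of a square matrix
#'
#' The maximum real part of the eigenvalues. Negative values mean the linear
#' dynamics `dx/dt = A x` are stable (Hurwitz).
#'
#' @param A square numeric matrix.
#' @return A single number, `max(Re(eigen(A)$values))`.
#' @export
spectral_abscissa <- function(A) {
  assert_square(A)
  max(Re(eigen(A, only.values = TRUE)$values))
}
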