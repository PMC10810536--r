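# The effective connectome container and its stability plumbing.
#
# A[i, j] is the directed influence of node j on node i, in units of 1/TR,
# for the linear latent dynamics dx/dt = A x (+ noise / input).

#' Construct an effective connectome
#'
#' @param A square numeric matrix; `A[i, j]` is the directed influence of
#'   node `j` on node `i` in units of 1/TR. Must have strictly negative
#'   diagonal and negative spectral abscissa (stable dynamics).
#' @param nodes a [node_table()]; defaults to a synthetic table matching
#'   `nrow(A)` when the default 74-node partition does not apply.
#' @param subject_id character label.
#' @param tr_seconds repetition time in seconds (time base of `A`).
#' @return An object of class `tc_ec` with fields `A`, `nodes`,
#'   `subject_id`, `tr_seconds`.
#' @export
effective_connectome <- function(A, nodes = NULL, subject_id = "subject",
                                 tr_seconds = 1.4) {
  assert_square(A)
  n <- nrow(A)
  if (any(diag(A) >= 0))
    stop_tc("all diagonal entries of A must be strictly negative",
            class = "tc_param_error")
  if (spectral_abscissa(A) >= 0)
    stop_tc("A must be stable (spectral abscissa < 0)", class = "tc_stability_error")
  if (is.null(nodes)) nodes <- default_nodes(n)
  if (nrow(nodes) != n)
    stop_tc("nodes table has %d rows but A is %dx%d", nrow(nodes), n, n,
            class = "tc_shape_error")
  assert_scalar_num(tr_seconds, "tr_seconds", lower = 0, strict_lower = TRUE)
  structure(list(A = unname(A), nodes = nodes, subject_id = subject_id,
                 tr_seconds = tr_seconds),
            class = "tc_ec")
}

default_nodes <- function(n) {
  if (n == sum(DEFAULT_RSN_SIZES)) return(synthetic_nodes())
  # small ad-hoc systems: cycle through labels so RSN-aware code still runs
  rsn <- rep(RSN_LABELS, length.out = n)
  node_table(node_id = 0:(n - 1L), name = sprintf("node_%02d", seq_len(n)),
             rsn = rsn, hemisphere = "M", x = 0, y = 0, z = 0)
}

#' @export
print.tc_ec <- function(x, ...) {
  n <- nrow(x$A)
  off <- x$A[row(x$A) != col(x$A)]
  cat(sprintf("<tc_ec> subject '%s': %d nodes, density %.3f, spectral abscissa %.4g (TR = %.2fs)\n",
              x$subject_id, n, mean(off != 0), spectral_abscissa(x$A), x$tr_seconds))
  invisible(x)
}

# accept either a tc_ec or a bare stable matrix
as_ec <- function(x, require_stable = TRUE) {
  if (inherits(x, "tc_ec")) return(x)
  if (is.matrix(x)) {
    assert_square(x)
    if (require_stable && spectral_abscissa(x) >= -1e-6)
      stop_tc("matrix is not stable (spectral abscissa >= -1e-6)",
              class = "tc_stability_error")
    return(structure(list(A = unname(x), nodes = default_nodes(nrow(x)),
                          subject_id = "anonymous", tr_seconds = 1.4),
                     class = "tc_ec"))
  }
  stop_tc("expected a tc_ec or a square matrix", class = "tc_param_error")
}

ec_matrix <- function(x) as_ec(x, require_stable = FALSE)$A

#' Shift a matrix to a prescribed stability margin
#'
#' Applies the uniform diagonal shift `A - c I` that places the spectral
#' abscissa (largest real part of the eigenvalues) exactly at `-margin`.
#' All eigenvalues move by the same real amount, so only the diagonal
#' changes; the operation is idempotent.
#'
#' @param A square numeric matrix.
#' @param margin positive real; the returned matrix has spectral abscissa
#'   `-margin` (to within `1e-9`).
#' @return The shifted matrix.
#' @export
ensure_stable <- function(A, margin = 0.05) {
  assert_square(A)
  assert_scalar_num(margin, "margin", lower = 0, strict_lower = TRUE)
  alpha <- spectral_abscissa(A)
  shift <- alpha + margin
  if (abs(shift) < 1e-12) return(A)
  A - diag(shift, nrow(A))
}

#' Cohort of effective connectomes
#'
#' @param subjects list of [effective_connectome()] objects sharing one node
#'   table.
#' @param nodes the shared node table (defaults to the first subject's).
#' @param config the [generator_config()] used, or `NULL` for loaded data.
#' @return An object of class `tc_cohort`.
#' @export
cohort <- function(subjects, nodes = NULL, config = NULL) {
  if (length(subjects) == 0)
    stop_tc("cohort needs at least one subject", class = "tc_param_error")
  nodes <- nodes %||% subjects[[1]]$nodes
  n <- nrow(nodes)
  for (s in subjects) {
    if (nrow(s$A) != n)
      stop_tc("all subjects must share the same node count", class = "tc_shape_error")
  }
  structure(list(subjects = subjects, nodes = nodes, config = config),
            class = "tc_cohort")
}

#' @export
print.tc_cohort <- function(x, ...) {
  cat(sprintf("<tc_cohort> %d subjects x %d nodes (%s)\n",
              length(x$subjects), nrow(x$nodes),
              if (is.null(x$config)) "loaded" else "generated"))
  invisible(x)
}

#' @export
length.tc_cohort <- function(x) length(x$subjects)

#' Write a cohort to a directory
#'
#' Writes `nodes.tsv` (columns node_id, name, rsn, hemisphere, x, y, z), one
#' dense `<subject_id>.ec.tsv` matrix per subject (first row/column are
#' node_ids; row i, column j holds `A[i, j]`, influence j to i), and
#' `generator_config.json` when the cohort was generated.
#'
#' @param x a `tc_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "tc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(x$nodes), file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ids <- x$nodes$node_id
  for (s in x$subjects) {
    M <- s$A
    dimnames(M) <- list(ids, ids)
    utils::write.table(M, file.path(dir, paste0(s$subject_id, ".ec.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
  }
  if (!is.null(x$config))
    jsonlite::write_json(unclass(x$config), file.path(dir, "generator_config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir directory written by [write_cohort()] (or hand-assembled in the
#'   same format).
#' @param tr_seconds time base to attach to each subject.
#' @return A `tc_cohort`.
#' @export
read_cohort <- function(dir, tr_seconds = 1.4) {
  nf <- file.path(dir, "nodes.tsv")
  if (!file.exists(nf))
    stop_tc("missing node metadata file: %s", nf, class = "tc_input_error")
  nd <- utils::read.table(nf, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  nodes <- node_table(nd$node_id, nd$name, nd$rsn, nd$hemisphere, nd$x, nd$y, nd$z)
  files <- sort(list.files(dir, pattern = "\\.ec\\.tsv$", full.names = TRUE))
  if (length(files) == 0)
    stop_tc("no <subject_id>.ec.tsv files in %s", dir, class = "tc_input_error")
  subjects <- lapply(files, function(f) {
    M <- as.matrix(utils::read.table(f, header = TRUE, sep = "\t",
                                     row.names = 1, check.names = FALSE))
    effective_connectome(M, nodes = nodes,
                         subject_id = sub("\\.ec\\.tsv$", "", basename(f)),
                         tr_seconds = tr_seconds)
  })
  cf <- file.path(dir, "generator_config.json")
  config <- if (file.exists(cf)) {
    cj <- jsonlite::read_json(cf, simplifyVector = TRUE)
    do.call(generator_config, cj[intersect(names(cj), names(formals(generator_config)))])
  }
  cohort(subjects, nodes, config)
}
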