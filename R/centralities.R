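# Per-node centralities used to rank candidate driver nodes, plus shortest
# paths and coupling scores that explain the pairwise energies.

#' Absolute in-/out-strength centralities
#'
#' Out-strength of node `i` is `sum_j |A[j, i]|` (total outgoing influence),
#' in-strength is `sum_j |A[i, j]|`; absolute values because links are
#' signed. The diagonal encodes leak/decay rather than inter-areal links
#' and is excluded by default.
#'
#' @param ec a `tc_ec` (or square matrix).
#' @param include_diagonal logical; include `A[i, i]` in both sums.
#' @return `data.frame` with `in_strength`, `out_strength` and `ratio`
#'   (out/in, `+Inf` when in-strength is 0), one row per node.
#' @export
strength_centralities <- function(ec, include_diagonal = FALSE) {
  A <- ec_matrix(ec)
  Aa <- abs(A)
  if (!include_diagonal) diag(Aa) <- 0
  ins <- rowSums(Aa)
  outs <- colSums(Aa)
  data.frame(in_strength = ins, out_strength = outs,
             ratio = ifelse(ins == 0, Inf, outs / ins))
}

#' PageRank on the binarized influence graph
#'
#' Standard PageRank on the directed unweighted graph with an edge `j -> i`
#' wherever `A[i, j] != 0` (`i != j`); signs and weights are discarded to
#' avoid negative-weight pathologies. Dangling nodes teleport uniformly;
#' scores sum to 1. In driver selection, low PageRank is preferred: good
#' drivers are nodes where a random walk does not get stuck, i.e. nodes
#' that do not receive many incoming connections.
#'
#' @param ec a `tc_ec` (or square matrix).
#' @param damping damping factor in (0, 1).
#' @param tol,max_iter power-iteration stopping rule.
#' @return Numeric score vector summing to 1.
#' @export
pagerank_centrality <- function(ec, damping = 0.85, tol = 1e-14,
                                max_iter = 1000L) {
  A <- ec_matrix(ec)
  assert_scalar_num(damping, "damping", 0, 1, strict_lower = TRUE)
  if (damping >= 1) stop_tc("damping must be < 1", class = "tc_param_error")
  n <- nrow(A)
  Adj <- (A != 0) * 1
  diag(Adj) <- 0            # Adj[i, j] = 1 iff edge j -> i
  outdeg <- colSums(Adj)
  dangling <- outdeg == 0
  Tmat <- sweep(Adj, 2, pmax(outdeg, 1), "/")
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- damping * (Tmat %*% p + sum(p[dangling]) / n) + (1 - damping) / n
    p_new <- as.numeric(p_new)
    if (sum(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  p / sum(p)
}

#' Gramian-trace (pq) control centrality
#'
#' `p_i = Tr(W^(i))` (single-driver controllability Gramian: ability of node
#' `i` to move the rest of the network) and `q_i = Tr(M^(i))` (single-target
#' observability Gramian: ability of the network to move node `i`);
#' `pq_i = p_i / q_i`. With an accessibility vector `beta`, driver columns
#' are scaled by `beta_i`, so `pq_i = beta_i^2 * pq_i` of the fully
#' accessible case, exactly.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param accessibility optional length-`n` vector with entries in `(0, 1]`.
#' @return `data.frame` with columns `p`, `q`, `pq`.
#' @export
pq_centrality <- function(ec, accessibility = NULL) {
  ec <- as_ec(ec)
  check_stable_for_gramian(ec$A)
  n <- nrow(ec$A)
  if (!is.null(accessibility)) {
    if (length(accessibility) != n || any(accessibility <= 0) || any(accessibility > 1))
      stop_tc("accessibility must be length n with entries in (0, 1]",
              class = "tc_param_error")
  }
  p <- rowSums(single_driver_gramian_diags(ec$A, weights = accessibility))
  q <- rowSums(single_driver_gramian_diags(t(ec$A)))
  data.frame(p = p, q = q, pq = p / q)
}

#' Driver and target energy centralities
#'
#' Means of the pairwise energy matrix: `driver_energy[i] = mean_j E[i, j]`
#' (average cost of controlling another node from `i`) and
#' `target_energy[i] = mean_j E[j, i]` (average cost of controlling `i`).
#' The self pair `j = i` is included in the averages; `+Inf` propagates.
#'
#' @param pe an `n x n` pairwise energy matrix from [pairwise_energies()].
#' @return `data.frame` with `driver_energy` and `target_energy`.
#' @export
energy_centralities <- function(pe) {
  if (!is.matrix(pe) || nrow(pe) != ncol(pe))
    stop_tc("pe must be a square matrix", class = "tc_shape_error")
  data.frame(driver_energy = rowMeans(pe), target_energy = colMeans(pe))
}

#' Shortest influence paths
#'
#' Directed graph with an edge `i -> j` of length `1 / |A[j, i]|` for every
#' nonzero off-diagonal influence of `i` on `j`; all-pairs shortest path
#' lengths by Dijkstra. `lengths[i, j]` is the distance from `i` to `j`
#' along influence direction; `+Inf` where unreachable.
#'
#' @param ec a `tc_ec` (or square matrix).
#' @return `n x n` matrix of path lengths with zero diagonal.
#' @export
shortest_paths <- function(ec) {
  A <- ec_matrix(ec)
  n <- nrow(A)
  Aoff <- A; diag(Aoff) <- 0
  nz <- which(Aoff != 0, arr.ind = TRUE)   # rows: (i = influenced, j = source)
  g <- igraph::graph_from_data_frame(
    data.frame(from = nz[, 2], to = nz[, 1], weight = 1 / abs(Aoff[nz])),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  D <- igraph::distances(g, mode = "out", algorithm = "dijkstra")
  ord <- match(as.character(seq_len(n)), rownames(D))
  unname(D[ord, ord])
}

#' Functional connectivity strength
#'
#' `F_i = sum_j F[j, i]` over `j != i` (the unit diagonal is excluded).
#'
#' @param fc a `tc_fc` or a correlation matrix.
#' @return Numeric vector of strengths.
#' @export
fc_strength <- function(fc) {
  F <- if (inherits(fc, "tc_fc")) fc$F else fc
  if (!is.matrix(F) || nrow(F) != ncol(F))
    stop_tc("fc must be square", class = "tc_shape_error")
  colSums(F) - diag(F)
}

#' Full centrality table for one subject
#'
#' Assembles every per-node measure used in driver selection: strengths and
#' their ratio, PageRank, Gramian traces `p`, `q`, `pq`, the energy
#' centralities, and (when `fc` is supplied) the FC strength.
#'
#' @param ec a `tc_ec` (or stable matrix).
#' @param fc optional `tc_fc` (computed from `ec` when `with_fc = TRUE`).
#' @param accessibility optional accessibility vector for the Gramian-based
#'   measures.
#' @param include_diagonal passed to [strength_centralities()].
#' @param with_fc compute model FC if `fc` is missing.
#' @return `data.frame`, one row per node, `node_id` first column.
#' @export
centrality_table <- function(ec, fc = NULL, accessibility = NULL,
                             include_diagonal = FALSE, with_fc = FALSE) {
  ec <- as_ec(ec)
  tab <- strength_centralities(ec, include_diagonal)
  tab$pagerank <- pagerank_centrality(ec)
  tab <- cbind(tab, pq_centrality(ec, accessibility))
  pe <- pairwise_energies(ec, weights = accessibility)
  tab <- cbind(tab, energy_centralities(pe))
  if (is.null(fc) && with_fc) fc <- stationary_fc(ec)
  if (!is.null(fc)) tab$fc_strength <- fc_strength(fc)
  cbind(node_id = ec$nodes$node_id, tab)
}
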