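# Ranking, driver-set construction, random baselines, optimal-centrality
# identification, rank aggregation, and Fisher-exact RSN enrichment.

#' Preferred ranking direction per centrality
#'
#' `ascending` means low scores make good drivers (energies, PageRank --
#' good drivers do not accumulate random-walk mass), `descending` means
#' high scores do (strengths, pq).
#' @export
CENTRALITY_DIRECTIONS <- c(
  driver_energy = "ascending", out_strength = "descending", pq = "descending",
  ratio = "descending", pagerank = "ascending", in_strength = "descending",
  fc_strength = "descending", fc_pagerank = "ascending")

#' Default driver-selection candidate centralities
#' @export
DEFAULT_CANDIDATES <- c("driver_energy", "out_strength", "pq", "ratio", "pagerank")

#' Rank nodes by a score vector
#'
#' Stable sort of the eligible nodes by score in the stated direction; ties
#' broken by ascending node index; `+Inf` scores (unusable nodes, e.g.
#' unreachable energies) always sort last regardless of direction.
#'
#' @param scores numeric vector over all nodes (`+Inf` allowed).
#' @param direction `"descending"` (high is good) or `"ascending"`.
#' @param eligible subset of node indices to rank (default all).
#' @param centrality_name optional label carried on the ranking.
#' @return A list of class `tc_ranking`: `order` (eligible indices, best
#'   first), `scores`, `positions` (1-based fractional ranks within the
#'   eligible set), `eligible`, `direction`, `centrality_name`,
#'   `tie_rule = "node_id"`.
#' @export
rank_nodes <- function(scores, direction = c("descending", "ascending"),
                       eligible = seq_along(scores), centrality_name = NULL) {
  direction <- match.arg(direction)
  eligible <- sort(as.integer(eligible))
  if (length(eligible) == 0)
    stop_tc("eligible set must be non-empty", class = "tc_param_error")
  s <- scores[eligible]
  oriented <- if (direction == "ascending") s else -s
  key <- ifelse(is.finite(s), oriented, Inf)   # +Inf scores always last
  ord <- eligible[order(key, eligible)]
  positions <- rank(key, ties.method = "average")
  structure(list(order = ord, scores = scores,
                 positions = stats::setNames(positions, eligible),
                 eligible = eligible, direction = direction,
                 centrality_name = centrality_name, tie_rule = "node_id"),
            class = "tc_ranking")
}

#' Select driver nodes from a ranking
#'
#' The first `n_d` ranked nodes not in the exclusion set (e.g. the target
#' RSN's own nodes).
#'
#' @param r a `tc_ranking`.
#' @param n_d number of drivers.
#' @param exclude node indices barred from selection (a [target_set()] or
#'   plain vector).
#' @return A [driver_set()].
#' @export
select_drivers <- function(r, n_d, exclude = integer(0)) {
  stopifnot(inherits(r, "tc_ranking"))
  if (inherits(exclude, "tc_targets")) exclude <- exclude$indices
  pool <- setdiff(r$order, exclude)
  if (n_d > length(pool))
    stop_tc("asked for %d drivers but only %d eligible nodes remain",
            n_d, length(pool), class = "tc_param_error")
  driver_set(pool[seq_len(n_d)])
}

#' Random driver sets
#'
#' `M` uniform samples of `n_d` nodes without replacement from the eligible
#' pool, the baseline against which centrality-based selections are
#' z-scored.
#'
#' @param n total node count.
#' @param n_d drivers per set.
#' @param exclude excluded node indices.
#' @param M number of sets (default 100).
#' @param seed integer seed.
#' @return List of `M` [driver_set()]s.
#' @export
random_driver_sets <- function(n, n_d, exclude = integer(0), M = 100L,
                               seed = 1L) {
  if (inherits(exclude, "tc_targets")) exclude <- exclude$indices
  pool <- setdiff(seq_len(n), exclude)
  if (n_d > length(pool) || n_d < 1 || M < 1)
    stop_tc("infeasible random driver configuration", class = "tc_param_error")
  set.seed(seed)
  lapply(seq_len(M), function(i) driver_set(sort(sample(pool, n_d))))
}

#' z-score a value against a random baseline
#'
#' `(value - mean(random)) / sd(random)` with the `M - 1` denominator; set
#' `scale = FALSE` for mean-only centering.
#'
#' @param value observed value.
#' @param random_values baseline sample (>= 2 values).
#' @param scale divide by the baseline standard deviation (default TRUE).
#' @return A single number.
#' @export
zscore_vs_random <- function(value, random_values, scale = TRUE) {
  random_values <- random_values[is.finite(random_values)]
  if (length(random_values) < 2)
    stop_tc("need >= 2 finite random values", class = "tc_param_error")
  s <- stats::sd(random_values)
  if (scale && s == 0)
    stop_tc("zero spread in the random baseline; z undefined", class = "tc_param_error")
  (value - mean(random_values)) / (if (scale) s else 1)
}

# per-subject candidate score vectors (shared expensive parts computed once)
candidate_scores <- function(ec, candidates, accessibility = NULL, fc = NULL) {
  ec <- as_ec(ec)
  out <- list()
  if (any(candidates %in% c("out_strength", "ratio", "in_strength"))) {
    st <- strength_centralities(ec)
    out$out_strength <- st$out_strength
    out$in_strength <- st$in_strength
    out$ratio <- st$ratio
  }
  if ("pagerank" %in% candidates) out$pagerank <- pagerank_centrality(ec)
  if (any(candidates %in% c("driver_energy", "pq"))) {
    G <- single_driver_gramian_diags(ec$A, weights = accessibility)
    E <- ifelse(G <= 1e-300, Inf, 1 / G)
    out$driver_energy <- rowMeans(E)
    if ("pq" %in% candidates) {
      q <- rowSums(single_driver_gramian_diags(t(ec$A)))
      out$pq <- rowSums(G) / q
    }
  }
  if (any(candidates %in% c("fc_strength", "fc_pagerank"))) {
    if (is.null(fc)) fc <- stationary_fc(ec)
    F <- fc$F
    out$fc_strength <- fc_strength(F)
    if ("fc_pagerank" %in% candidates) {
      thr <- stats::median(abs(F[row(F) != col(F)]))
      Adj <- (abs(F) >= thr) * 1   # diagonal dropped inside pagerank_centrality
      out$fc_pagerank <- pagerank_centrality(Adj)
    }
  }
  unknown <- setdiff(candidates, names(out))
  if (length(unknown))
    stop_tc("unknown centrality candidate(s): %s", paste(unknown, collapse = ", "),
            class = "tc_param_error")
  out[candidates]
}

#' Identify the optimal driver-selection centrality for a target set
#'
#' For each candidate centrality and each subject: rank nodes, select the
#' `n_d` best-ranked nodes outside the target set, and compute the
#' worst-case target control energy. The candidate minimizing the cohort
#' mean of `log10` energy wins. Subjects with infinite energy under every
#' candidate are excluded from the means with a warning.
#'
#' @param x a `tc_cohort` (or single `tc_ec`).
#' @param targets target node indices (or [target_set()]).
#' @param candidates centrality names from [CENTRALITY_DIRECTIONS].
#' @param n_d number of driver nodes.
#' @param accessibility optional accessibility vector (weights the Gramians
#'   and the energy computation).
#' @return List with `name` (winning centrality), `mean_log10_energy`
#'   (named vector over candidates), `per_subject` (subjects x candidates
#'   matrix of log10 energies), and `rankings` (per subject, per candidate).
#' @export
optimal_centrality <- function(x, targets, candidates = DEFAULT_CANDIDATES,
                               n_d = 10L, accessibility = NULL) {
  if (inherits(x, "tc_ec")) x <- cohort(list(x))
  stopifnot(inherits(x, "tc_cohort"))
  if (length(candidates) == 0)
    stop_tc("candidates must be non-empty", class = "tc_param_error")
  targets <- as_targets(targets)
  n <- nrow(x$nodes)
  ns <- length(x$subjects)
  L <- matrix(NA_real_, ns, length(candidates),
              dimnames = list(NULL, candidates))
  rankings <- vector("list", ns)
  for (s in seq_len(ns)) {
    ec <- x$subjects[[s]]
    fact <- lyap_factor(ec$A)
    sc <- candidate_scores(ec, candidates, accessibility)
    rankings[[s]] <- lapply(candidates, function(cn) {
      rank_nodes(sc[[cn]], CENTRALITY_DIRECTIONS[[cn]], centrality_name = cn)
    })
    names(rankings[[s]]) <- candidates
    for (cn in candidates) {
      dr <- select_drivers(rankings[[s]][[cn]], n_d, exclude = targets)
      if (!is.null(accessibility)) dr$weights <- accessibility[dr$indices]
      L[s, cn] <- log10(target_control_energy(ec, dr, targets, fact = fact))
    }
  }
  dead <- apply(L, 1, function(r) all(!is.finite(r)))
  if (any(dead))
    warning(sprintf("%d subject(s) had infinite energy for every candidate; excluded from means",
                    sum(dead)))
  means <- apply(L[!dead, , drop = FALSE], 2, function(v) mean(v[is.finite(v)]))
  list(name = candidates[which.min(means)], mean_log10_energy = means,
       per_subject = L, rankings = rankings)
}

#' Aggregate rankings by average rank
#'
#' Group consensus ordering: per node, the mean of its 1-based (fractional,
#' tie-averaged) rank positions across subjects; nodes are re-ranked by
#' ascending mean rank, ties broken by ascending node index.
#'
#' @param rankings list of `tc_ranking`s over the same eligible set.
#' @return A `tc_ranking` whose `scores` are the mean rank positions
#'   (direction `ascending`).
#' @export
aggregate_ranks <- function(rankings) {
  if (length(rankings) == 0)
    stop_tc("no rankings to aggregate", class = "tc_param_error")
  elig <- rankings[[1]]$eligible
  for (r in rankings)
    if (!identical(r$eligible, elig))
      stop_tc("all rankings must share one eligible set", class = "tc_param_error")
  P <- vapply(rankings, function(r) r$positions, numeric(length(elig)))
  meanrank <- rowMeans(P)
  scores <- rep(NA_real_, max(elig))
  scores[elig] <- meanrank
  rank_nodes(scores, "ascending", eligible = elig,
             centrality_name = "aggregated_mean_rank")
}

#' Fisher exact enrichment of a driver RSN among optimal drivers
#'
#' Pools the per-subject optimal driver sets `O(s)` and asks whether nodes
#' of `driver_rsn` are over- or under-represented among them, restricted to
#' nodes eligible as drivers for `target_rsn` (its own nodes are excluded).
#' Counts: `n1 = sum_s |O(s) n D|`, `n2 = sum_s |O(s) n D-complement|`,
#' `n3 = sum_s |O-complement(s) n D|`, `n4` the rest; two-sided Fisher
#' exact test on `[[n1, n2], [n3, n4]]`. Degenerate margins give `p = 1`
#' (flagged).
#'
#' @param optimal_sets list (one per subject) of optimal driver node
#'   indices, each already excluding the target RSN's nodes.
#' @param node_rsn character vector of RSN labels, one per node.
#' @param driver_rsn,target_rsn RSN labels, distinct.
#' @return One-row `data.frame`: labels, `n1..n4`, `mean_top_count`,
#'   `odds_ratio`, `p_value`, `degenerate`, plus placeholder `q_value`/
#'   `marker` columns filled by the analysis level after FDR.
#' @export
enrichment_test <- function(optimal_sets, node_rsn, driver_rsn, target_rsn) {
  if (driver_rsn == target_rsn)
    stop_tc("driver and target RSN must differ", class = "tc_param_error")
  eligible <- which(node_rsn != target_rsn)
  D <- which(node_rsn == driver_rsn)
  n1 <- n2 <- n3 <- n4 <- 0L
  for (O in optimal_sets) {
    O <- intersect(O, eligible)
    Obar <- setdiff(eligible, O)
    n1 <- n1 + length(intersect(O, D))
    n2 <- n2 + length(setdiff(O, D))
    n3 <- n3 + length(intersect(Obar, D))
    n4 <- n4 + length(setdiff(Obar, D))
  }
  tab <- matrix(c(n1, n2, n3, n4), 2, byrow = TRUE)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  orat <- (n1 * n4) / max(n2 * n3, .Machine$double.xmin)
  data.frame(driver_rsn = driver_rsn, target_rsn = target_rsn,
             n1 = n1, n2 = n2, n3 = n3, n4 = n4,
             mean_top_count = n1 / length(optimal_sets),
             odds_ratio = orat, p_value = p, degenerate = degenerate,
             q_value = NA_real_, marker = "none",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values: `q_(i) = min_{j >= i} p_(j) * m / j`, capped
#' at 1; the ordering of q matches the ordering of p.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop_tc("p-values must lie in [0, 1]", class = "tc_param_error")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Top-k overlap between two rankings
#'
#' Fraction of shared nodes among the `k` best-ranked of each ranking; the
#' standard robustness measure for driver-selection sensitivity.
#'
#' @param r1,r2 `tc_ranking`s.
#' @param k top-list size (default 10).
#' @return A fraction in `[0, 1]`.
#' @export
top_k_overlap <- function(r1, r2, k = 10L) {
  if (k <= 0) stop_tc("k must be positive", class = "tc_param_error")
  if (k > length(r1$order) || k > length(r2$order))
    stop_tc("k exceeds ranking size", class = "tc_param_error")
  length(intersect(r1$order[seq_len(k)], r2$order[seq_len(k)])) / k
}
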