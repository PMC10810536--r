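# Cohort-level analyses: energy scaling, pairwise-energy correlates, hub
# structure, RSN target control, enrichment, sensitivity, accessibility.

#' Experiment configuration
#'
#' @param T propagator horizon in TR units (default 10, the perturbation
#'   propagation timescale).
#' @param n_d_grid driver counts for scaling curves.
#' @param n_t_grid target counts for scaling curves.
#' @param n_d_targets fixed driver count for the target-scaling curve.
#' @param n_d_rsn driver count for the RSN control and enrichment analyses.
#' @param M random-baseline repetitions (default 100).
#' @param k top-k size for overlaps and enrichment (default 10).
#' @param f_grid perturbation levels for the sensitivity analysis.
#' @param n_sensitivity_reps noise realizations per perturbation level.
#' @param candidates driver-selection candidate centralities.
#' @param zscore_scale divide z-scores by the baseline sd (vs mean-centering
#'   only).
#' @param seed base seed for all experiment-level randomness.
#' @return A list of class `tc_experiment_config`.
#' @export
experiment_config <- function(T = 10, n_d_grid = c(2L, 5L, 10L, 20L),
                              n_t_grid = c(1L, 2L, 3L, 5L, 8L, 12L, 16L, 20L),
                              n_d_targets = 5L, n_d_rsn = 10L, M = 100L,
                              k = 10L, f_grid = seq(0, 0.25, by = 0.05),
                              n_sensitivity_reps = 10L,
                              candidates = DEFAULT_CANDIDATES,
                              zscore_scale = TRUE, seed = 1L) {
  assert_scalar_num(T, "T", 0, strict_lower = TRUE)
  if (length(n_d_grid) == 0 || any(n_d_grid < 1) ||
      length(n_t_grid) == 0 || any(n_t_grid < 1) || M < 2 || k < 1)
    stop_tc("invalid experiment configuration", class = "tc_param_error")
  if (any(f_grid < 0))
    stop_tc("perturbation levels must be >= 0", class = "tc_param_error")
  structure(list(T = T, n_d_grid = as.integer(sort(n_d_grid)),
                 n_t_grid = as.integer(sort(n_t_grid)),
                 n_d_targets = as.integer(n_d_targets),
                 n_d_rsn = as.integer(n_d_rsn), M = as.integer(M),
                 k = as.integer(k), f_grid = f_grid,
                 n_sensitivity_reps = as.integer(n_sensitivity_reps),
                 candidates = candidates, zscore_scale = zscore_scale,
                 seed = as.integer(seed)),
            class = "tc_experiment_config")
}

finite_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

#' Whole-network control energy versus number of drivers
#'
#' For each driver count and each candidate centrality (plus `M` random
#' driver selections), the worst-case energy to control the whole network,
#' per subject. Energies are summarized as `log10`; per subject and driver
#' count, each centrality's log-energy is z-scored against the random
#' baseline distribution.
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()].
#' @param accessibility optional per-node accessibility vector: drivers are
#'   weighted by it and the `pq`/energy candidates account for it.
#' @return List with `energies` (long data.frame: subject, n_d, method,
#'   log10_energy), `median_curve`, and `zscores`.
#' @export
scaling_vs_drivers <- function(x, config = experiment_config(),
                               accessibility = NULL) {
  stopifnot(inherits(x, "tc_cohort"))
  n <- nrow(x$nodes)
  all_targets <- target_set(seq_len(n))
  rows <- list(); zrows <- list()
  for (s in seq_along(x$subjects)) {
    ec <- x$subjects[[s]]
    fact <- lyap_factor(ec$A)
    sc <- candidate_scores(ec, config$candidates, accessibility)
    rankings <- lapply(config$candidates, function(cn)
      rank_nodes(sc[[cn]], CENTRALITY_DIRECTIONS[[cn]], centrality_name = cn))
    names(rankings) <- config$candidates
    for (nd in config$n_d_grid) {
      if (nd > n) next
      ener <- function(dr) {
        if (!is.null(accessibility)) dr$weights <- accessibility[dr$indices]
        log10(target_control_energy(ec, dr, all_targets, fact = fact))
      }
      cent <- vapply(config$candidates,
                     function(cn) ener(select_drivers(rankings[[cn]], nd)),
                     numeric(1))
      rnd <- vapply(random_driver_sets(n, nd, M = config$M,
                                       seed = config$seed + 1000L * s + nd),
                    ener, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ec$subject_id, n_d = nd,
        method = c(config$candidates, rep("random", config$M)),
        log10_energy = c(cent, rnd))
      z <- tryCatch(vapply(cent, zscore_vs_random, numeric(1),
                           random_values = rnd, scale = config$zscore_scale),
                    error = function(e) rep(NA_real_, length(cent)))
      zrows[[length(zrows) + 1L]] <- data.frame(
        subject = ec$subject_id, n_d = nd, method = config$candidates, z = z)
    }
  }
  energies <- do.call(rbind, rows)
  med <- stats::aggregate(log10_energy ~ n_d + method, energies, stats::median)
  list(energies = energies, median_curve = med, zscores = do.call(rbind, zrows))
}

#' Control energy versus number of targets
#'
#' Fixed driver count, nested growing target sets: in `random` mode the
#' nodes are randomly sorted per subject and prefixes of the sorted order
#' are taken; in `within_rsn` mode the nesting stays inside one network.
#' Drivers are selected per candidate centrality (and `M` random baselines);
#' the least-squares slope of mean `log10` energy versus target count is
#' reported (exponential scaling shows as a positive slope).
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()]; uses `n_d_targets`, `n_t_grid`.
#' @param mode `"random"` or `"within_rsn"`.
#' @param rsn network label for `within_rsn` mode.
#' @return List with `energies` (long data.frame), `mean_curve`, `slope`
#'   (per method), and `zscores` versus the random-driver baseline.
#' @export
scaling_vs_targets <- function(x, config = experiment_config(),
                               mode = c("random", "within_rsn"), rsn = "DMN") {
  stopifnot(inherits(x, "tc_cohort"))
  mode <- match.arg(mode)
  n <- nrow(x$nodes)
  pool <- if (mode == "within_rsn") which(x$nodes$rsn == rsn) else seq_len(n)
  grid <- config$n_t_grid[config$n_t_grid <= length(pool)]
  nd <- config$n_d_targets
  rows <- list(); zrows <- list()
  for (s in seq_along(x$subjects)) {
    ec <- x$subjects[[s]]
    fact <- lyap_factor(ec$A)
    set.seed(config$seed + s)
    order_pool <- sample(pool)
    sc <- candidate_scores(ec, config$candidates)
    W_of <- function(dr) controllability_gramian(ec, dr, fact = fact)$W
    energy_from_W <- function(W, tix) {
      lmin <- min(eigen(W[tix, tix, drop = FALSE], symmetric = TRUE,
                        only.values = TRUE)$values)
      if (lmin > 1e-12) -log10(lmin) else Inf
    }
    Ws <- lapply(config$candidates, function(cn) {
      r <- rank_nodes(sc[[cn]], CENTRALITY_DIRECTIONS[[cn]])
      W_of(select_drivers(r, nd))
    })
    names(Ws) <- config$candidates
    Wrnd <- lapply(random_driver_sets(n, nd, M = config$M,
                                      seed = config$seed + 7000L + s), W_of)
    for (nt in grid) {
      tix <- order_pool[seq_len(nt)]
      cent <- vapply(Ws, energy_from_W, numeric(1), tix = tix)
      rnd <- vapply(Wrnd, energy_from_W, numeric(1), tix = tix)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ec$subject_id, n_t = nt,
        method = c(config$candidates, rep("random", config$M)),
        log10_energy = c(cent, rnd))
      z <- tryCatch(vapply(cent, zscore_vs_random, numeric(1),
                           random_values = rnd, scale = config$zscore_scale),
                    error = function(e) rep(NA_real_, length(cent)))
      zrows[[length(zrows) + 1L]] <- data.frame(
        subject = ec$subject_id, n_t = nt, method = config$candidates, z = z)
    }
  }
  energies <- do.call(rbind, rows)
  mc <- stats::aggregate(log10_energy ~ n_t + method, energies, finite_mean)
  slope <- vapply(split(mc, mc$method), function(d) {
    d <- d[is.finite(d$log10_energy), ]
    if (nrow(d) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log10_energy ~ n_t, d))[2])
  }, numeric(1))
  list(energies = energies, mean_curve = mc, slope = slope,
       zscores = do.call(rbind, zrows))
}

#' Correlates of single-driver single-target energies
#'
#' Spearman correlations of `log10 E[i, j]` (finite pairs only) against:
#' the direct influence `A[j, i]` split by sign, the propagator coupling
#' `[exp(A T)][j, i]` split by sign, the shortest influence-path length
#' from `i` to `j`, and the model functional connectivity `F[j, i]`.
#' Strata with fewer than `min_pairs` pairs give `NaN` with a warning.
#'
#' @param x a `tc_ec` or `tc_cohort`.
#' @param config an [experiment_config()] (uses `T`).
#' @param fc optional precomputed `tc_fc` (single-subject input only).
#' @param min_pairs minimum stratum size (default 10).
#' @return Long `data.frame`: subject, measure, stratum, `R`, `n_pairs`.
#' @export
pair_energy_correlates <- function(x, config = experiment_config(), fc = NULL,
                                   min_pairs = 10L) {
  subjects <- if (inherits(x, "tc_cohort")) x$subjects else list(as_ec(x))
  out <- list()
  for (ec in subjects) {
    E <- pairwise_energies(ec)
    logE <- log10(E)
    direct <- t(ec$A)                     # [i, j] = influence of i on j
    prop <- t(propagator_coupling(ec, config$T))
    sp <- shortest_paths(ec)
    Fm <- (fc %||% stationary_fc(ec))$F   # symmetric: F[j, i] == F[i, j]
    offd <- row(E) != col(E)
    ok <- is.finite(logE) & offd
    strata <- list(
      direct_positive = list(v = direct, keep = ok & direct > 0),
      direct_negative = list(v = direct, keep = ok & direct < 0),
      propagator_positive = list(v = abs(prop), keep = ok & prop > 0),
      propagator_negative = list(v = abs(prop), keep = ok & prop < 0),
      shortest_path = list(v = sp, keep = ok & is.finite(sp)),
      fc = list(v = Fm, keep = ok))
    for (nm in names(strata)) {
      st <- strata[[nm]]
      npairs <- sum(st$keep)
      R <- if (npairs < min_pairs) {
        warning(sprintf("stratum %s has %d < %d pairs; correlation is NaN",
                        nm, npairs, min_pairs))
        NaN
      } else suppressWarnings(
        stats::cor(logE[st$keep], st$v[st$keep], method = "spearman"))
      out[[length(out) + 1L]] <- data.frame(
        subject = ec$subject_id, stratum = nm, R = R, n_pairs = npairs)
    }
  }
  do.call(rbind, out)
}

#' Hub structure of driver and target energies
#'
#' Per subject: Pearson correlations of the log10 driver/target energy
#' centralities with the in-/out-/FC strengths. Per node: coefficient of
#' variation across subjects of the energy centralities and strengths, and
#' the spread of energy-based ranks. Also correlates the mean log10 target
#' energy with the sagittal (y) and axial (z) node coordinates.
#'
#' @param x a `tc_cohort` with at least 2 subjects.
#' @return List of data.frames: `correlations`, `cv`, `rank_spread`,
#'   `coordinate_gradients`.
#' @export
hub_analysis <- function(x) {
  stopifnot(inherits(x, "tc_cohort"))
  if (length(x$subjects) < 2)
    stop_tc("hub_analysis needs >= 2 subjects", class = "tc_param_error")
  ns <- length(x$subjects)
  n <- nrow(x$nodes)
  Ed <- Et <- Outs <- Ins <- Fs <- matrix(NA_real_, ns, n)
  RankD <- RankT <- matrix(NA_real_, ns, n)
  cors <- list()
  for (s in seq_len(ns)) {
    ec <- x$subjects[[s]]
    pe <- pairwise_energies(ec)
    enc <- energy_centralities(pe)
    st <- strength_centralities(ec)
    fs <- fc_strength(stationary_fc(ec))
    Ed[s, ] <- enc$driver_energy; Et[s, ] <- enc$target_energy
    Outs[s, ] <- st$out_strength; Ins[s, ] <- st$in_strength; Fs[s, ] <- fs
    RankD[s, ] <- rank(enc$driver_energy)   # low energy = good driver = low rank
    RankT[s, ] <- rank(enc$target_energy)
    safe_cor <- function(a, b) {
      k <- is.finite(a) & is.finite(b)
      if (sum(k) < 3) NA_real_ else stats::cor(a[k], b[k])
    }
    cors[[s]] <- data.frame(
      subject = ec$subject_id,
      Ed_out = safe_cor(log10(enc$driver_energy), st$out_strength),
      Ed_in = safe_cor(log10(enc$driver_energy), st$in_strength),
      Ed_fc = safe_cor(log10(enc$driver_energy), fs),
      Et_in = safe_cor(log10(enc$target_energy), st$in_strength),
      Et_out = safe_cor(log10(enc$target_energy), st$out_strength),
      Et_fc = safe_cor(log10(enc$target_energy), fs))
  }
  cv <- function(M) apply(M, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2 || mean(v) == 0) NA_real_ else stats::sd(v) / mean(v)
  })
  cvtab <- data.frame(node_id = x$nodes$node_id,
                      cv_driver_energy = cv(Ed), cv_target_energy = cv(Et),
                      cv_out_strength = cv(Outs), cv_in_strength = cv(Ins))
  spread <- data.frame(node_id = x$nodes$node_id,
                       mean_rank_driver = colMeans(RankD),
                       sd_rank_driver = apply(RankD, 2, stats::sd),
                       mean_rank_target = colMeans(RankT),
                       sd_rank_target = apply(RankT, 2, stats::sd))
  mEt <- apply(log10(Et), 2, finite_mean)
  axes <- c(sagittal = "y", axial = "z")
  grad <- do.call(rbind, lapply(names(axes), function(nm) {
    ct <- stats::cor.test(mEt, x$nodes[[axes[[nm]]]])
    data.frame(axis = nm, coordinate = axes[[nm]],
               R = unname(ct$estimate), p_value = ct$p.value)
  }))
  list(correlations = do.call(rbind, cors), cv = cvtab, rank_spread = spread,
       coordinate_gradients = grad)
}

#' RSN target control table
#'
#' For each resting-state network as target set: the optimal driver-selection
#' centrality among the candidates, the cohort mean log10 worst-case energy
#' under individual rankings, the same under the group-aggregated ranking of
#' the optimal centrality, and their difference `deltaE` (>= 0 in
#' expectation: the individual ranking is optimal by construction). Also a
#' per-target-node normalized energy and, optionally, the FC-based selection
#' variant with its three delta quantities.
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()]; uses `n_d_rsn` and `candidates`.
#' @param fc_variant also compute the functional-connectivity-based
#'   selection comparison.
#' @return List with `table` (one row per RSN), `fc_table` (or NULL), and
#'   `details` (per-RSN optimal_centrality results, including rankings).
#' @export
rsn_control_analysis <- function(x, config = experiment_config(),
                                 fc_variant = TRUE) {
  stopifnot(inherits(x, "tc_cohort"))
  rsns <- intersect(RSN_LABELS, unique(x$nodes$rsn))
  nd <- config$n_d_rsn
  details <- list(); rows <- list(); fcrows <- list()
  for (r in rsns) {
    tix <- which(x$nodes$rsn == r)
    if (length(which(x$nodes$rsn != r)) < nd)
      stop_tc("RSN %s leaves fewer than n_d eligible remote drivers", r,
              class = "tc_param_error")
    oc <- optimal_centrality(x, tix, candidates = config$candidates, n_d = nd)
    agg <- aggregate_ranks(lapply(oc$rankings, `[[`, oc$name))
    agg_drivers <- select_drivers(agg, nd, exclude = tix)
    agg_log10 <- vapply(x$subjects, function(ec)
      log10(target_control_energy(ec, agg_drivers, target_set(tix))), numeric(1))
    ind_mean <- finite_mean(oc$per_subject[, oc$name])
    agg_mean <- finite_mean(agg_log10)
    rows[[r]] <- data.frame(
      region = r, centrality = oc$name, n_t = length(tix), n_d = nd,
      mean_log10E = ind_mean, mean_log10E_agg = agg_mean,
      deltaE = agg_mean - ind_mean,
      mean_log10E_per_node = ind_mean / length(tix))
    details[[r]] <- oc
    if (fc_variant) {
      occ <- optimal_centrality(x, tix, candidates = c("fc_strength", "fc_pagerank"),
                                n_d = nd)
      fagg <- aggregate_ranks(lapply(occ$rankings, `[[`, occ$name))
      fagg_drivers <- select_drivers(fagg, nd, exclude = tix)
      fagg_log10 <- vapply(x$subjects, function(ec)
        log10(target_control_energy(ec, fagg_drivers, target_set(tix))), numeric(1))
      fc_ind <- finite_mean(occ$per_subject[, occ$name])
      fc_agg <- finite_mean(fagg_log10)
      fcrows[[r]] <- data.frame(
        region = r, fc_centrality = occ$name,
        delta_fcagg_fc = fc_agg - fc_ind,       # group vs individual, FC-based
        delta_fc_ec = fc_ind - ind_mean,        # FC vs EC, individual rankings
        delta_fcagg_ecagg = fc_agg - agg_mean)  # FC vs EC, group rankings
    }
  }
  list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       fc_table = if (fc_variant)
         do.call(rbind, c(fcrows, list(make.row.names = FALSE))),
       details = details)
}

#' Driver-RSN by target-RSN enrichment matrices
#'
#' For each target RSN, each subject's top-k optimal drivers (by that RSN's
#' optimal centrality, target RSN excluded) are tallied per driver RSN.
#' Matrix A holds the mean count over subjects with +/- markers from
#' two-sided Fisher exact tests, FDR-adjusted over the `p^2 - p` ordered
#' RSN pairs; matrix B repeats the tally for the single group-aggregated
#' ranking (each row sums to k).
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()]; uses `k`, `n_d_rsn`, `candidates`.
#' @param control precomputed [rsn_control_analysis()] output (recomputed
#'   when NULL).
#' @return List with `individual_counts`, `aggregated_counts` (target RSN x
#'   driver RSN matrices), `markers` (character matrix), and `tests` (the
#'   long enrichment table with q-values).
#' @export
rsn_enrichment_analysis <- function(x, config = experiment_config(),
                                    control = NULL) {
  stopifnot(inherits(x, "tc_cohort"))
  if (is.null(control)) control <- rsn_control_analysis(x, config, fc_variant = FALSE)
  rsns <- intersect(RSN_LABELS, unique(x$nodes$rsn))
  k <- config$k
  node_rsn <- x$nodes$rsn
  cntA <- cntB <- matrix(0, length(rsns), length(rsns),
                         dimnames = list(target = rsns, driver = rsns))
  tests <- list()
  for (r in rsns) {
    oc <- control$details[[r]]
    tix <- which(node_rsn == r)
    osets <- lapply(oc$rankings, function(rk)
      select_drivers(rk[[oc$name]], k, exclude = tix)$indices)
    for (d in rsns) {
      cntA[r, d] <- mean(vapply(osets, function(o)
        sum(node_rsn[o] == d), numeric(1)))
      if (d != r)
        tests[[paste(d, r)]] <- enrichment_test(osets, node_rsn, d, r)
    }
    agg <- aggregate_ranks(lapply(oc$rankings, `[[`, oc$name))
    aggtop <- select_drivers(agg, k, exclude = tix)$indices
    for (d in rsns) cntB[r, d] <- sum(node_rsn[aggtop] == d)
  }
  tests <- do.call(rbind, c(tests, list(make.row.names = FALSE)))
  tests$q_value <- fdr_adjust(tests$p_value)
  tests$marker <- ifelse(tests$q_value < 0.05,
                         ifelse(tests$odds_ratio > 1, "+", "-"), "none")
  markers <- matrix("none", length(rsns), length(rsns),
                    dimnames = dimnames(cntA))
  for (i in seq_len(nrow(tests)))
    markers[tests$target_rsn[i], tests$driver_rsn[i]] <- tests$marker[i]
  list(individual_counts = cntA, aggregated_counts = cntB,
       markers = markers, tests = tests)
}

#' Sensitivity of driver rankings to EC perturbation
#'
#' Adds relative Gaussian noise of magnitude `f` to every connection
#' ([perturb_connectome()]), re-ranks nodes under each centrality, and
#' measures the top-k overlap with the unperturbed ranking, averaged over
#' noise realizations.
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()]; uses `f_grid`, `k`,
#'   `n_sensitivity_reps`.
#' @param centralities measures to stress (default the spectral and
#'   strength-based selection set).
#' @return List with `overlaps` (long data.frame: subject, f, centrality,
#'   mean_overlap) and `summary` (cohort mean per f and centrality).
#' @export
sensitivity_analysis <- function(x, config = experiment_config(),
                                 centralities = c("out_strength", "ratio",
                                                  "pagerank", "pq")) {
  stopifnot(inherits(x, "tc_cohort"))
  rows <- list()
  for (s in seq_along(x$subjects)) {
    ec <- x$subjects[[s]]
    base_sc <- candidate_scores(ec, centralities)
    base_rank <- lapply(centralities, function(cn)
      rank_nodes(base_sc[[cn]], CENTRALITY_DIRECTIONS[[cn]]))
    names(base_rank) <- centralities
    for (f in config$f_grid) {
      acc <- stats::setNames(numeric(length(centralities)), centralities)
      for (rep in seq_len(config$n_sensitivity_reps)) {
        pec <- perturb_connectome(ec, f,
                                  seed = config$seed + 100000L * s + 1000L * rep +
                                    round(400 * f))
        psc <- candidate_scores(pec, centralities)
        for (cn in centralities) {
          pr <- rank_nodes(psc[[cn]], CENTRALITY_DIRECTIONS[[cn]])
          acc[cn] <- acc[cn] + top_k_overlap(base_rank[[cn]], pr, config$k)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = ec$subject_id, f = f, centrality = centralities,
        mean_overlap = unname(acc) / config$n_sensitivity_reps)
    }
  }
  overlaps <- do.call(rbind, rows)
  list(overlaps = overlaps,
       summary = stats::aggregate(mean_overlap ~ f + centrality, overlaps, mean))
}

#' Control-energy scaling under non-unit node accessibility
#'
#' Repeats the whole-network driver-scaling analysis with input columns
#' weighted by an accessibility vector `beta` (control signals reach node
#' `i` attenuated by `beta_i`). The `pq` and energy candidates are
#' beta-aware (their Gramians scale by `beta^2` exactly); strength-based
#' centralities ignore accessibility and a random baseline is included.
#'
#' @param x a `tc_cohort`.
#' @param config an [experiment_config()].
#' @param beta accessibility vector; sampled uniform on `[0.01, 1]` with
#'   the config seed when NULL.
#' @return As [scaling_vs_drivers()], plus the `beta` used.
#' @export
accessibility_analysis <- function(x, config = experiment_config(), beta = NULL) {
  stopifnot(inherits(x, "tc_cohort"))
  n <- nrow(x$nodes)
  if (is.null(beta)) beta <- sample_accessibility(n, 0.01, 1, seed = config$seed)
  res <- scaling_vs_drivers(x, config, accessibility = beta)
  res$beta <- beta
  res
}

#' Run every analysis and write a report directory
#'
#' Accepts a cohort, a generator config (a cohort is generated), or a
#' cohort directory path. Writes one TSV per result table plus a
#' `metadata.json` sidecar (config, seeds, package version, table index)
#' so every table is regenerable from the metadata alone. Stage failures
#' are logged and the partial report is kept.
#'
#' @param input `tc_cohort`, `tc_generator_config`, or a directory path.
#' @param config an [experiment_config()].
#' @param out_dir report directory (created).
#' @return Invisibly, a list with all stage results and `failures`.
#' @export
run_all <- function(input, config = experiment_config(), out_dir = "tc_report") {
  x <- if (inherits(input, "tc_cohort")) input
  else if (inherits(input, "tc_generator_config")) generate_cohort(input)
  else if (is.character(input)) read_cohort(input)
  else stop_tc("input must be a cohort, generator config, or directory path",
               class = "tc_param_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(); results <- list(); failures <- character(0)
  add <- function(name, df) {
    utils::write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tables[[name]] <<- paste0(name, ".tsv")
  }
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", name, conditionMessage(e)))
      message(sprintf("stage %s failed: %s", name, conditionMessage(e)))
      NULL
    })
    results[[name]] <<- res
    res
  }
  sd_ <- stage("scaling_vs_drivers", scaling_vs_drivers(x, config))
  if (!is.null(sd_)) { add("driver_scaling", sd_$median_curve)
                       add("driver_scaling_z", sd_$zscores) }
  st_ <- stage("scaling_vs_targets", scaling_vs_targets(x, config))
  if (!is.null(st_)) { add("target_scaling", st_$mean_curve)
                       add("target_scaling_slope",
                           data.frame(method = names(st_$slope), slope = st_$slope)) }
  pc <- stage("pair_energy_correlates", pair_energy_correlates(x, config))
  if (!is.null(pc)) add("pair_energy_correlates", pc)
  if (length(x$subjects) >= 2) {
    hb <- stage("hub_analysis", hub_analysis(x))
    if (!is.null(hb)) { add("hub_correlations", hb$correlations)
                        add("hub_cv", hb$cv)
                        add("hub_gradients", hb$coordinate_gradients) }
  }
  rc <- stage("rsn_control", rsn_control_analysis(x, config))
  if (!is.null(rc)) { add("rsn_control", rc$table)
                      if (!is.null(rc$fc_table)) add("rsn_control_fc", rc$fc_table) }
  en <- stage("rsn_enrichment",
              rsn_enrichment_analysis(x, config, control = results$rsn_control))
  if (!is.null(en)) { add("rsn_enrichment_tests", en$tests)
                      add("rsn_enrichment_counts",
                          as.data.frame.table(en$individual_counts,
                                              responseName = "mean_count")) }
  se <- stage("sensitivity", sensitivity_analysis(x, config))
  if (!is.null(se)) add("sensitivity", se$summary)
  ac <- stage("accessibility", accessibility_analysis(x, config))
  if (!is.null(ac)) add("accessibility_scaling", ac$median_curve)
  meta <- list(
    package = "targetctrl",
    version = as.character(utils::packageVersion("targetctrl")),
    experiment_config = unclass(config),
    generator_config = if (!is.null(x$config)) unclass(x$config),
    n_subjects = length(x$subjects), n_nodes = nrow(x$nodes),
    tables = tables, failures = failures)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (length(failures)) warning(paste(failures, collapse = "; "))
  invisible(c(results, list(failures = failures, out_dir = out_dir)))
}
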