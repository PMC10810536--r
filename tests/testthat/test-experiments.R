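# cohort-level orchestration

small_config <- function(...) {
  experiment_config(n_d_grid = c(2L, 5L, 10L), n_t_grid = c(1L, 2L, 4L, 6L, 8L),
                    n_d_targets = 5L, n_d_rsn = 4L, M = 20L, k = 5L,
                    f_grid = c(0, 0.25), n_sensitivity_reps = 3L, seed = 1L, ...)
}

test_that("driver scaling curves are non-increasing for nested selections", {
  co <- small_cohort()
  cfg <- small_config()
  res <- scaling_vs_drivers(co, cfg)
  expect_true(all(c("energies", "median_curve", "zscores") %in% names(res)))
  # per subject and centrality the selection is nested, so energy cannot rise
  for (cn in cfg$candidates) {
    for (sid in unique(res$energies$subject)) {
      d <- res$energies[res$energies$method == cn & res$energies$subject == sid, ]
      d <- d[order(d$n_d), ]
      expect_true(all(diff(d$log10_energy) <= 1e-8))
    }
  }
})

test_that("target scaling: n_t = 1 consistency, energy grows with nested targets, slope > 0", {
  co <- small_cohort()
  cfg <- small_config()
  res <- scaling_vs_targets(co, cfg, mode = "random")
  e <- res$energies
  # nested growth never decreases energy for fixed drivers
  for (cn in cfg$candidates) for (sid in unique(e$subject)) {
    d <- e[e$method == cn & e$subject == sid, ]
    d <- d[order(d$n_t), ]
    expect_true(all(diff(d$log10_energy) >= -1e-8))
  }
  # exponential scaling: positive fitted slope on the mean curve
  expect_true(all(res$slope[is.finite(res$slope)] > 0))
  # within-RSN variant runs and respects the pool
  res2 <- scaling_vs_targets(co, cfg, mode = "within_rsn", rsn = co$nodes$rsn[1])
  expect_true(all(res2$energies$n_t <= sum(co$nodes$rsn == co$nodes$rsn[1])))
})

test_that("pair-energy correlates: Spearman equals rank-then-Pearson and strata behave", {
  ec <- small_cohort()$subjects[[1]]
  tab <- pair_energy_correlates(ec, small_config())
  expect_setequal(unique(tab$stratum),
                  c("direct_positive", "direct_negative", "propagator_positive",
                    "propagator_negative", "shortest_path", "fc"))
  # oracle: recompute one stratum by hand with rank-then-Pearson
  E <- pairwise_energies(ec)
  logE <- log10(E); direct <- t(ec$A)
  keep <- is.finite(logE) & (row(E) != col(E)) & direct > 0
  R_hand <- cor(rank(logE[keep]), rank(direct[keep]))
  expect_equal(tab$R[tab$stratum == "direct_positive"], R_hand, tolerance = 1e-12)
  # tiny stratum -> NaN with warning
  A <- -0.7 * diag(3); A[2, 1] <- 0.5
  A <- ensure_stable(A, 0.2)
  w <- capture_warnings(tab2 <- pair_energy_correlates(effective_connectome(A),
                                                       small_config()))
  expect_match(w, "pairs", all = FALSE)
  expect_true(any(is.nan(tab2$R)))
})

test_that("hub analysis: identical subjects give zero cv; fixture matches hand formula", {
  ec <- small_cohort()$subjects[[1]]
  co_id <- cohort(list(ec, ec, ec))
  hb <- hub_analysis(co_id)
  expect_true(all(hb$cv$cv_driver_energy < 1e-12, na.rm = TRUE))
  expect_true(all(hb$cv$cv_out_strength < 1e-12, na.rm = TRUE))
  # hand-check the cv on a 3-subject fixture for one node's out-strength
  co3 <- cohort(small_cohort()$subjects[c(1, 2, 3)])
  hb3 <- hub_analysis(co3)
  outs <- sapply(co3$subjects, function(s) strength_centralities(s)$out_strength[5])
  expect_equal(hb3$cv$cv_out_strength[5], sd(outs) / mean(outs), tolerance = 1e-12)
  expect_true(all(c("sagittal", "axial") %in% hb3$coordinate_gradients$axis))
})

test_that("RSN control table has the documented schema and non-negative deltaE on one subject", {
  co <- cohort(small_cohort()$subjects[1])  # single subject: agg == individual
  cfg <- small_config()
  res <- rsn_control_analysis(co, cfg, fc_variant = FALSE)
  expect_equal(names(res$table)[1:7],
               c("region", "centrality", "n_t", "n_d", "mean_log10E",
                 "mean_log10E_agg", "deltaE"))
  expect_true(all(abs(res$table$deltaE) < 1e-9))  # aggregation of one
  expect_true(all(res$table$centrality %in% cfg$candidates))
})

test_that("enrichment matrices: aggregated rows sum to k, own column zero, markers recomputable", {
  co <- small_cohort()
  cfg <- small_config()
  ctl <- rsn_control_analysis(co, cfg, fc_variant = FALSE)
  en <- rsn_enrichment_analysis(co, cfg, control = ctl)
  for (r in rownames(en$aggregated_counts)) {
    expect_equal(sum(en$aggregated_counts[r, ]), cfg$k)
    expect_equal(en$individual_counts[r, r], 0)  # target RSN excluded
    expect_equal(sum(en$individual_counts[r, ]), cfg$k)
  }
  # markers reproduce the direct recomputation from the tests table
  expect_equal(fdr_adjust(en$tests$p_value), en$tests$q_value)
  recomputed <- ifelse(en$tests$q_value < 0.05,
                       ifelse(en$tests$odds_ratio > 1, "+", "-"), "none")
  expect_equal(en$tests$marker, recomputed)
})

test_that("sensitivity: f = 0 gives overlap 1; overlap degrades with noise", {
  co <- cohort(small_cohort()$subjects[1:2])
  cfg <- small_config()
  res <- sensitivity_analysis(co, cfg)
  s0 <- res$summary[res$summary$f == 0, ]
  expect_true(all(s0$mean_overlap == 1))
  s25 <- res$summary[res$summary$f == 0.25, ]
  expect_true(all(s25$mean_overlap <= 1))
})

test_that("accessibility: all-ones beta reproduces the plain scaling analysis", {
  co <- cohort(small_cohort()$subjects[1:2])
  cfg <- small_config()
  plain <- scaling_vs_drivers(co, cfg)
  acc <- accessibility_analysis(co, cfg, beta = rep(1, 24))
  expect_equal(acc$median_curve, plain$median_curve, tolerance = 1e-10)
})

test_that("run_all writes a reproducible report and errors on a broken input", {
  co <- cohort(small_cohort()$subjects[1:2])
  cfg <- small_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_all(co, cfg, d1)
  r2 <- run_all(co, cfg, d2)
  expect_length(r1$failures, 0)
  expect_true(file.exists(file.path(d1, "metadata.json")))
  for (f in list.files(d1, pattern = "\\.tsv$")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_error(run_all(withr::local_tempdir(), cfg, withr::local_tempdir()),
               class = "tc_input_error")
})

test_that("the CLI generates and analyzes a cohort end to end", {
  d <- withr::local_tempdir()
  cj <- file.path(d, "cfg.json")
  jsonlite::write_json(list(generator = list(n_nodes = 16, n_subjects = 2),
                            experiment = list(n_d_grid = c(2, 4), M = 5,
                                              n_t_grid = c(1, 2))),
                       cj, auto_unbox = TRUE)
  gdir <- file.path(d, "cohort")
  expect_equal(tc_cli(c("generate", "--config", cj, "--seed", "3",
                        "--out-dir", gdir)), 0L)
  expect_true(file.exists(file.path(gdir, "nodes.tsv")))
  odir <- file.path(d, "out")
  expect_equal(tc_cli(c("energy", "--cohort", gdir, "--config", cj,
                        "--seed", "3", "--out-dir", odir)), 0L)
  expect_true(file.exists(file.path(odir, "driver_scaling.tsv")))
  expect_equal(tc_cli(c("bogus")), 1L)
})
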