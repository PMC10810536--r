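# ranking, selection, baselines, aggregation, enrichment, FDR

test_that("rank_nodes sorts by direction with node-id ties and Inf always last", {
  r <- rank_nodes(c(3, 1, 2), "descending")
  expect_equal(r$order, c(1L, 3L, 2L))
  r2 <- rank_nodes(c(1, 1, 1), "descending")
  expect_equal(r2$order, 1:3)            # tie rule: ascending node id
  r3 <- rank_nodes(c(2, Inf, 1), "descending")
  expect_equal(r3$order, c(1L, 3L, 2L))  # +Inf last even when descending
  # naive sort oracle over random score vectors
  set.seed(10)
  for (k in 1:200) {
    s <- sample(c(rnorm(8), Inf, Inf))
    for (dir in c("ascending", "descending")) {
      r <- rank_nodes(s, dir)
      key <- ifelse(is.finite(s), if (dir == "ascending") s else -s, Inf)
      expect_equal(r$order, order(key, seq_along(s)))
    }
  }
  expect_error(rank_nodes(1:3, eligible = integer(0)), class = "tc_param_error")
})

test_that("select_drivers takes the first eligible ranked nodes outside the exclusion", {
  r <- rank_nodes(c(5, 4, 3, 2, 1), "descending")
  expect_equal(select_drivers(r, 1)$indices, 1L)
  expect_equal(select_drivers(r, 5)$indices, 1:5)
  expect_equal(select_drivers(r, 2, exclude = c(1, 3))$indices, c(2L, 4L))
  expect_error(select_drivers(r, 5, exclude = 1), class = "tc_param_error")
  # exclusion honoured on random configurations
  set.seed(4)
  for (k in 1:100) {
    s <- rnorm(20)
    excl <- sample(20, 5)
    dr <- select_drivers(rank_nodes(s, "descending"), 6, exclude = excl)
    expect_length(intersect(dr$indices, excl), 0)
  }
})

test_that("random driver sets are uniform and reproducible", {
  s1 <- random_driver_sets(10, 3, M = 5, seed = 2)
  s2 <- random_driver_sets(10, 3, M = 5, seed = 2)
  expect_identical(s1, s2)
  expect_length(s1, 5)
  full <- random_driver_sets(6, 4, exclude = c(1, 2), M = 3, seed = 1)
  for (d in full) expect_equal(d$indices, 3:6)
  # inclusion frequency ~ n_d / |eligible| within 3 sigma binomial bounds
  M <- 10000L
  sets <- random_driver_sets(12, 4, M = M, seed = 9)
  freq <- tabulate(unlist(lapply(sets, `[[`, "indices")), 12) / M
  p <- 4 / 12
  expect_true(all(abs(freq - p) < 3 * sqrt(p * (1 - p) / M)))
  expect_error(random_driver_sets(5, 6), class = "tc_param_error")
})

test_that("z-scores match the textbook formula", {
  expect_equal(zscore_vs_random(2.5, c(1, 2, 3, 4)), 0)
  r <- c(1, 2, 3, 4)
  expect_equal(zscore_vs_random(mean(r) + sd(r), r), 1)
  expect_equal(zscore_vs_random(3, r), 0.5 / sd(r))
  expect_equal(round(zscore_vs_random(3, r), 4), 0.3873)
  expect_equal(zscore_vs_random(3, r, scale = FALSE), 0.5)
  expect_error(zscore_vs_random(1, c(2, 2, 2)), class = "tc_param_error")
})

test_that("optimal_centrality returns the single candidate trivially and picks the
           direct-strength winner on a constructed instance", {
  ec <- small_cohort()$subjects[[1]]
  oc1 <- optimal_centrality(ec, targets = 1:2, candidates = "out_strength", n_d = 3)
  expect_equal(oc1$name, "out_strength")
  # constructed 6-node system: node 1 has overwhelming out-strength straight
  # into both targets (5, 6), which have distinct leak rates so the target
  # Gramian is nonsingular; pagerank prefers other nodes
  A <- -0.8 * diag(6)
  A[5, 5] <- -0.6; A[6, 6] <- -1.2
  A[5, 1] <- 3; A[6, 1] <- 2   # 1 -> targets, very strong
  A[2, 3] <- A[3, 4] <- A[4, 2] <- 0.3
  A[1, 2] <- A[1, 3] <- A[1, 4] <- 0.3  # node 1 collects incoming links:
  A[1, 5] <- 0.05                       # high pagerank, so not pagerank's pick
  oc <- optimal_centrality(effective_connectome(ensure_stable(A, 0.3)),
                           targets = c(5, 6),
                           candidates = c("out_strength", "pagerank"), n_d = 1)
  expect_equal(oc$name, "out_strength")
  # direct verification: the out-strength driver really is cheaper
  e_out <- oc$per_subject[1, "out_strength"]
  e_pr <- oc$per_subject[1, "pagerank"]
  expect_lt(e_out, e_pr)
})

test_that("rank aggregation averages positions with the documented tie rule", {
  r1 <- rank_nodes(c(3, 2, 1), "descending")  # order 1, 2, 3
  agg1 <- aggregate_ranks(list(r1, r1))
  expect_equal(agg1$order, r1$order)          # idempotent on identical inputs
  r2 <- rank_nodes(c(1, 2, 3), "descending")  # order 3, 2, 1
  agg2 <- aggregate_ranks(list(r1, r2))
  expect_equal(agg2$order, 1:3)               # all mean ranks 2 -> node-id order
  # mean-of-positions oracle on random permutations
  set.seed(6)
  for (k in 1:20) {
    rs <- lapply(1:4, function(i) rank_nodes(rnorm(9), "ascending"))
    agg <- aggregate_ranks(rs)
    pos <- sapply(rs, function(r) {
      p <- integer(9); p[r$order] <- 1:9; p
    })
    expect_equal(agg$order, order(rowMeans(pos), 1:9))
  }
})

test_that("enrichment counts, Fisher p, and the enumeration oracle agree", {
  node_rsn <- rep(c("CON", "DMN", "VIS"), times = c(4, 4, 4))
  # all optimal sets exactly the driver RSN -> maximal enrichment
  osets <- replicate(3, which(node_rsn == "DMN"), simplify = FALSE)
  row <- enrichment_test(osets, node_rsn, "DMN", "VIS")
  expect_equal(row$n1, 12)  # 3 subjects x 4 DMN nodes
  expect_equal(row$n2, 0)
  expect_lt(row$p_value, 1e-4)
  expect_gt(row$odds_ratio, 1)
  # margin identities
  n_subj <- length(osets); elig <- sum(node_rsn != "VIS"); D <- sum(node_rsn == "DMN")
  expect_equal(row$n1 + row$n3, n_subj * D)
  expect_equal(row$n1 + row$n2 + row$n3 + row$n4, n_subj * elig)
  # [[3,1],[1,3]] gives p = 34/70 by exhaustive enumeration
  expect_equal(fisher_enum(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(stats::fisher.test(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))$p.value,
               34 / 70, tolerance = 1e-9)
  # random tables: package p equals enumeration p
  set.seed(12)
  for (k in 1:25) {
    m <- matrix(rpois(4, 6) + 1, 2)
    expect_equal(stats::fisher.test(m)$p.value,
                 fisher_enum(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-8)
  }
})

test_that("null calibration: random optimal sets produce ~5% raw positives, fewer after FDR", {
  set.seed(33)
  node_rsn <- rep(RSN_LABELS, times = c(3, 3, 3, 3, 3, 3, 3, 3))
  raw <- q05 <- 0; reps <- 200
  for (r in seq_len(reps)) {
    eligible <- which(node_rsn != "VIS")
    osets <- lapply(1:6, function(s) sample(eligible, 6))
    row <- enrichment_test(osets, node_rsn, "DMN", "VIS")
    raw <- raw + (row$p_value < 0.05)
  }
  expect_lt(raw / reps, 0.08)  # two-sided exact test is conservative
})

test_that("BH adjustment matches the hand example and stats::p.adjust", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(3)
  for (k in 1:20) {
    p <- runif(56)  # the 8x8 - 8 RSN comparisons
    expect_equal(fdr_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
  expect_error(fdr_adjust(c(0.5, 1.2)), class = "tc_param_error")
})

test_that("top-k overlap counts shared top nodes", {
  r1 <- rank_nodes(10:1, "descending")
  r2 <- rank_nodes(10:1, "descending")
  expect_equal(top_k_overlap(r1, r2, 10), 1)
  r3 <- rank_nodes(1:10, "descending")
  expect_equal(top_k_overlap(r1, r3, 5), 0)
  expect_error(top_k_overlap(r1, r3, 0), class = "tc_param_error")
})
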