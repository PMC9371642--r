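pp_b <- tiny_population(v = 12, k = 2, n = 60, seed = 3)
gt_b <- estimate_ground_truth(pp_b$population, pp_b$partition,
                              engine = perm_engine(200, 2))

test_that("group resampling draws without replacement, reproducibly", {
  g <- resample_groups(pp_b$population, 20, rep_seed = 5)
  g2 <- resample_groups(pp_b$population, 20, rep_seed = 5)
  expect_identical(g$condition_a, g2$condition_a)
  expect_identical(g$n_subjects, 20L)
  # n = population size returns every subject exactly once (up to order)
  gall <- resample_groups(pp_b$population, 60, rep_seed = 1)
  expect_equal(sort(rowSums(gall$condition_a)),
               sort(rowSums(pp_b$population$condition_a)))
  expect_error(resample_groups(pp_b$population, 61, 1), "exceeds")
  # inclusion frequency ~ n/N across repetitions
  marks <- rowSums(vapply(1:1000, function(r) {
    g <- resample_groups(pp_b$population, 20, r)
    # identify drawn subjects by their first-edge fingerprint
    pp_b$population$condition_a[, 1] %in% g$condition_a[, 1]
  }, logical(60)))
  p <- 20 / 60
  expect_true(all(abs(marks / 1000 - p) < 3 * sqrt(p * (1 - p) / 1000) + 0.02))
})

test_that("fake contrasts shuffle the two rest runs per subject", {
  fake <- make_fake_contrast(pp_b$population, rep_seed = 9)
  fake2 <- make_fake_contrast(pp_b$population, rep_seed = 9)
  expect_identical(fake$condition_a, fake2$condition_a)
  # each subject's rows come from the two rest runs, possibly swapped
  for (s in c(1, 17, 60)) {
    a_is_b1 <- identical(fake$condition_a[s, ], pp_b$population$condition_b[s, ])
    a_is_b2 <- identical(fake$condition_a[s, ], pp_b$population$condition_b2[s, ])
    expect_true(xor(a_is_b1, a_is_b2))
    expect_identical(sort(c(fake$condition_a[s, 1], fake$condition_b[s, 1])),
                     sort(c(pp_b$population$condition_b[s, 1],
                            pp_b$population$condition_b2[s, 1])))
  }
  # both coins appear across 60 subjects
  swapped <- vapply(1:60, function(s)
    identical(fake$condition_a[s, ], pp_b$population$condition_b2[s, ]),
    logical(1))
  expect_true(any(swapped) && any(!swapped))
  no2 <- paired_sample(pp_b$population$condition_a,
                       pp_b$population$condition_b, pp_b$index)
  expect_error(make_fake_contrast(no2, 1), "second null run")
  # identical runs give all-zero differences
  same <- paired_sample(pp_b$population$condition_b,
                        pp_b$population$condition_b, pp_b$index,
                        condition_b2 = pp_b$population$condition_b)
  expect_true(all(paired_differences(make_fake_contrast(same, 4)) == 0))
})

test_that("sign-matched classification of edge detections", {
  gt <- gt_b
  e <- length(gt$d_edge)
  det <- connbench:::new_detections(
    "edge-fwer", "edge", 0.05,
    tibble::tibble(element = c(1L, 2L), sign = c(1, 1),
                   stat = c(3, 3), p_or_q = c(0.01, 0.01)),
    e, pos_edges = c(TRUE, TRUE, rep(FALSE, e - 2)))
  gt$sign_edge[1] <- 1   # matching sign -> TP
  gt$sign_edge[2] <- -1  # opposite sign -> FP
  cl <- classify_detections(det, gt, "real")
  expect_true(cl$tp_edges[1] && !cl$fp_edges[1])
  expect_true(cl$fp_edges[2] && !cl$tp_edges[2])
  # sparse-like sign 0 counts any detection as FP
  gt$sign_edge[1] <- 0
  cl0 <- classify_detections(det, gt, "real")
  expect_true(cl0$fp_edges[1])
  # fake contrast: every detection is a false positive
  clf <- classify_detections(det, gt_b, "fake")
  expect_identical(sum(clf$fp_edges), 2L)
  expect_identical(sum(clf$tp_edges), 0L)
})

test_that("cluster detections classify as units and per edge", {
  gt <- gt_b
  e <- length(gt$d_edge)
  gt$sign_edge[] <- 0
  gt$sign_edge[1:4] <- c(1, 1, -1, 1)
  pos_edges <- rep(FALSE, e); pos_edges[1:4] <- TRUE
  det <- connbench:::new_detections(
    "nbs", "cluster", 0.05,
    tibble::tibble(element = "pos_1", sign = 1, stat = 4, p_or_q = 0.002,
                   n_implicated = 4L),
    e, pos_edges = pos_edges,
    extra = list(clusters = list(pos = list(1:4), neg = list())))
  cl <- classify_detections(det, gt, "real")
  # the cluster contains matching-sign edges: one TP detection unit
  expect_identical(cl$n_tp_detections, 1L)
  expect_identical(cl$n_fp_detections, 0L)
  expect_false(any(cl$fp_implicated))
  # but edge-level accounting flags the wrong-sign member edge
  expect_identical(which(cl$fp_edges), 3L)
  expect_identical(which(cl$tp_edges), c(1L, 2L, 4L))
  # a cluster with no matching-sign edge is a false-positive unit
  det2 <- connbench:::new_detections(
    "nbs", "cluster", 0.05,
    tibble::tibble(element = "neg_1", sign = -1, stat = 2, p_or_q = 0.01,
                   n_implicated = 2L),
    e, neg_edges = c(TRUE, TRUE, rep(FALSE, e - 2)),
    extra = list(clusters = list(pos = list(), neg = list(1:2))))
  gt$sign_edge[1:2] <- 1
  cl2 <- classify_detections(det2, gt, "real")
  expect_identical(cl2$n_fp_detections, 1L)
  expect_identical(sum(cl2$fp_implicated), 2L)
})

test_that("whole-brain classification is signless", {
  det <- connbench:::new_detections(
    "mv-cnbs", "whole_brain", 0.05,
    tibble::tibble(element = "whole_brain", sign = NA_real_, stat = 50,
                   p_or_q = 0.002),
    length(gt_b$d_edge), wb_detected = TRUE)
  cl <- classify_detections(det, gt_b, "real")
  expect_true(cl$tp_elements)
  expect_identical(cl$n_fp_detections, 0L)
  clf <- classify_detections(det, gt_b, "fake")
  expect_true(clf$fp_elements)
  expect_true(all(clf$fp_edges))
})

test_that("metric aggregation matches hand-computed rates", {
  gt <- gt_b
  e <- length(gt$d_edge)
  gt$sign_edge[] <- 1
  acc <- list(level = "edge", tp_count = rep(400, e),
              n_tp = rep(5, 500), n_fp = rep(0, 500),
              n_tp_det = rep(5, 500), n_fp_det = rep(0, 500),
              n_fp_impl = rep(0, 500), any_det = rep(TRUE, 500))
  m <- compute_metrics(acc, gt, 0.05, 500, "real", e)
  expect_equal(m$tpr[[1]][1], 0.8) # 400 of 500 repetitions
  expect_equal(m$mean_power, 0.8)
  expect_equal(m$prop_power_ge_80, 1)
  expect_equal(m$fwer_strong, 0)
  expect_true(m$fwer_valid)
  # 25 of 500 fake repetitions with a detection: weak FWER 5%, valid
  accf <- list(level = "edge", tp_count = rep(0, e),
               n_tp = rep(0, 500), n_fp = c(rep(1, 25), rep(0, 475)),
               n_tp_det = rep(0, 500), n_fp_det = c(rep(1, 25), rep(0, 475)),
               n_fp_impl = c(rep(2, 25), rep(0, 475)),
               any_det = c(rep(TRUE, 25), rep(FALSE, 475)))
  mf <- compute_metrics(accf, gt, 0.05, 500, "fake", 100)
  expect_equal(mf$fwer_weak, 0.05)
  expect_equal(mf$fwer_bound, 0.05 + 1.96 * sqrt(0.05 * 0.95 / 500))
  expect_true(mf$fwer_valid) # bound ~ 6.9%
  # 2 FP edges out of E = 100 contribute 0.02 to the spatial extent
  expect_equal(mf$fp_spatial_extent, mean(c(rep(0.02, 25), rep(0, 475))))
})

test_that("power-by-effect-size bins behave on constructed inputs", {
  d <- seq(0, 0.99, length.out = 200)
  flat <- power_by_effect_size(rep(0.4, 200), d, bins = 5)
  expect_true(all(abs(flat$mean_power - 0.4) < 1e-12))
  step <- power_by_effect_size(as.numeric(abs(d) > 0.5), d,
                               bins = seq(0, 1, 0.25))
  expect_equal(step$mean_power, c(0, 0, 1, 1), tolerance = 0.05)
  # empty bins reported as NA
  sparse <- power_by_effect_size(c(0.5, 0.5), c(0.1, 0.9),
                                 bins = seq(0, 0.9, 0.3))
  expect_true(is.na(sparse$mean_power[2]))
  expect_error(power_by_effect_size(0.5, 0.3, bins = numeric(1)), "bin")
})

test_that("experiment grids enumerate the Cartesian product", {
  g <- experiment_grid_plan(connbench_procedures(),
                            c(paste0("task", 1:7), "fake"), c(40, 80, 120))
  expect_identical(nrow(g), 168L)
  expect_identical(nrow(experiment_grid_plan("nbs", "real", 40)), 1L)
  expect_error(experiment_grid_plan(character(0), "real", 40), "nonempty")
})

test_that("a perfectly detecting repetition yields power 1 and no errors", {
  # large effects, generous alpha: edge FDR detects everything in sign
  pp <- tiny_population(v = 8, k = 2, n = 50, seed = 61)
  pp$spec$delta[] <- 1.2
  pop <- simulate_population(pp$spec)
  gt1 <- estimate_ground_truth(pop, pp$partition,
                               engine = perm_engine(100, 5))
  cfg <- benchmark_config(procedures = "edge-fdr", contrast = "real",
                          n = 40, repetitions = 1, seed = 2,
                          n_permutations = 50)
  bm <- run_benchmark(cfg, pop, gt1)
  expect_equal(bm$summary$mean_power, 1)
  expect_equal(bm$summary$fwer_strong, 0)
  expect_equal(bm$summary$spatial_precision, 1)
})

test_that("benchmark runs are deterministic given the seed", {
  cfg <- benchmark_config(procedures = c("edge-fwer", "nbs", "cnbs-fdr"),
                          contrast = "real", n = 20, repetitions = 3,
                          seed = 9, n_permutations = 99)
  b1 <- run_benchmark(cfg, pp_b$population, gt_b)
  b2 <- run_benchmark(cfg, pp_b$population, gt_b)
  expect_identical(b1$summary, b2$summary)
  # variants reuse identical detections: full and a duplicate agree
  cfgv <- benchmark_config(procedures = "edge-fwer", contrast = "real",
                           n = 20, repetitions = 2, seed = 9,
                           n_permutations = 49)
  bv <- run_benchmark(cfgv, pp_b$population,
                      list(full = gt_b, again = gt_b))
  s <- bv$summary
  expect_equal(s$mean_power[s$variant == "full"],
               s$mean_power[s$variant == "again"])
})

test_that("null-truth real contrast matches fake-contrast accounting", {
  # zero-effect ground truth: every detection under the real contrast is a
  # false positive, mirroring the fake-contrast rule
  gt0 <- gt_b
  gt0$sign_edge[] <- 0
  gt0$sig_edge[] <- FALSE
  gt0$sign_network[] <- 0
  gt0$whole_brain_nonnull <- FALSE
  det <- connbench:::new_detections(
    "edge-fwer", "edge", 0.05,
    tibble::tibble(element = 3L, sign = -1, stat = -4, p_or_q = 0.01),
    length(gt0$d_edge),
    neg_edges = c(FALSE, FALSE, TRUE, rep(FALSE, length(gt0$d_edge) - 3)))
  cl_real <- classify_detections(det, gt0, "real")
  cl_fake <- classify_detections(det, gt0, "fake")
  expect_identical(cl_real$fp_edges, cl_fake$fp_edges)
  expect_identical(cl_real$n_fp_detections, cl_fake$n_fp_detections)
})
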