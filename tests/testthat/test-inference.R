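# small helper: edge_stats object with prescribed one-sided p-values
fake_stats <- function(p_pos, df = 39L) {
  t <- qt(p_pos, df = df, lower.tail = FALSE)
  structure(list(t = t, d = t / sqrt(df + 1), p_two = 2 * pmin(p_pos, 1 - p_pos),
                 p_pos = p_pos, p_neg = 1 - p_pos, df = df, n = df + 1L,
                 degenerate = rep(FALSE, length(p_pos))),
            class = "edge_stats")
}

test_that("Bonferroni edge correction detects exactly at the boundary", {
  p <- rep(0.5, 100)
  p[7] <- 0.0005
  res <- edge_bonferroni(fake_stats(p), alpha = 0.05, split_tails = FALSE)
  expect_identical(res$detections$element, 7L) # 0.0005 <= 0.05/100
  expect_identical(res$detections$sign, 1)
  p[7] <- 0.001
  res2 <- edge_bonferroni(fake_stats(p), alpha = 0.05, split_tails = FALSE)
  expect_identical(nrow(res2$detections), 0L)
  # E = 1 reduces to the uncorrected one-sided test
  res3 <- edge_bonferroni(fake_stats(0.04), alpha = 0.05, split_tails = FALSE)
  expect_identical(nrow(res3$detections), 1L)
  expect_error(edge_bonferroni(fake_stats(p), alpha = 1.2), "alpha")
})

test_that("Storey q-values match the worked step-up example", {
  out <- storey_qvalues(c(0.6, 0.7, 0.8, 0.9), lambda = 0.5)
  expect_equal(out$pi0, 1) # min(1, 4/2) capped
  out2 <- storey_qvalues(c(0.01, 0.02, 0.03, 0.9), lambda = 0.5)
  expect_equal(out2$pi0, 0.5)
  expect_equal(out2$q, c(0.02, 0.02, 0.02, 0.45))
  expect_error(storey_qvalues(c(0.1), lambda = 1), "lambda")
  expect_error(storey_qvalues(c(-0.1)), "0, 1")
})

test_that("q-values are monotone in p, order-invariant, and reduce to BH", {
  set.seed(3)
  for (rep in 1:20) {
    p <- runif(50)^sample(1:3, 1)
    q <- storey_qvalues(p)$q
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
    perm <- sample(50)
    expect_equal(storey_qvalues(p[perm])$q, q[perm])
    # with pi0 forced to 1 the step-up equals Benjamini-Hochberg
    p_hi <- pmin(1, p + 0.6) # pushes pi0 estimate to the cap
    if (storey_qvalues(p_hi)$pi0 == 1) {
      expect_equal(storey_qvalues(p_hi)$q, p.adjust(p_hi, "BH"))
    }
  }
})

test_that("pi0 is near 1 for uniform p-values", {
  set.seed(10)
  expect_lt(abs(storey_qvalues(runif(10000))$pi0 - 1), 0.05)
})

test_that("Storey FDR edge detection dominates Bonferroni", {
  set.seed(14)
  for (rep in 1:50) {
    pp <- tiny_population(v = 10, n = 20, seed = rep)
    st <- paired_t_and_d(paired_differences(pp$population))
    nb <- nrow(edge_bonferroni(st)$detections)
    nf <- nrow(edge_storey_fdr(st)$detections)
    expect_gte(nf, nb)
  }
  # single edge at p = 0.01 is detected; uninformative p (0.5 both tails)
  # yields nothing
  expect_identical(nrow(edge_storey_fdr(fake_stats(0.01))$detections), 1L)
  expect_identical(nrow(edge_storey_fdr(fake_stats(rep(0.5, 5)))$detections),
                   0L)
})

test_that("supra-threshold components match the flood-fill oracle", {
  idx <- edge_index(6)
  mask <- logical(idx$n_edges)
  mask[pair_to_edge(idx, c(1, 2, 4), c(2, 3, 5))] <- TRUE
  cc <- edge_components(mask, idx)
  expect_identical(sort(cc$sizes, decreasing = TRUE), c(2L, 1L))
  expect_identical(edge_components(logical(idx$n_edges), idx)$sizes,
                   integer(0))
  # complete graph on 4 nodes is one component of 6 edges
  idx4 <- edge_index(4)
  cc4 <- edge_components(rep(TRUE, 6), idx4)
  expect_identical(cc4$sizes, 6L)
  set.seed(22)
  for (rep in 1:200) {
    v <- sample(3:12, 1)
    idx <- edge_index(v)
    mask <- runif(idx$n_edges) < runif(1, 0.05, 0.5)
    got <- edge_components(mask, idx)
    want <- oracle_components(which(mask), idx)
    norm <- function(x) unname(lapply(x, sort))[order(vapply(x, min, 1))]
    expect_identical(norm(got$components),
                     if (length(want)) norm(want) else list())
  }
})

test_that("NBS cluster p-values follow the max-size permutation null", {
  # observed max size 10 against null maxima {3,5,12,10} gives p = 0.6
  expect_equal(permutation_pvalue(10, c(3, 5, 12, 10), "ge"), 0.6)
  pp <- tiny_population(v = 12, n = 15, seed = 2, null_effects = TRUE)
  diffs <- paired_differences(pp$population)
  eng <- perm_engine(99, seed = 4)
  # a huge threshold leaves no supra-threshold edges and no detections
  res <- nbs_cluster(diffs, eng, cdt = 50)
  expect_identical(nrow(res$detections), 0L)
  expect_false(any(res$pos_edges | res$neg_edges))
  expect_error(nbs_cluster(diffs, eng, cdt = -1), "positive")
})

test_that("NBS agrees with the exhaustive sign-flip oracle", {
  pp <- tiny_population(v = 8, k = 2, n = 6, seed = 3)
  diffs <- paired_differences(pp$population)
  idx <- pp$index
  cdt <- connbench:::default_cdt(5)
  # exact null distribution of the max supra-threshold component size
  flips <- all_sign_flips(6)
  exact_max <- apply(flips, 2, function(s) {
    tv <- paired_t_and_d(diffs * s)$t
    sz <- edge_components(tv > cdt, idx)$sizes
    if (length(sz)) max(sz) else 0L
  })
  eng <- perm_engine(1500, seed = 8)
  tm <- connbench:::perm_t_matrix(diffs, perm_sign_matrix(eng, 6))
  null_mc <- connbench:::perm_max_component_cpp(tm, idx$i, idx$j,
                                                idx$n_nodes, cdt)
  for (s_ref in unique(round(quantile(exact_max, c(0.5, 0.8, 0.95))))) {
    p_exact <- mean(exact_max >= s_ref)
    p_mc <- permutation_pvalue(s_ref, null_mc, "ge")
    se <- sqrt(p_exact * (1 - p_exact) / 1500)
    expect_lt(abs(p_mc - p_exact), 2 * se + 2 / 1500)
  }
})

test_that("TFCE single-step scores equal the closed form", {
  idx5 <- edge_index(5)
  tv <- numeric(10)
  path <- pair_to_edge(idx5, 1:4, 2:5)
  tv[path] <- 2
  sc <- tfce_transform(tv, idx5, tfce_params(0.5, 2, 1))
  expect_equal(sc[path], rep(4^0.5 * 2^2 * 2, 4)) # 16 each
  expect_equal(sc[-path], rep(0, 6))
  expect_equal(tfce_transform(numeric(10), idx5), numeric(10))
  expect_equal(tfce_transform(rep(-3, 10), idx5), numeric(10))
})

test_that("TFCE matches the stepwise oracle on random graphs", {
  set.seed(17)
  for (rep in 1:25) {
    v <- sample(4:11, 1)
    idx <- edge_index(v)
    tv <- rnorm(idx$n_edges)
    for (ns in c(1, 13, 60)) {
      got <- tfce_transform(tv, idx, tfce_params(0.5, 2, ns))
      expect_equal(got, oracle_tfce(pmax(tv, 0), idx, 0.5, 2, ns),
                   tolerance = 1e-10)
    }
  }
})

test_that("raising an isolated edge never lowers other TFCE scores", {
  set.seed(19)
  idx <- edge_index(8)
  tv <- pmax(rnorm(idx$n_edges), 0)
  iso <- which.min(tv)
  base <- tfce_transform(tv, idx, tfce_params(n_steps = 40))
  tv2 <- tv
  tv2[iso] <- max(tv) # raising within the existing height range
  bumped <- tfce_transform(tv2, idx, tfce_params(n_steps = 40))
  expect_true(all(bumped[-iso] >= base[-iso] - 1e-10))
})

test_that("pooled network statistics average edgewise t per pair", {
  idx <- edge_index(4)
  pm <- assign_network_pairs(node_partition(c("A", "A", "B", "B")), idx)
  tvec <- numeric(6)
  tvec[pm$pair_of_edge == which(pm$pairs$community_a == "A" &
                                  pm$pairs$community_b == "A")] <- 2
  stats <- cnbs_stats(tvec, pm)
  expect_equal(stats[pm$pairs$within & pm$pairs$community_a == "A"], 2)
  expect_equal(cnbs_stats(rep(3.5, 6), pm), rep(3.5, 3))
  pm1 <- assign_network_pairs(node_partition(rep("A", 4)), idx)
  tv <- rnorm(6)
  expect_equal(cnbs_stats(tv, pm1), mean(tv))
  # matrix form agrees with rowwise application
  tmat <- matrix(rnorm(12), 2, 6)
  expect_equal(cnbs_stats(tmat, pm)[1, ], cnbs_stats(tmat[1, ], pm))
})

test_that("Simes step-up detects per the worked examples", {
  # three network pairs: direct check of the step-up rule via p.adjust
  expect_true(all(p.adjust(c(0.01, 0.02, 0.04), "BH") <= 0.05))
  expect_false(any(p.adjust(c(0.04, 0.5, 0.9), "BH") <= 0.05))
})

test_that("network inference: Bonferroni detections nest in Simes", {
  set.seed(9)
  for (rep in 1:10) {
    pp <- tiny_population(v = 12, k = 3, n = 20, seed = rep)
    diffs <- paired_differences(pp$population)
    pm <- assign_network_pairs(pp$partition, pp$index)
    eng <- perm_engine(199, seed = rep)
    tm <- connbench:::perm_t_matrix(diffs, perm_sign_matrix(eng, 20))
    bon <- cnbs_network(diffs, pm, eng, pp$index, correction = "bonferroni",
                        perm_t = tm)
    sim <- cnbs_network(diffs, pm, eng, pp$index, correction = "simes",
                        perm_t = tm)
    key <- function(r) paste(r$detections$element, r$detections$sign)
    expect_true(all(key(bon) %in% key(sim)))
  }
})

test_that("network detections implicate exactly their pair's edges", {
  pp <- tiny_population(v = 12, k = 2, n = 30, seed = 6)
  diffs <- paired_differences(pp$population)
  pm <- assign_network_pairs(pp$partition, pp$index)
  res <- cnbs_network(diffs, pm, perm_engine(199, 2), pp$index)
  for (r in seq_len(nrow(res$detections))) {
    el <- as.integer(res$detections$element[r])
    edges <- which(pm$pair_of_edge == el)
    mask <- if (res$detections$sign[r] > 0) res$pos_edges else res$neg_edges
    expect_true(all(mask[edges]))
  }
})

test_that("whole-brain omnibus test behaves at the extremes", {
  pp <- tiny_population(v = 12, k = 2, n = 30, seed = 13)
  diffs <- paired_differences(pp$population)
  pm <- assign_network_pairs(pp$partition, pp$index)
  eng <- perm_engine(299, seed = 5)
  res <- mv_cnbs(diffs, pm, eng, pp$index)
  expect_true(res$wb_detected) # strong dense effects
  expect_equal(res$p_value, 1 / 300)
  # null data: p is rarely tiny (single dataset sanity, not a rate check)
  pp0 <- tiny_population(v = 12, k = 2, n = 30, seed = 14,
                         null_effects = TRUE)
  res0 <- mv_cnbs(paired_differences(pp0$population), pm, eng, pp0$index)
  expect_gt(res0$p_value, 0.01)
  expect_error(mv_cnbs(diffs, pm, perm_engine(3, 1), pp$index), "draws")
})

test_that("leave-one-out Mahalanobis matches direct recomputation", {
  set.seed(25)
  p <- 60
  x <- matrix(rnorm(p * 3), p, 3)
  mu <- colMeans(x)
  sig <- cov(x)
  d2_full <- stats::mahalanobis(x, mu, sig)
  got <- connbench:::loo_mahalanobis(d2_full, p)
  direct <- vapply(seq_len(p), function(i) {
    stats::mahalanobis(x[i, ], colMeans(x[-i, ]), cov(x[-i, ]))
  }, numeric(1))
  expect_equal(got, direct, tolerance = 1e-8)
})

test_that("the dispatcher routes ids and validates requirements", {
  pp <- tiny_population(v = 10, k = 2, n = 12, seed = 1)
  diffs <- paired_differences(pp$population)
  pm <- assign_network_pairs(pp$partition, pp$index)
  eng <- perm_engine(49, 1)
  for (p in connbench_procedures()) {
    res <- run_inference(diffs, p, engine = eng, pair_map = pm)
    expect_s3_class(res, "detections")
    expect_identical(res$procedure, p)
  }
  expect_error(run_inference(diffs, "nbs"), "engine")
  expect_error(run_inference(diffs, "cnbs-fdr", engine = eng), "pair_map")
})
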