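#' Estimate the full-sample ground truth
#'
#' Treats the full population sample as the truth for benchmarking:
#' edgewise paired Cohen's d, effect signs, and a two-sided significance
#' mask (Storey FDR at `alpha`); pooled network-level d and sign per
#' network pair, with network significance from two-sided permutation
#' p-values of the pooled t statistic (the same permutation pool recipe as
#' the network-level inference procedure), Storey-FDR corrected; and a
#' whole-brain non-null flag (true when at least one edge is significant).
#'
#' @param population A [paired_sample()] covering the full population.
#' @param partition A `node_partition`.
#' @param alpha Two-sided significance level for the masks (default 0.05).
#' @param lambda Storey lambda.
#' @param engine A [perm_engine()] for the network-level nulls; default
#'   `perm_engine(1000, seed)`.
#' @param seed Seed for the default engine.
#' @return Object of class `ground_truth_map`.
#' @export
estimate_ground_truth <- function(population, partition, alpha = 0.05,
                                  lambda = 0.5, engine = NULL, seed = 7L) {
  stopifnot(inherits(population, "paired_sample"),
            inherits(partition, "node_partition"))
  if (population$n_subjects < 3L) {
    stop("ground-truth estimation needs at least 3 subjects", call. = FALSE)
  }
  check_alpha(alpha)
  if (is.null(engine)) engine <- perm_engine(1000L, seed)
  index <- population$index
  pair_map <- assign_network_pairs(partition, index)
  diffs <- paired_differences(population)
  stats_full <- paired_t_and_d(diffs)
  sig_edge <- storey_qvalues(stats_full$p_two, lambda)$q <= alpha

  # network level: pooled d for effect size, pooled t against its
  # permutation null for significance (two-sided)
  d_network <- cnbs_stats(stats_full$d, pair_map)
  t_obs <- cnbs_stats(stats_full$t, pair_map)
  perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, nrow(diffs)))
  t_null <- cnbs_stats(perm_t, pair_map)
  np <- nrow(t_null)
  p_pos <- (1 + colSums(t_null >= rep(t_obs, each = np))) / (np + 1)
  p_neg <- (1 + colSums(t_null <= rep(t_obs, each = np))) / (np + 1)
  p_two_net <- pmin(1, 2 * pmin(p_pos, p_neg))
  sig_network <- storey_qvalues(p_two_net, lambda)$q <= alpha

  structure(
    list(d_edge = stats_full$d, sign_edge = sign(stats_full$d),
         sig_edge = sig_edge,
         d_network = d_network, sign_network = sign(d_network),
         sig_network = sig_network,
         whole_brain_nonnull = any(sig_edge),
         variant = "full", sparsity_cutoff = NA_real_,
         index = index, pair_map = pair_map, alpha = alpha),
    class = "ground_truth_map"
  )
}

#' @export
print.ground_truth_map <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth_map (%s): %d edges (%d significant), ",
                     "%d network pairs (%d significant)>\n"),
              x$variant, length(x$d_edge), sum(x$sig_edge),
              length(x$d_network), sum(x$sig_network)))
  invisible(x)
}

#' @export
tidy.ground_truth_map <- function(x, ...) {
  tibble::tibble(edge = seq_along(x$d_edge), d = x$d_edge,
                 sign = x$sign_edge, significant = x$sig_edge,
                 network_pair = x$pair_map$pair_of_edge)
}

#' Weak and sparse ground-truth variants
#'
#' `weak` multiplies all effect sizes by `param` (< 1), preserving signs.
#' `sparse` declares every element with `|d| <` `param` null: its sign and
#' significance are zeroed (any detection there counts as a false positive)
#' while d is retained for bookkeeping.
#'
#' @param gt A `ground_truth_map`.
#' @param kind `"weak"` or `"sparse"`.
#' @param param Shrinkage factor (weak) or `|d|` cutoff (sparse, e.g. 0.2).
#' @return A new `ground_truth_map`.
#' @export
derive_variant <- function(gt, kind = c("weak", "sparse"), param) {
  kind <- match.arg(kind)
  stopifnot(inherits(gt, "ground_truth_map"))
  if (length(param) != 1L || !is.finite(param) || param < 0 ||
      (kind == "weak" && param <= 0)) {
    stop("`param` must be a positive scalar", call. = FALSE)
  }
  out <- gt
  if (kind == "weak") {
    out$d_edge <- gt$d_edge * param
    out$d_network <- gt$d_network * param
    out$variant <- "weak"
  } else {
    null_e <- abs(gt$d_edge) < param
    null_n <- abs(gt$d_network) < param
    out$sign_edge[null_e] <- 0
    out$sig_edge[null_e] <- FALSE
    out$sign_network[null_n] <- 0
    out$sig_network[null_n] <- FALSE
    out$whole_brain_nonnull <- any(out$sig_edge)
    out$variant <- "sparse"
    out$sparsity_cutoff <- param
  }
  out
}

#' Count effect clusters at an absolute-d threshold
#'
#' Components of contiguous edges (shared nodes) computed separately on
#' `d > cutoff` and `d < -cutoff`.
#'
#' @param d_edge Per-edge effect sizes.
#' @param cutoff Positive `|d|` threshold (e.g. 0.8).
#' @param index The `edge_index`.
#' @return Named integer vector `c(positive = ..., negative = ...)`.
#' @export
count_clusters_at_threshold <- function(d_edge, cutoff,
                                        index = attr(d_edge, "index")) {
  stopifnot(inherits(index, "edge_index"))
  if (length(cutoff) != 1L || cutoff <= 0) {
    stop("`cutoff` must be a single positive value", call. = FALSE)
  }
  c(positive = length(edge_components(d_edge > cutoff, index)$sizes),
    negative = length(edge_components(d_edge < -cutoff, index)$sizes))
}

# one-way between/within variance ratio of values grouped by `groups`
f_stat <- function(values, groups) {
  k <- length(unique(groups))
  n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(gn * (gm - grand)^2)
  ssw <- sum((values - gm[match(groups, names(gm))])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Between-network heterogeneity of edge effects
#'
#' One-way F statistic of per-edge effect sizes grouped by network pair
#' (between- versus within-network-pair variance), with two permutation
#' nulls: (1) shuffling node-to-community memberships and regrouping, and
#' (2) shuffling effect values across edges separately within the
#' within-community edge set and within the between-community edge set
#' (preserving the within/between composition).
#'
#' @param d_edge Per-edge effect sizes.
#' @param partition A `node_partition`.
#' @param index The `edge_index`.
#' @param n_shuffles Number of permutations per null (default 1000).
#' @param seed Seed.
#' @return Object of class `heterogeneity_result`: list with `F`,
#'   `p_node_shuffle`, `p_edge_shuffle`, `n_shuffles`.
#' @export
network_heterogeneity <- function(d_edge, partition,
                                  index = attr(d_edge, "index"),
                                  n_shuffles = 1000L, seed = 1L) {
  stopifnot(inherits(partition, "node_partition"), inherits(index, "edge_index"))
  pair_map <- assign_network_pairs(partition, index)
  groups <- pair_map$pair_of_edge
  if (pair_map$n_pairs < 2L || any(pair_map$pairs$n_edges < 2L)) {
    stop("need >= 2 network pairs, each with >= 2 edges", call. = FALSE)
  }
  f_obs <- f_stat(d_edge, groups)
  labels <- as.integer(partition$node_community)
  ci <- labels[index$i]; cj <- labels[index$j]
  within_set <- ci == cj
  nulls <- withr::with_seed(seed, {
    f_node <- numeric(n_shuffles)
    f_edge <- numeric(n_shuffles)
    for (s in seq_len(n_shuffles)) {
      lab_s <- sample(labels)
      a <- pmin(lab_s[index$i], lab_s[index$j])
      b <- pmax(lab_s[index$i], lab_s[index$j])
      f_node[s] <- f_stat(d_edge, a * (max(b) + 1L) + b)
      d_s <- d_edge
      d_s[within_set] <- sample(d_edge[within_set])
      d_s[!within_set] <- sample(d_edge[!within_set])
      f_edge[s] <- f_stat(d_s, groups)
    }
    list(node = f_node, edge = f_edge)
  })
  structure(
    list(F = f_obs,
         p_node_shuffle = permutation_pvalue(f_obs, nulls$node, "ge"),
         p_edge_shuffle = permutation_pvalue(f_obs, nulls$edge, "ge"),
         n_shuffles = as.integer(n_shuffles)),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf(paste0("<heterogeneity: F = %.3f, p(node shuffle) = %.4g, ",
                     "p(edge shuffle) = %.4g, %d shuffles>\n"),
              x$F, x$p_node_shuffle, x$p_edge_shuffle, x$n_shuffles))
  invisible(x)
}

#' @export
glance.heterogeneity_result <- function(x, ...) {
  tibble::tibble(statistic = x$F, p_node_shuffle = x$p_node_shuffle,
                 p_edge_shuffle = x$p_edge_shuffle,
                 n_shuffles = x$n_shuffles)
}
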