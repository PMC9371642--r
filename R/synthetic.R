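#' Block-structured effect-size map
#'
#' Builds the target per-edge Cohen's d map the generator injects on the
#' paired task-minus-rest difference scale. The default layout emulates the
#' spatial signature of task-versus-rest contrasts: within-community
#' connectivity decreases (negative d), one designated community-pair block
#' (e.g. motor-visual) also decreases, and the remaining between-community
#' edges carry small, mostly positive effects drawn from a Gaussian.
#'
#' @param index An `edge_index`.
#' @param partition A `node_partition`.
#' @param delta_within Effect for within-community edges (default -0.5).
#' @param delta_block Effect for the designated between-community block
#'   (default -0.4).
#' @param block Length-2 vector of community labels (or indices) for the
#'   designated block; `NULL` for none.
#' @param between_mean,between_sd Gaussian parameters for the remaining
#'   between-community edges (defaults +0.1 and 0.1).
#' @param seed Seed for the Gaussian draw (deterministic map).
#' @return Numeric vector of per-edge target d values, attribute `index`.
#' @export
make_effect_map <- function(index, partition, delta_within = -0.5,
                            delta_block = -0.4, block = c(1, 2),
                            between_mean = 0.1, between_sd = 0.1,
                            seed = 1L) {
  stopifnot(inherits(index, "edge_index"), inherits(partition, "node_partition"))
  ci <- as.integer(partition$node_community)[index$i]
  cj <- as.integer(partition$node_community)[index$j]
  delta <- withr::with_seed(
    seed, stats::rnorm(index$n_edges, between_mean, between_sd))
  if (!is.null(block)) {
    if (length(block) != 2L) {
      stop("`block` must name exactly two communities", call. = FALSE)
    }
    bl <- if (is.numeric(block)) as.integer(block) else
      match(as.character(block), partition$communities)
    if (anyNA(bl) || any(bl < 1L | bl > partition$n_communities)) {
      stop("`block` labels not found in the partition", call. = FALSE)
    }
    in_block <- (ci == bl[1] & cj == bl[2]) | (ci == bl[2] & cj == bl[1])
    delta[in_block] <- delta_block
  }
  delta[ci == cj] <- delta_within
  attr(delta, "index") <- index
  delta
}

#' Generator specification for paired task/rest connectome populations
#'
#' @param index An `edge_index`.
#' @param partition A `node_partition`.
#' @param delta Target per-edge Cohen's d of the paired task-minus-rest
#'   difference (e.g. from [make_effect_map()]); `|delta|` capped at 2.
#' @param n_subjects Population size N.
#' @param rho Within-network-pair noise correlation loading in \[0, 1): the
#'   task noise of the edges of one network pair shares one Gaussian factor
#'   per subject with loading `rho` (pairwise correlation `rho^2`).
#' @param mu_within,mu_between Baseline connectivity means for within- and
#'   between-community edges (z-scored correlation units).
#' @param subject_sd Between-subject variability of baseline connectivity.
#' @param run_noise_sd Per-run measurement noise of the rest runs.
#' @param task_extra_noise_sd Optional extra task-condition noise emulating a
#'   shorter task scan; inflates the difference sd to
#'   `sqrt(1 + task_extra_noise_sd^2)`, so the realised d shrinks
#'   accordingly. Default 0 (off), in which case the population Cohen's d of
#'   the difference equals `delta` exactly.
#' @param seed Integer seed.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(index, partition, delta, n_subjects,
                           rho = 0, mu_within = 0.4, mu_between = 0.15,
                           subject_sd = 0.2, run_noise_sd = 0.3,
                           task_extra_noise_sd = 0, seed = 1L) {
  stopifnot(inherits(index, "edge_index"), inherits(partition, "node_partition"))
  if (length(delta) != index$n_edges) {
    stop("`delta` must have one entry per edge", call. = FALSE)
  }
  if (max(abs(delta)) > 2) {
    stop("|delta| must be bounded by 2", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) stop("`rho` must be in [0, 1)", call. = FALSE)
  if (n_subjects < 2) stop("`n_subjects` must be >= 2", call. = FALSE)
  pair_map <- assign_network_pairs(partition, index)
  ci <- as.integer(partition$node_community)[index$i]
  cj <- as.integer(partition$node_community)[index$j]
  mu <- ifelse(ci == cj, mu_within, mu_between)
  structure(
    list(index = index, partition = partition, pair_map = pair_map,
         delta = as.numeric(delta), mu = mu, rho = rho,
         subject_sd = subject_sd, run_noise_sd = run_noise_sd,
         task_extra_noise_sd = task_extra_noise_sd,
         n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
    class = "generator_spec"
  )
}

#' @export
print.generator_spec <- function(x, ...) {
  cat(sprintf(paste0("<generator_spec: V = %d, K = %d, N = %d, rho = %g, ",
                     "seed = %d>\n"),
              x$index$n_nodes, x$partition$n_communities, x$n_subjects,
              x$rho, x$seed))
  invisible(x)
}

#' Simulate a paired task/rest connectome population
#'
#' Per subject s and edge e, the two rest runs are
#' `rest_r = mu_e + u_se + v_ser` with subject effect `u` and run noise `v`
#' zero-mean Gaussian. The task condition adds the effect and unit-variance
#' task noise on top of the first rest run,
#' `task = rest_1 + delta_e + eps_se`,
#' `eps = sqrt(1 - rho^2) z + rho g_{s,k(e)}` with `z`, `g` standard normal
#' and `g` shared across the edges of network pair `k(e)`. The paired
#' task-minus-rest difference therefore has mean `delta_e` and unit standard
#' deviation, so the population Cohen's d equals `delta_e` exactly (the
#' ground truth is analytically known, not merely estimated).
#'
#' @param spec A [generator_spec()].
#' @return A [paired_sample()] with `condition_a` = task, `condition_b` =
#'   rest run 1 and `condition_b2` = rest run 2, plus attribute `delta`
#'   (the injected map).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_subjects
  e <- spec$index$n_edges
  k <- spec$pair_map$n_pairs
  withr::with_seed(spec$seed, {
    u <- matrix(stats::rnorm(n * e, 0, spec$subject_sd), n, e)
    base <- sweep(u, 2L, spec$mu, "+")
    rest1 <- base + matrix(stats::rnorm(n * e, 0, spec$run_noise_sd), n, e)
    rest2 <- base + matrix(stats::rnorm(n * e, 0, spec$run_noise_sd), n, e)
    eps <- matrix(stats::rnorm(n * e, 0, sqrt(1 - spec$rho^2)), n, e)
    if (spec$rho > 0) {
      g <- matrix(stats::rnorm(n * k), n, k)
      eps <- eps + spec$rho * g[, spec$pair_map$pair_of_edge, drop = FALSE]
    }
    if (spec$task_extra_noise_sd > 0) {
      eps <- eps + matrix(stats::rnorm(n * e, 0, spec$task_extra_noise_sd),
                          n, e)
    }
    task <- rest1 + rep(spec$delta, each = n) + eps
  })
  out <- paired_sample(task, rest1, spec$index, condition_b2 = rest2)
  attr(out, "delta") <- spec$delta
  out
}

#' Desk-scale default design
#'
#' A scaled-down stand-in for a large benchmarking design (hundreds of
#' atlas nodes, ten communities, a ~1,000-subject population): 60 nodes in 6
#' equal communities of 10, a 600-subject population, within-network-pair
#' noise correlation 0.3, and the default block effect map. The full
#' benchmark grid over this design runs in minutes on one CPU.
#'
#' @param n_subjects Population size (default 600).
#' @param rho Within-network-pair noise correlation (default 0.3).
#' @param seed Seed (default 42).
#' @param null_effects If `TRUE`, use an all-zero effect map (null
#'   generator) instead of the default block map.
#' @return A `generator_spec`.
#' @export
default_desk_scale_spec <- function(n_subjects = 600L, rho = 0.3,
                                    seed = 42L, null_effects = FALSE) {
  idx <- edge_index(60L)
  part <- node_partition(rep(1:6, each = 10L))
  delta <- if (null_effects) {
    structure(numeric(idx$n_edges), index = idx)
  } else {
    make_effect_map(idx, part, seed = seed)
  }
  generator_spec(idx, part, delta, n_subjects = n_subjects, rho = rho,
                 seed = seed)
}
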