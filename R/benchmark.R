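#' Resample a subject group from the population
#'
#' Draws `n` subjects without replacement; draws are independent across
#' repetitions and fully determined by `rep_seed`.
#'
#' @param population A [paired_sample()].
#' @param n Group size (`n <=` population size).
#' @param rep_seed Integer seed for this repetition.
#' @return A [paired_sample()] of `n` subjects (second null run carried
#'   along when present).
#' @export
resample_groups <- function(population, n, rep_seed) {
  stopifnot(inherits(population, "paired_sample"))
  if (n > population$n_subjects) {
    stop("`n` exceeds the population size", call. = FALSE)
  }
  pick <- withr::with_seed(rep_seed, sample.int(population$n_subjects, n))
  paired_sample(
    population$condition_a[pick, , drop = FALSE],
    population$condition_b[pick, , drop = FALSE],
    population$index,
    condition_b2 = if (!is.null(population$condition_b2))
      population$condition_b2[pick, , drop = FALSE]
  )
}

#' Build the fake task contrast from two rest runs
#'
#' Per subject, the two null (rest) runs are assigned to condition a/b in a
#' random order (independent fair coin), producing an exchangeable null
#' contrast used to estimate weak-sense FWER.
#'
#' @param sample A [paired_sample()] carrying a second null run
#'   (`condition_b2`).
#' @param rep_seed Integer seed for the per-subject shuffle.
#' @return A [paired_sample()] whose conditions are the shuffled rest runs.
#' @export
make_fake_contrast <- function(sample, rep_seed) {
  stopifnot(inherits(sample, "paired_sample"))
  if (is.null(sample$condition_b2)) {
    stop("fake contrast needs a second null run per subject", call. = FALSE)
  }
  n <- sample$n_subjects
  swap <- withr::with_seed(rep_seed, sample(c(TRUE, FALSE), n, replace = TRUE))
  a <- sample$condition_b
  b <- sample$condition_b2
  a[swap, ] <- sample$condition_b2[swap, , drop = FALSE]
  b[swap, ] <- sample$condition_b[swap, , drop = FALSE]
  paired_sample(a, b, sample$index)
}

#' Classify detections against the ground truth
#'
#' Sign-matched accounting at two granularities.
#'
#' *Edge level* (used for power of edge- and cluster-level procedures and
#' for spatial precision): an implicated edge is a true positive when its
#' detection sign matches the ground-truth edge sign, a false positive when
#' it is opposite or the ground-truth sign is 0 (sparse variants).
#'
#' *Detection level* (used for FDR, FWER and the spatial extent of false
#' positives): the units are the procedure's own detections — edges for
#' edge-level procedures, supra-threshold clusters for the network-based
#' statistic and components of significant edges for its threshold-free
#' variant (a cluster is a true positive when at least one member edge
#' matches the ground-truth sign, since a significant cluster implies an
#' effect for at least one edge within it), network pairs for pooled-network
#' procedures (sign of the pooled effect), and the signless whole-brain test
#' (true positive iff the ground truth is non-null anywhere). Under the fake
#' contrast every detection is a false positive.
#'
#' @param result A `detections` object.
#' @param gt A `ground_truth_map`.
#' @param contrast `"real"` or `"fake"`.
#' @return List with: `tp_elements` / `fp_elements` (logical per detection
#'   unit: edges, detected clusters, network pairs, or a scalar),
#'   `tp_edges` / `fp_edges` (edge-level sign accounting over implicated
#'   edges), `n_tp_detections` / `n_fp_detections` (detection-unit counts),
#'   and `fp_implicated` (logical over edges: edges implicated by
#'   false-positive detections).
#' @export
classify_detections <- function(result, gt, contrast = c("real", "fake")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(result, "detections"), inherits(gt, "ground_truth_map"))
  if (result$n_edges != length(gt$d_edge)) {
    stop("detections and ground truth index different edge sets", call. = FALSE)
  }
  e <- result$n_edges
  gs <- gt$sign_edge
  pos <- result$pos_edges
  neg <- result$neg_edges

  if (result$level == "whole_brain") {
    det <- result$wb_detected
    tp_el <- if (contrast == "fake") FALSE else det && gt$whole_brain_nonnull
    fp_el <- if (contrast == "fake") det else det && !gt$whole_brain_nonnull
    all_e <- rep(TRUE, e)
    return(list(
      tp_elements = tp_el, fp_elements = fp_el,
      tp_edges = if (isTRUE(tp_el)) all_e else logical(e),
      fp_edges = if (isTRUE(fp_el)) all_e else logical(e),
      n_tp_detections = as.integer(tp_el), n_fp_detections = as.integer(fp_el),
      fp_implicated = if (isTRUE(fp_el)) all_e else logical(e)))
  }

  # edge-level sign accounting over implicated edges
  if (contrast == "fake") {
    tp_edges <- logical(e)
    fp_edges <- pos | neg
  } else {
    tp_edges <- (pos & gs > 0) | (neg & gs < 0)
    fp_edges <- (pos & gs < 0) | (neg & gs > 0) | ((pos | neg) & gs == 0)
  }

  if (result$level == "edge") {
    return(list(tp_elements = tp_edges, fp_elements = fp_edges,
                tp_edges = tp_edges, fp_edges = fp_edges,
                n_tp_detections = sum(tp_edges),
                n_fp_detections = sum(fp_edges),
                fp_implicated = fp_edges))
  }

  if (result$level == "network") {
    k <- length(gt$sign_network)
    det_rows <- result$detections
    det_pos <- det_neg <- logical(k)
    det_pos[as.integer(det_rows$element[det_rows$sign > 0])] <- TRUE
    det_neg[as.integer(det_rows$element[det_rows$sign < 0])] <- TRUE
    gsn <- gt$sign_network
    if (contrast == "fake") {
      tp_el <- logical(k)
      fp_el <- det_pos | det_neg
    } else {
      tp_el <- (det_pos & gsn > 0) | (det_neg & gsn < 0)
      fp_el <- (det_pos & gsn < 0) | (det_neg & gsn > 0) |
        ((det_pos | det_neg) & gsn == 0)
    }
    fp_impl <- gt$pair_map$pair_of_edge %in% which(fp_el)
    return(list(tp_elements = tp_el, fp_elements = fp_el,
                tp_edges = tp_edges, fp_edges = fp_edges,
                n_tp_detections = sum(tp_el), n_fp_detections = sum(fp_el),
                fp_implicated = fp_impl))
  }

  # cluster level: detection units are the significant clusters per tail
  cl <- result$clusters
  cluster_tp <- function(edges, sign) {
    if (contrast == "fake") return(FALSE)
    if (sign > 0) any(gs[edges] > 0) else any(gs[edges] < 0)
  }
  tp_el <- c(vapply(cl$pos, cluster_tp, logical(1), sign = 1),
             vapply(cl$neg, cluster_tp, logical(1), sign = -1))
  fp_el <- !tp_el
  if (length(tp_el) == 0L) fp_el <- logical(0)
  fp_impl <- logical(e)
  for (cc in c(cl$pos[!vapply(cl$pos, cluster_tp, logical(1), sign = 1)],
               cl$neg[!vapply(cl$neg, cluster_tp, logical(1), sign = -1)])) {
    fp_impl[cc] <- TRUE
  }
  list(tp_elements = tp_el, fp_elements = fp_el,
       tp_edges = tp_edges, fp_edges = fp_edges,
       n_tp_detections = sum(tp_el), n_fp_detections = sum(fp_el),
       fp_implicated = fp_impl)
}

#' Benchmark experiment configuration
#'
#' @param procedures Character vector of procedure ids
#'   (see [connbench_procedures()]).
#' @param contrast `"real"` (task vs rest) or `"fake"` (two shuffled rest
#'   runs; the weak-sense FWER condition).
#' @param n Group size per repetition.
#' @param repetitions Number of resampling repetitions R.
#' @param alpha Nominal level (default 0.05).
#' @param n_permutations Permutation draws P per repetition (default 1000,
#'   enough to resolve the Bonferroni-corrected network-pair threshold at
#'   the suite's overall level); one draw set is shared by all permutation
#'   procedures of a repetition.
#' @param seed Base seed; the seed of repetition r is `bitwXor(seed, r)`, so
#'   any repetition can be re-run in isolation.
#' @param cdt,cdt_p NBS cluster-determining threshold (statistic form wins
#'   over the one-sided p form).
#' @param tfce A [tfce_params()].
#' @param lambda Storey lambda.
#' @param split_tails See [edge_bonferroni()].
#' @return Object of class `benchmark_config`.
#' @export
benchmark_config <- function(procedures = connbench_procedures(),
                             contrast = c("real", "fake"), n = 40L,
                             repetitions = 100L, alpha = 0.05,
                             n_permutations = 1000L, seed = 1L, cdt = NULL,
                             cdt_p = 0.01, tfce = tfce_params(),
                             lambda = 0.5, split_tails = TRUE) {
  contrast <- match.arg(contrast)
  procedures <- match.arg(procedures, connbench_procedures(),
                          several.ok = TRUE)
  if (repetitions < 1) stop("`repetitions` must be >= 1", call. = FALSE)
  check_alpha(alpha)
  structure(
    list(procedures = procedures, contrast = contrast, n = as.integer(n),
         repetitions = as.integer(repetitions), alpha = alpha,
         n_permutations = as.integer(n_permutations), seed = as.integer(seed),
         cdt = cdt, cdt_p = cdt_p, tfce = tfce, lambda = lambda,
         split_tails = split_tails),
    class = "benchmark_config"
  )
}

# deterministic per-repetition seed derivations (all below 2^31)
rep_seed_of <- function(base_seed, rep) bitwXor(as.integer(base_seed),
                                                as.integer(rep))
shuffle_seed_of <- function(rep_seed) bitwXor(rep_seed, 134775813L)
engine_seed_of <- function(rep_seed) bitwXor(rep_seed, 97531863L)

#' Run one benchmarking experiment
#'
#' The resampling loop: at each repetition a group of `config$n`
#' subjects is drawn from the population (for the fake contrast the two rest
#' runs are additionally shuffled per subject), edgewise statistics and one
#' shared set of sign-flip permutation draws are computed, every procedure
#' in the configuration is run, and its detections are classified against
#' the ground truth (optionally against several ground-truth variants at
#' once, reusing the identical detections). Accuracy measures are then
#' aggregated over repetitions by [compute_metrics()].
#'
#' @param config A [benchmark_config()].
#' @param population A [paired_sample()] population (with a second null run
#'   when `config$contrast == "fake"`).
#' @param gt A `ground_truth_map`, or a named list of variants (e.g.
#'   `list(full = gt, sparse = derive_variant(gt, "sparse", 0.2))`).
#' @param progress Print a line every `progress` repetitions (0 = silent).
#' @return Object of class `benchmark_result`: `summary` is a tibble with
#'   one row per procedure x ground-truth variant (metrics columns plus a
#'   `tpr` list-column of per-element true-positive rates), `config` the
#'   configuration echo.
#' @export
run_benchmark <- function(config, population, gt, progress = 0L) {
  stopifnot(inherits(config, "benchmark_config"),
            inherits(population, "paired_sample"))
  variants <- if (inherits(gt, "ground_truth_map")) list(full = gt) else gt
  stopifnot(length(variants) >= 1L,
            all(vapply(variants, inherits, logical(1), "ground_truth_map")))
  index <- population$index
  gt1 <- variants[[1L]]
  pair_map <- gt1$pair_map
  needs_pairs <- any(config$procedures %in% c("cnbs-fwer", "cnbs-fdr",
                                              "mv-cnbs"))
  if (needs_pairs && is.null(pair_map)) {
    stop("ground truth lacks the network pair map", call. = FALSE)
  }
  r_total <- config$repetitions
  acc <- list() # per procedure x variant accumulators
  key <- function(p, v) paste(p, v, sep = ".")
  for (p in config$procedures) {
    for (v in names(variants)) {
      lev <- procedure_level(p)
      n_el <- switch(lev, edge = , cluster = index$n_edges,
                     network = length(gt1$sign_network), whole_brain = 1L)
      acc[[key(p, v)]] <- list(
        level = lev, tp_count = numeric(n_el),
        n_tp = numeric(r_total), n_fp = numeric(r_total),
        n_tp_det = numeric(r_total), n_fp_det = numeric(r_total),
        n_fp_impl = numeric(r_total), any_det = logical(r_total))
    }
  }
  for (r in seq_len(r_total)) {
    rs <- rep_seed_of(config$seed, r)
    grp <- resample_groups(population, config$n, rs)
    if (config$contrast == "fake") {
      grp <- make_fake_contrast(grp, shuffle_seed_of(rs))
    }
    diffs <- paired_differences(grp)
    engine <- perm_engine(config$n_permutations, engine_seed_of(rs))
    perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, config$n))
    for (p in config$procedures) {
      res <- run_inference(diffs, p, engine = engine, pair_map = pair_map,
                           index = index, alpha = config$alpha,
                           cdt = config$cdt, cdt_p = config$cdt_p,
                           params = config$tfce, lambda = config$lambda,
                           split_tails = config$split_tails, perm_t = perm_t)
      for (v in names(variants)) {
        cl <- classify_detections(res, variants[[v]], config$contrast)
        a <- acc[[key(p, v)]]
        # power: edge level for edge- and cluster-level procedures, element
        # level for network- and whole-brain-level procedures
        a$tp_count <- a$tp_count +
          if (a$level %in% c("edge", "cluster")) cl$tp_edges else
            cl$tp_elements
        a$n_tp[r] <- sum(cl$tp_edges)
        a$n_fp[r] <- sum(cl$fp_edges)
        a$n_tp_det[r] <- cl$n_tp_detections
        a$n_fp_det[r] <- cl$n_fp_detections
        a$n_fp_impl[r] <- sum(cl$fp_implicated)
        a$any_det[r] <- nrow(res$detections) > 0L
        acc[[key(p, v)]] <- a
      }
    }
    if (progress > 0 && r %% progress == 0) {
      message(sprintf("[connbench] %s n=%d rep %d/%d", config$contrast,
                      config$n, r, r_total))
    }
  }
  rows <- list()
  for (p in config$procedures) {
    for (v in names(variants)) {
      a <- acc[[key(p, v)]]
      m <- compute_metrics(a, variants[[v]], config$alpha, r_total,
                           config$contrast, index$n_edges)
      rows[[key(p, v)]] <- dplyr::mutate(m, procedure = p, variant = v,
                                         contrast = config$contrast,
                                         n = config$n, .before = 1L)
    }
  }
  structure(list(summary = dplyr::bind_rows(rows), config = config),
            class = "benchmark_result")
}

procedure_level <- function(procedure) {
  switch(procedure,
         "edge-fwer" = , "edge-fdr" = "edge",
         "nbs" = , "nbs-tfce" = "cluster",
         "cnbs-fwer" = , "cnbs-fdr" = "network",
         "mv-cnbs" = "whole_brain",
         stop("unknown procedure id: ", procedure, call. = FALSE))
}

#' Aggregate classified repetitions into the six accuracy measures
#'
#' Power: per-element true-positive rate (elements are edges for edge- and
#' cluster-level procedures, network pairs for network-level, a scalar for
#' whole brain), its mean over non-null elements, and the proportion of
#' non-null elements at or above 80% power. Empirical FDR: per-repetition
#' FP/(TP+FP) over the procedure's own detections, averaged. Spatial extent
#' of false positives: per-repetition fraction of the connectome implicated
#' by false-positive detections, averaged. Spatial precision:
#' per-repetition fraction of implicated edges overlapping same-sign
#' ground-truth effects, averaged over repetitions with detections (NA for
#' the signless whole-brain test). FWER: fraction of repetitions with at
#' least one false-positive detection — strong sense under the real
#' contrast, weak sense (any detection) under the fake contrast — with the
#' 95% binomial validity bound `alpha + 1.96 sqrt(alpha (1-alpha) / R)`.
#'
#' @param acc Accumulated classification record (internal; see
#'   [run_benchmark()]).
#' @param gt The `ground_truth_map` used for classification.
#' @param alpha Nominal level.
#' @param r_total Number of repetitions R.
#' @param contrast `"real"` or `"fake"`.
#' @param n_edges Edge count E.
#' @return One-row tibble of metrics with a `tpr` list-column.
#' @export
compute_metrics <- function(acc, gt, alpha, r_total, contrast, n_edges) {
  tpr <- acc$tp_count / r_total
  nonnull <- switch(acc$level,
    edge = , cluster = gt$sign_edge != 0,
    network = gt$sign_network != 0,
    whole_brain = gt$whole_brain_nonnull)
  mean_power <- if (any(nonnull)) mean(tpr[nonnull]) else NA_real_
  prop80 <- if (any(nonnull)) mean(tpr[nonnull] >= 0.8) else NA_real_
  n_det <- acc$n_tp_det + acc$n_fp_det
  fdr_rep <- acc$n_fp_det / pmax(1, n_det)
  n_impl_edges <- acc$n_tp + acc$n_fp
  prec_rep <- ifelse(n_impl_edges > 0, acc$n_tp / n_impl_edges, NA_real_)
  upper <- alpha + 1.96 * sqrt(alpha * (1 - alpha) / r_total)
  fwer <- mean(acc$n_fp_det > 0)
  tibble::tibble(
    level = acc$level,
    mean_power = mean_power,
    prop_power_ge_80 = prop80,
    mean_fdr = mean(fdr_rep),
    mean_fdr_se = stats::sd(fdr_rep) / sqrt(r_total),
    fp_spatial_extent = mean(acc$n_fp_impl / n_edges),
    spatial_precision = if (acc$level == "whole_brain") NA_real_ else
      if (all(is.na(prec_rep))) NA_real_ else mean(prec_rep, na.rm = TRUE),
    fwer_strong = if (contrast == "real") fwer else NA_real_,
    fwer_weak = if (contrast == "fake") mean(acc$any_det) else NA_real_,
    fwer_bound = upper,
    fwer_valid = (if (contrast == "real") fwer else mean(acc$any_det)) <= upper,
    repetitions = r_total,
    tpr = list(tpr)
  )
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result: %s contrast, n = %d, R = %d>\n",
              x$config$contrast, x$config$n, x$config$repetitions))
  print(dplyr::select(x$summary, -"tpr"))
  invisible(x)
}

#' @export
glance.benchmark_result <- function(x, ...) {
  dplyr::select(x$summary, -"tpr")
}

#' @export
tidy.benchmark_result <- function(x, ...) {
  tidyr::unnest_longer(
    dplyr::select(x$summary, "procedure", "variant", "contrast", "n",
                  "level", "tpr"),
    "tpr", values_to = "tpr", indices_to = "element")
}

#' Power as a function of ground-truth effect size
#'
#' Bins edges by `|d|` and averages the per-edge true-positive rate within
#' each bin, with a Monte-Carlo standard error per bin.
#'
#' @param tpr_per_edge Per-edge true-positive rates (edge- or cluster-level
#'   procedure).
#' @param d_edge Ground-truth per-edge effect sizes.
#' @param bins Bin breaks on `|d|` (default 10 equal bins spanning the data).
#' @param repetitions R used to estimate `tpr` (for the MC standard error).
#' @return Tibble: `bin_lo`, `bin_hi`, `n_edges`, `mean_power`, `mc_se`
#'   (NA for empty bins).
#' @export
power_by_effect_size <- function(tpr_per_edge, d_edge, bins = 10L,
                                 repetitions = NULL) {
  ad <- abs(d_edge)
  if (length(bins) == 1L) {
    bins <- seq(0, max(ad) + 1e-12, length.out = bins + 1L)
  }
  if (length(bins) < 2L) stop("need at least one bin", call. = FALSE)
  cut_idx <- findInterval(ad, bins, rightmost.closed = TRUE)
  cut_idx[cut_idx == 0L] <- 1L
  k <- length(bins) - 1L
  out <- tibble::tibble(
    bin_lo = bins[-length(bins)], bin_hi = bins[-1L],
    n_edges = as.integer(tabulate(cut_idx, k)),
    mean_power = NA_real_, mc_se = NA_real_
  )
  for (b in seq_len(k)) {
    in_b <- cut_idx == b
    if (!any(in_b)) next
    p <- tpr_per_edge[in_b]
    out$mean_power[b] <- mean(p)
    if (!is.null(repetitions)) {
      out$mc_se[b] <- sqrt(sum(p * (1 - p) / repetitions)) / sum(in_b)
    }
  }
  out
}

#' Enumerate an experiment grid
#'
#' The Cartesian product of procedures, contrasts, and group sizes; one row
#' per experiment cell.
#'
#' @param procedures,contrasts,group_sizes The grid axes.
#' @return Tibble with columns `procedure`, `contrast`, `n`, `cell`.
#' @examples
#' # the full published design enumerates 7 x 8 x 3 = 168 experiments
#' nrow(experiment_grid_plan(
#'   connbench_procedures(),
#'   c(paste0("task", 1:7), "fake"),
#'   c(40, 80, 120)))
#' @export
experiment_grid_plan <- function(procedures, contrasts, group_sizes) {
  if (!length(procedures) || !length(contrasts) || !length(group_sizes)) {
    stop("all grid axes must be nonempty", call. = FALSE)
  }
  g <- tidyr::expand_grid(procedure = procedures, contrast = contrasts,
                          n = group_sizes)
  dplyr::mutate(g, cell = dplyr::row_number())
}

#' Run a grid of benchmarking experiments
#'
#' Executes [run_benchmark()] over contrasts x group sizes (all procedures
#' of a cell share the repetition's permutation draws), with an independent
#' deterministic seed per cell. Results are invariant to cell execution
#' order.
#'
#' @param population A [paired_sample()] population.
#' @param gt Ground truth (map or named list of variants).
#' @param procedures Procedure ids.
#' @param contrasts Subset of `c("real", "fake")`.
#' @param group_sizes Integer vector of group sizes.
#' @param repetitions R per cell.
#' @param seed Base seed; cell c uses `seed + 7919 * c`.
#' @param ... Further arguments to [benchmark_config()].
#' @return Object of class `benchmark_grid`: tibble of per-cell summaries.
#' @export
run_experiment_grid <- function(population, gt, procedures = connbench_procedures(),
                                contrasts = c("real", "fake"),
                                group_sizes = c(20L, 40L, 60L),
                                repetitions = 100L, seed = 1L, ...) {
  cells <- tidyr::expand_grid(contrast = contrasts, n = group_sizes)
  out <- vector("list", nrow(cells))
  for (cidx in seq_len(nrow(cells))) {
    cfg <- benchmark_config(
      procedures = procedures, contrast = cells$contrast[cidx],
      n = cells$n[cidx], repetitions = repetitions,
      seed = as.integer(seed + 7919L * cidx), ...)
    out[[cidx]] <- run_benchmark(cfg, population, gt)$summary
  }
  structure(dplyr::bind_rows(out),
            class = c("benchmark_grid", class(tibble::tibble())))
}
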