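#' @title Detection results
#' @description Internal constructor for the common result container of all
#'   inferential procedures. `pos_edges` / `neg_edges` are the implicated
#'   edges per tail (for edge procedures the detected edges themselves; for
#'   cluster procedures all edges of significant clusters; for network
#'   procedures all edges of significant pairs). The whole-brain procedure is
#'   signless and implicates every edge when it detects.
#' @noRd
new_detections <- function(procedure, level, alpha, detections, n_edges,
                           pos_edges = NULL, neg_edges = NULL,
                           wb_detected = FALSE, extra = list()) {
  if (is.null(pos_edges)) pos_edges <- logical(n_edges)
  if (is.null(neg_edges)) neg_edges <- logical(n_edges)
  structure(
    c(list(procedure = procedure, level = level, alpha = alpha,
           detections = detections, n_edges = n_edges,
           pos_edges = pos_edges, neg_edges = neg_edges,
           wb_detected = wb_detected),
      extra),
    class = "detections"
  )
}

#' @export
print.detections <- function(x, ...) {
  cat(sprintf("<detections: %s (%s level), alpha = %g>\n", x$procedure,
              x$level, x$alpha))
  cat(sprintf("  %d detection(s); %d / %d edges implicated\n",
              nrow(x$detections), sum(x$pos_edges | x$neg_edges) +
                if (x$wb_detected) x$n_edges else 0L, x$n_edges))
  invisible(x)
}

#' @export
tidy.detections <- function(x, ...) {
  dplyr::mutate(x$detections, procedure = x$procedure, level = x$level,
                .before = 1L)
}

#' @export
glance.detections <- function(x, ...) {
  tibble::tibble(
    procedure = x$procedure, level = x$level, alpha = x$alpha,
    n_detections = nrow(x$detections),
    n_implicated_edges = if (x$level == "whole_brain" && x$wb_detected)
      x$n_edges else sum(x$pos_edges | x$neg_edges)
  )
}

# nominal level per directional analysis: alpha/2 each by default so the
# two-sided suite has overall level alpha (split_tails = FALSE runs the two
# independent directional analyses at full alpha each instead)
tail_alpha <- function(alpha, split_tails) if (split_tails) alpha / 2 else alpha

#' Edge-level inference with Bonferroni FWER control
#'
#' Two one-sided edgewise t tests, each Bonferroni-corrected over the E
#' edges; a significant edge implies an effect at that edge.
#'
#' @param stats An `edge_stats` object from [paired_t_and_d()].
#' @param alpha Nominal FWER level.
#' @param split_tails If `TRUE` (default) each directional analysis runs at
#'   `alpha/2`, so the two-sided suite has overall level `alpha`; `FALSE`
#'   runs each tail at `alpha` (independent directional analyses).
#' @return A `detections` object (level `"edge"`).
#' @export
edge_bonferroni <- function(stats, alpha = 0.05, split_tails = TRUE) {
  stopifnot(inherits(stats, "edge_stats"))
  check_alpha(alpha)
  a <- tail_alpha(alpha, split_tails)
  e <- length(stats$t)
  pos <- stats$p_pos <= a / e
  neg <- stats$p_neg <= a / e
  det <- dplyr::bind_rows(
    tibble::tibble(element = which(pos), sign = 1,
                   stat = stats$t[pos], p_or_q = pmin(1, stats$p_pos[pos] * e)),
    tibble::tibble(element = which(neg), sign = -1,
                   stat = stats$t[neg], p_or_q = pmin(1, stats$p_neg[neg] * e))
  )
  new_detections("edge-fwer", "edge", alpha, det, e,
                 pos_edges = pos, neg_edges = neg)
}

#' Storey q-values
#'
#' The point-estimate Storey procedure: \eqn{\hat\pi_0 = \min(1,
#' \#\{p > \lambda\} / (m (1 - \lambda)))} and step-up q-values
#' \eqn{q_i = \min_{p_j \ge p_i} \hat\pi_0 \, m \, p_j / \mathrm{rank}(p_j)}.
#' With \eqn{\hat\pi_0 = 1} this reduces to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param pvals Vector of p-values in \[0, 1\].
#' @param lambda Tuning parameter in (0, 1) for the pi0 estimate; a fixed
#'   0.5 default (no smoother), appropriate for dense signal.
#' @return List with `pi0` and `q` (same order as `pvals`).
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.03, 0.9), lambda = 0.5)$q
#' @export
storey_qvalues <- function(pvals, lambda = 0.5) {
  if (length(lambda) != 1L || lambda <= 0 || lambda >= 1) {
    stop("`lambda` must be in (0, 1)", call. = FALSE)
  }
  if (any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  # floored at 1/m: a zero estimate (no p beyond lambda) would zero every
  # q-value regardless of the p-values themselves
  pi0 <- min(1, max(1 / m, sum(pvals > lambda) / (m * (1 - lambda))))
  o <- order(pvals)
  q_ord <- pi0 * m * pvals[o] / seq_len(m)
  q_ord <- rev(cummin(rev(q_ord)))
  q <- numeric(m)
  q[o] <- pmin(1, q_ord)
  list(pi0 = pi0, q = q)
}

#' Edge-level inference with Storey FDR control
#'
#' Two one-sided analyses; within each tail, q-values from [storey_qvalues()]
#' on the one-sided p-values, detecting edges with `q <= alpha`.
#'
#' @inheritParams edge_bonferroni
#' @param lambda Storey pi0 tuning parameter.
#' @return A `detections` object (level `"edge"`).
#' @export
edge_storey_fdr <- function(stats, alpha = 0.05, lambda = 0.5,
                            split_tails = TRUE) {
  stopifnot(inherits(stats, "edge_stats"))
  check_alpha(alpha)
  a <- tail_alpha(alpha, split_tails)
  e <- length(stats$t)
  qp <- storey_qvalues(stats$p_pos, lambda)$q
  qn <- storey_qvalues(stats$p_neg, lambda)$q
  pos <- qp <= a
  neg <- qn <= a
  det <- dplyr::bind_rows(
    tibble::tibble(element = which(pos), sign = 1,
                   stat = stats$t[pos], p_or_q = qp[pos]),
    tibble::tibble(element = which(neg), sign = -1,
                   stat = stats$t[neg], p_or_q = qn[neg])
  )
  new_detections("edge-fdr", "edge", alpha, det, e,
                 pos_edges = pos, neg_edges = neg)
}

#' Connected components of supra-threshold edges
#'
#' Two supra-threshold edges belong to the same component when they are
#' linked by a chain of supra-threshold edges sharing nodes (the cluster
#' definition of the network-based statistic).
#'
#' @param supra_mask Logical vector over edges (TRUE = supra-threshold).
#' @param index The `edge_index`.
#' @return List with `components` (list of integer edge-id vectors) and
#'   `sizes` (edge counts), ordered by first edge appearance.
#' @export
edge_components <- function(supra_mask, index) {
  stopifnot(inherits(index, "edge_index"))
  if (length(supra_mask) != index$n_edges) {
    stop("`supra_mask` length must equal the edge count", call. = FALSE)
  }
  ids <- which(supra_mask)
  if (length(ids) == 0L) {
    return(list(components = list(), sizes = integer(0)))
  }
  lab <- cc_label_cpp(index$i[ids], index$j[ids], index$n_nodes)
  comps <- split(ids, lab)
  names(comps) <- NULL
  list(components = comps, sizes = lengths(comps))
}

# default cluster-determining threshold: the t quantile of a one-sided
# p = cdt_p test at the sample's degrees of freedom
default_cdt <- function(df, cdt_p = 0.01) stats::qt(1 - cdt_p, df = df)

#' Cluster-level inference: the network-based statistic (NBS)
#'
#' Per tail, edges with one-sided t beyond the cluster-determining threshold
#' (CDT) form connected components; each observed component's edge count is
#' compared against the permutation null of the maximum component size
#' (max-statistic FWER control). A significant cluster implies an effect for
#' at least one edge within it; all its edges are implicated.
#'
#' @param diffs `n x E` matrix of paired differences with the `edge_index`
#'   as attribute `index` (as returned by [paired_differences()]).
#' @param engine A [perm_engine()].
#' @param index The `edge_index` (taken from `diffs` if absent).
#' @param cdt Cluster-determining threshold on the t statistic; default is
#'   the t quantile at one-sided `cdt_p` for the sample's df.
#' @param cdt_p One-sided p-value form of the CDT (used when `cdt` is NULL).
#' @param alpha Nominal FWER level.
#' @param split_tails See [edge_bonferroni()].
#' @param perm_t Optional precomputed `P x E` permutation t matrix (rows =
#'   draws), so several procedures can share one set of draws.
#' @return A `detections` object (level `"cluster"`); elements are clusters
#'   labelled `pos_k` / `neg_k`.
#' @export
nbs_cluster <- function(diffs, engine, index = attr(diffs, "index"),
                        cdt = NULL, cdt_p = 0.01, alpha = 0.05,
                        split_tails = TRUE, perm_t = NULL) {
  stopifnot(inherits(index, "edge_index"), inherits(engine, "perm_engine"))
  check_alpha(alpha)
  if (is.null(cdt)) cdt <- default_cdt(nrow(diffs) - 1L, cdt_p)
  if (!is.numeric(cdt) || length(cdt) != 1L || cdt <= 0) {
    stop("`cdt` must be a single positive statistic threshold", call. = FALSE)
  }
  a <- tail_alpha(alpha, split_tails)
  obs <- paired_t_and_d(diffs)
  if (is.null(perm_t)) {
    perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, nrow(diffs)))
  }
  e <- index$n_edges
  pos_edges <- logical(e); neg_edges <- logical(e)
  clusters <- list(pos = list(), neg = list())
  rows <- list()
  for (tail in c("pos", "neg")) {
    tv <- if (tail == "pos") obs$t else -obs$t
    cc <- edge_components(tv > cdt, index)
    if (length(cc$sizes) == 0L) next
    null_max <- perm_max_component_cpp(
      if (tail == "pos") perm_t else -perm_t, index$i, index$j,
      index$n_nodes, cdt)
    pvals <- permutation_pvalues(cc$sizes, null_max, "ge")
    sig <- which(pvals <= a)
    clusters[[tail]] <- cc$components[sig]
    for (kk in sig) {
      edges <- cc$components[[kk]]
      if (tail == "pos") pos_edges[edges] <- TRUE else neg_edges[edges] <- TRUE
    }
    rows[[tail]] <- tibble::tibble(
      element = paste0(tail, "_", seq_along(cc$sizes)),
      sign = if (tail == "pos") 1 else -1,
      stat = as.numeric(cc$sizes), p_or_q = pvals,
      n_implicated = as.integer(cc$sizes)
    )[sig, , drop = FALSE]
  }
  det <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(element = character(0), sign = numeric(0),
                   stat = numeric(0), p_or_q = numeric(0),
                   n_implicated = integer(0))
  new_detections("nbs", "cluster", alpha, det, e,
                 pos_edges = pos_edges, neg_edges = neg_edges,
                 extra = list(cdt = cdt, clusters = clusters))
}

#' TFCE parameters
#'
#' @param extent_exponent Exponent on component extent (edges), default 0.5.
#' @param height_exponent Exponent on threshold height, default 2.
#' @param n_steps Number of integration steps, default 100.
#' @return Object of class `tfce_params`.
#' @export
tfce_params <- function(extent_exponent = 0.5, height_exponent = 2,
                        n_steps = 100L) {
  if (extent_exponent <= 0 || height_exponent < 0 || n_steps < 1) {
    stop("invalid TFCE parameters", call. = FALSE)
  }
  structure(list(extent_exponent = extent_exponent,
                 height_exponent = height_exponent,
                 n_steps = as.integer(n_steps)),
            class = "tfce_params")
}

#' Threshold-free cluster enhancement over the connectome graph
#'
#' For each edge, integrates component extent and statistic height over
#' `n_steps` thresholds spanning (0, max(t)\]:
#' \eqn{\mathrm{tfce}(e) = \sum_k \mathrm{extent}_k(e)^{E}\, h_k^{H}\, \Delta h},
#' where extent is the edge count of the supra-threshold component containing
#' the edge at height \eqn{h_k}. Applied to the positive part of the
#' statistic; all-nonpositive input yields all-zero scores.
#'
#' @param t Numeric vector of edgewise statistics (one tail).
#' @param index The `edge_index`.
#' @param params A [tfce_params()].
#' @return Numeric vector of TFCE scores per edge.
#' @export
tfce_transform <- function(t, index, params = tfce_params()) {
  stopifnot(inherits(index, "edge_index"), inherits(params, "tfce_params"))
  if (length(t) != index$n_edges) {
    stop("`t` length must equal the edge count", call. = FALSE)
  }
  tfce_cpp(pmax(t, 0), index$i, index$j, index$n_nodes,
           params$extent_exponent, params$height_exponent, params$n_steps)
}

#' Cluster-level inference: threshold-free NBS (TFCE)
#'
#' Per tail, each edge's TFCE score is compared against the permutation null
#' of the maximum TFCE score over edges (max-statistic FWER control). A
#' significant edge implies an effect for at least one edge in the clusters
#' associated with it.
#'
#' @inheritParams nbs_cluster
#' @param params A [tfce_params()].
#' @return A `detections` object (level `"cluster"`, elements are edges).
#' @export
nbs_tfce <- function(diffs, engine, index = attr(diffs, "index"),
                     params = tfce_params(), alpha = 0.05,
                     split_tails = TRUE, perm_t = NULL) {
  stopifnot(inherits(index, "edge_index"), inherits(engine, "perm_engine"),
            inherits(params, "tfce_params"))
  check_alpha(alpha)
  a <- tail_alpha(alpha, split_tails)
  obs <- paired_t_and_d(diffs)
  if (is.null(perm_t)) {
    perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, nrow(diffs)))
  }
  e <- index$n_edges
  pos_edges <- logical(e); neg_edges <- logical(e)
  rows <- list()
  for (tail in c("pos", "neg")) {
    tv <- if (tail == "pos") obs$t else -obs$t
    sc <- tfce_transform(tv, index, params)
    null_max <- sort(perm_max_tfce_cpp(
      if (tail == "pos") perm_t else -perm_t, index$i, index$j,
      index$n_nodes, params$extent_exponent, params$height_exponent,
      params$n_steps))
    np <- length(null_max)
    # p(e) = (1 + #{null_max >= sc}) / (P + 1), vectorized over edges
    pvals <- (1 + np - findInterval(sc, null_max, left.open = TRUE)) / (np + 1)
    det_tail <- sc > 0 & pvals <= a
    if (tail == "pos") pos_edges <- det_tail else neg_edges <- det_tail
    rows[[tail]] <- tibble::tibble(
      element = which(det_tail), sign = if (tail == "pos") 1 else -1,
      stat = sc[det_tail], p_or_q = pvals[det_tail]
    )
  }
  det <- dplyr::bind_rows(rows)
  # significant TFCE edges cluster into components per tail: those are the
  # detection units for error accounting
  clusters <- list(
    pos = edge_components(pos_edges, index)$components,
    neg = edge_components(neg_edges, index)$components
  )
  new_detections("nbs-tfce", "cluster", alpha, det, e,
                 pos_edges = pos_edges, neg_edges = neg_edges,
                 extra = list(clusters = clusters))
}

#' Pooled network statistics (cNBS)
#'
#' @param t Numeric vector of edgewise statistics, or a `P x E` matrix (one
#'   row per permutation draw).
#' @param pair_map A `network_pair_map` from [assign_network_pairs()].
#' @return For a vector, the vector of network-pair means (length
#'   `n_pairs`); for a matrix, a `P x n_pairs` matrix.
#' @export
cnbs_stats <- function(t, pair_map) {
  stopifnot(inherits(pair_map, "network_pair_map"))
  if (any(pair_map$pairs$n_edges == 0L)) {
    stop("every network pair must contain at least one edge", call. = FALSE)
  }
  w <- pool_weights(pair_map)
  if (is.matrix(t)) t %*% w else drop(t %*% w)
}

# E x n_pairs averaging weights
pool_weights <- function(pair_map) {
  e <- length(pair_map$pair_of_edge)
  k <- pair_map$n_pairs
  w <- matrix(0, e, k)
  w[cbind(seq_len(e), pair_map$pair_of_edge)] <-
    1 / pair_map$pairs$n_edges[pair_map$pair_of_edge]
  w
}

#' Network-level inference: cNBS with Bonferroni or Simes correction
#'
#' Pools edgewise t statistics within each predefined network pair, compares
#' each pooled statistic to its permutation null, and corrects the
#' network-pair p-values per tail either by Bonferroni (FWER) or by the
#' Simes/Benjamini-Hochberg step-up (FDR). A significant network implies an
#' effect for the pooled network but not for any edge in particular; its
#' edges are nevertheless implicated for spatial bookkeeping.
#'
#' @inheritParams nbs_cluster
#' @param pair_map A `network_pair_map`.
#' @param correction `"bonferroni"` or `"simes"`.
#' @return A `detections` object (level `"network"`, elements are pair ids).
#' @export
cnbs_network <- function(diffs, pair_map, engine,
                         index = attr(diffs, "index"),
                         alpha = 0.05, correction = c("bonferroni", "simes"),
                         split_tails = TRUE, perm_t = NULL) {
  correction <- match.arg(correction)
  stopifnot(inherits(pair_map, "network_pair_map"),
            inherits(engine, "perm_engine"))
  check_alpha(alpha)
  a <- tail_alpha(alpha, split_tails)
  obs <- paired_t_and_d(diffs)
  if (is.null(perm_t)) {
    perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, nrow(diffs)))
  }
  t_obs <- cnbs_stats(obs$t, pair_map)
  t_null <- cnbs_stats(perm_t, pair_map)
  np <- nrow(t_null)
  k <- pair_map$n_pairs
  p_pos <- (1 + colSums(t_null >= rep(t_obs, each = np))) / (np + 1)
  p_neg <- (1 + colSums(t_null <= rep(t_obs, each = np))) / (np + 1)
  sel <- function(p) {
    if (correction == "bonferroni") {
      list(det = p <= a / k, q = pmin(1, p * k))
    } else {
      q <- stats::p.adjust(p, method = "BH")
      list(det = q <= a, q = q)
    }
  }
  sp <- sel(p_pos); sn <- sel(p_neg)
  e <- index$n_edges
  pos_edges <- pair_map$pair_of_edge %in% which(sp$det)
  neg_edges <- pair_map$pair_of_edge %in% which(sn$det)
  det <- dplyr::bind_rows(
    tibble::tibble(element = which(sp$det), sign = 1,
                   stat = t_obs[sp$det], p_or_q = sp$q[sp$det]),
    tibble::tibble(element = which(sn$det), sign = -1,
                   stat = t_obs[sn$det], p_or_q = sn$q[sn$det])
  )
  proc <- if (correction == "bonferroni") "cnbs-fwer" else "cnbs-fdr"
  new_detections(proc, "network", alpha, det, e,
                 pos_edges = pos_edges, neg_edges = neg_edges,
                 extra = list(p_pos = p_pos, p_neg = p_neg,
                              network_stats = t_obs))
}

#' Whole-brain inference: multivariate cNBS (mv-cNBS)
#'
#' An omnibus test of the pooled-network statistic vector. The observed
#' vector T is compared to the permutation null cloud via the squared
#' Mahalanobis distance \eqn{D^2 = (T - \hat\mu)' \hat\Sigma^{-1} (T -
#' \hat\mu)} with \eqn{\hat\mu, \hat\Sigma} estimated from the null draws
#' (ridge-regularised). Null reference distances are exact leave-one-out
#' distances of each draw against the remaining draws, so observed and null
#' values are on the same footing. The test is two-sided in each coordinate
#' (a test of inequality) and carries no sign.
#'
#' @inheritParams cnbs_network
#' @param ridge Ridge coefficient: `Sigma + eps I` with
#'   `eps = ridge * trace(Sigma) / n_pairs`.
#' @return A `detections` object (level `"whole_brain"`).
#' @export
mv_cnbs <- function(diffs, pair_map, engine, index = attr(diffs, "index"),
                    alpha = 0.05, ridge = 1e-6, perm_t = NULL) {
  stopifnot(inherits(pair_map, "network_pair_map"),
            inherits(engine, "perm_engine"))
  check_alpha(alpha)
  obs <- paired_t_and_d(diffs)
  if (is.null(perm_t)) {
    perm_t <- perm_t_matrix(diffs, perm_sign_matrix(engine, nrow(diffs)))
  }
  t_obs <- cnbs_stats(obs$t, pair_map)
  t_null <- cnbs_stats(perm_t, pair_map)
  np <- nrow(t_null)
  k <- pair_map$n_pairs
  if (np < k + 2) {
    stop(sprintf(paste0("mv-cNBS needs at least n_pairs + 2 = %d permutation",
                        " draws to estimate the null covariance"), k + 2),
         call. = FALSE)
  }
  mu <- colMeans(t_null)
  sigma <- stats::cov(t_null)
  eps <- ridge * sum(diag(sigma)) / k
  sigma_r <- sigma + diag(eps, k)
  d2 <- tryCatch({
    d2_obs <- stats::mahalanobis(t_obs, mu, sigma_r)
    d2_full <- stats::mahalanobis(t_null, mu, sigma_r)
    list(obs = d2_obs, null = loo_mahalanobis(d2_full, np))
  }, error = function(e) {
    stop("null covariance is singular even after ridge regularisation: ",
         conditionMessage(e), call. = FALSE)
  })
  p <- permutation_pvalue(d2$obs, d2$null, "ge")
  detected <- p <= alpha
  det <- if (detected) {
    tibble::tibble(element = "whole_brain", sign = NA_real_,
                   stat = d2$obs, p_or_q = p)
  } else {
    tibble::tibble(element = character(0), sign = numeric(0),
                   stat = numeric(0), p_or_q = numeric(0))
  }
  new_detections("mv-cnbs", "whole_brain", alpha, det, index$n_edges,
                 wb_detected = detected,
                 extra = list(d2_obs = d2$obs, p_value = p))
}

# Exact leave-one-out squared Mahalanobis distances from the full-sample
# ones (rank-one mean/covariance downdate; monotone in the full-sample
# distance). d2_full are distances of each of the P draws to the full-sample
# mean/covariance (unbiased covariance).
loo_mahalanobis <- function(d2_full, p) {
  c2 <- (p / (p - 1))^2
  u <- d2_full / (p - 1)
  denom <- 1 - (p / (p - 1)) * u
  out <- c2 * (p - 2) * u / denom
  out[denom <= 0] <- Inf
  out
}

check_alpha <- function(alpha) {
  if (length(alpha) != 1L || !is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
}

#' Run one inferential procedure by id
#'
#' Dispatcher over the seven procedures, used by the benchmarking harness
#' and the command-line interface. Procedure ids: `"edge-fwer"`,
#' `"edge-fdr"`, `"nbs"`, `"nbs-tfce"`, `"cnbs-fwer"`, `"cnbs-fdr"`,
#' `"mv-cnbs"`.
#'
#' @param diffs `n x E` matrix of paired differences (attribute `index`
#'   required unless `index` given).
#' @param procedure Procedure id.
#' @param engine A [perm_engine()] (required for permutation procedures).
#' @param pair_map A `network_pair_map` (required for network and
#'   whole-brain procedures).
#' @param index The `edge_index`.
#' @param alpha Nominal level.
#' @param cdt,cdt_p NBS cluster-determining threshold (statistic or p form).
#' @param params TFCE parameters.
#' @param lambda Storey lambda.
#' @param split_tails See [edge_bonferroni()].
#' @param perm_t Optional shared `P x E` permutation t matrix.
#' @return A `detections` object.
#' @export
run_inference <- function(diffs, procedure, engine = NULL, pair_map = NULL,
                          index = attr(diffs, "index"), alpha = 0.05,
                          cdt = NULL, cdt_p = 0.01, params = tfce_params(),
                          lambda = 0.5, split_tails = TRUE, perm_t = NULL) {
  procedure <- match.arg(procedure, connbench_procedures())
  needs_perm <- !procedure %in% c("edge-fwer", "edge-fdr")
  if (needs_perm && is.null(engine)) {
    stop("`engine` is required for permutation-based procedures", call. = FALSE)
  }
  if (procedure %in% c("cnbs-fwer", "cnbs-fdr", "mv-cnbs") &&
      is.null(pair_map)) {
    stop("`pair_map` is required for network and whole-brain procedures",
         call. = FALSE)
  }
  switch(procedure,
    "edge-fwer" = edge_bonferroni(paired_t_and_d(diffs), alpha, split_tails),
    "edge-fdr" = edge_storey_fdr(paired_t_and_d(diffs), alpha, lambda,
                                 split_tails),
    "nbs" = nbs_cluster(diffs, engine, index, cdt, cdt_p, alpha, split_tails,
                        perm_t),
    "nbs-tfce" = nbs_tfce(diffs, engine, index, params, alpha, split_tails,
                          perm_t),
    "cnbs-fwer" = cnbs_network(diffs, pair_map, engine, index, alpha,
                               "bonferroni", split_tails, perm_t),
    "cnbs-fdr" = cnbs_network(diffs, pair_map, engine, index, alpha,
                              "simes", split_tails, perm_t),
    "mv-cnbs" = mv_cnbs(diffs, pair_map, engine, index, alpha,
                        perm_t = perm_t)
  )
}

#' The seven procedure ids
#'
#' @return Character vector of the procedure identifiers, ordered from the
#'   most focal (edge) to the broadest (whole brain) scale of inference.
#' @export
connbench_procedures <- function() {
  c("edge-fwer", "edge-fdr", "nbs", "nbs-tfce", "cnbs-fwer", "cnbs-fdr",
    "mv-cnbs")
}
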