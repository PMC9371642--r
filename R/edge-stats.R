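#' Per-subject paired differences
#'
#' @param sample A [paired_sample()].
#' @return Numeric `n_subjects x n_edges` matrix of `condition_a -
#'   condition_b` differences, with the `edge_index` attached as attribute
#'   `index`.
#' @export
paired_differences <- function(sample) {
  stopifnot(inherits(sample, "paired_sample"))
  if (sample$n_subjects < 2L) {
    stop("need at least 2 subjects for a paired analysis", call. = FALSE)
  }
  d <- sample$condition_a - sample$condition_b
  attr(d, "index") <- sample$index
  d
}

#' Edgewise paired t-statistics and Cohen's d
#'
#' For each edge, computes the one-sample t statistic of the paired
#' differences, \eqn{t = \bar{x} / (s / \sqrt{n})} with the sample (n-1)
#' standard deviation, the paired Cohen's d \eqn{d = \bar{x} / s}, and
#' parametric one- and two-sided p-values from the t reference with n-1
#' degrees of freedom. Zero-variance edges are flagged: t = 0 when the mean
#' is also zero, and t = +/-Inf (p = 0 on the matching tail) otherwise.
#'
#' @param diffs `n x E` matrix of per-subject paired differences
#'   (rows = subjects), e.g. from [paired_differences()].
#' @return Object of class `edge_stats`: list with vectors `t`, `d`,
#'   `p_two`, `p_pos`, `p_neg`, scalar `df` and `n`, and logical
#'   `degenerate` marking zero-variance edges.
#' @examples
#' s <- paired_t_and_d(cbind(c(2, 0, 4, 2)))
#' s$t  # 2.449...
#' @export
paired_t_and_d <- function(diffs) {
  if (!is.matrix(diffs)) diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 2L) stop("need at least 2 subjects", call. = FALSE)
  m <- colMeans(diffs)
  v <- (colSums(diffs^2) - n * m^2) / (n - 1)
  v[v < 0] <- 0 # guard tiny negative round-off
  s <- sqrt(v)
  degenerate <- s == 0
  t <- m / (s / sqrt(n))
  d <- m / s
  t[degenerate & m == 0] <- 0
  d[degenerate & m == 0] <- 0
  # zero sd, nonzero mean: infinite t with the sign of the mean
  inf_idx <- degenerate & m != 0
  t[inf_idx] <- sign(m[inf_idx]) * Inf
  d[inf_idx] <- sign(m[inf_idx]) * Inf
  p_pos <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  p_neg <- stats::pt(t, df = n - 1, lower.tail = TRUE)
  p_two <- 2 * pmin(p_pos, p_neg)
  p_two[p_two > 1] <- 1
  structure(
    list(t = t, d = d, p_two = p_two, p_pos = p_pos, p_neg = p_neg,
         df = n - 1L, n = n, degenerate = degenerate),
    class = "edge_stats"
  )
}

#' @export
print.edge_stats <- function(x, ...) {
  cat(sprintf("<edge_stats: %d edges, df = %d>\n", length(x$t), x$df))
  invisible(x)
}

#' @export
tidy.edge_stats <- function(x, ...) {
  tibble::tibble(
    edge = seq_along(x$t), t = x$t, d = x$d,
    p_two = x$p_two, p_pos = x$p_pos, p_neg = x$p_neg,
    degenerate = x$degenerate
  )
}

#' Sign-flip permutation engine for paired designs
#'
#' The exact null scheme for a paired contrast: under exchangeability of the
#' two condition labels within subject, each subject's difference vector may
#' be multiplied by an independent fair +/-1. Draw 0 is reserved for the
#' identity (observed) labelling; draws `1..n_permutations` are random.
#' All draws are a pure function of `(seed, draw)`.
#'
#' @param n_permutations Number of random draws P.
#' @param seed Integer seed.
#' @return Object of class `perm_engine`.
#' @export
perm_engine <- function(n_permutations = 1000L, seed = 1L) {
  if (n_permutations < 1) stop("`n_permutations` must be >= 1", call. = FALSE)
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "perm_engine")
}

#' @export
print.perm_engine <- function(x, ...) {
  cat(sprintf("<perm_engine: P = %d, seed = %d>\n", x$n_permutations, x$seed))
  invisible(x)
}

#' Sign matrix of all permutation draws
#'
#' @param engine A [perm_engine()].
#' @param n_subjects Number of subjects (columns).
#' @return `P x n_subjects` matrix of +/-1, row p = draw p. Generated in one
#'   deterministic pass so any row is reproducible from `(seed, draw)`.
#' @export
perm_sign_matrix <- function(engine, n_subjects) {
  stopifnot(inherits(engine, "perm_engine"))
  withr::with_seed(
    engine$seed,
    matrix(sample(c(-1, 1), engine$n_permutations * n_subjects, replace = TRUE),
           nrow = engine$n_permutations, ncol = n_subjects)
  )
}

#' Signs for one permutation draw
#'
#' @inheritParams perm_sign_matrix
#' @param draw Draw index in `0..P`; 0 is the identity labelling.
#' @return Numeric vector of +/-1 of length `n_subjects`.
#' @export
perm_signs <- function(engine, n_subjects, draw) {
  stopifnot(inherits(engine, "perm_engine"))
  if (length(draw) != 1L || draw < 0 || draw > engine$n_permutations) {
    stop("`draw` must be in 0..n_permutations", call. = FALSE)
  }
  if (draw == 0) return(rep(1, n_subjects))
  perm_sign_matrix(engine, n_subjects)[draw, ]
}

#' Edgewise statistics under one sign-flip draw
#'
#' @param diffs `n x E` matrix of paired differences.
#' @param engine A [perm_engine()].
#' @param draw Draw index (0 = observed labelling).
#' @return An `edge_stats` object for the sign-flipped differences.
#' @export
permuted_stats <- function(diffs, engine, draw) {
  s <- perm_signs(engine, nrow(diffs), draw)
  paired_t_and_d(diffs * s)
}

# Fast path shared by all permutation procedures: t statistics for every
# draw at once. Sign flips leave sum(x^2) unchanged, so only the means need
# the P x n by n x E product; one BLAS call dominates.
perm_t_matrix <- function(diffs, signs) {
  n <- nrow(diffs)
  m <- (signs %*% diffs) / n
  css <- colSums(diffs^2)
  v <- sweep(-n * m^2, 2L, css, "+") / (n - 1)
  v[v < 0] <- 0
  t <- m / sqrt(v / n)
  t[!is.finite(t) & m == 0] <- 0
  t
}

#' Permutation p-value with the add-one convention
#'
#' \eqn{p = (1 + \#\{null \succeq observed\}) / (P + 1)}; the observed
#' statistic counts as one of its own null draws, so p is never 0 and the
#' test is valid at any finite P. Ties count against the observed value
#' (conservative).
#'
#' @param observed Scalar observed statistic.
#' @param null_samples Vector of null draws (the observed draw excluded).
#' @param tail `"ge"`, `"le"` or `"two"` (two-sided on absolute values).
#' @return p-value in (0, 1].
#' @examples
#' permutation_pvalue(10, c(3, 5, 12, 10), "ge") # 0.6
#' @export
permutation_pvalue <- function(observed, null_samples, tail = c("ge", "le", "two")) {
  tail <- match.arg(tail)
  if (length(null_samples) == 0) {
    stop("`null_samples` must be nonempty", call. = FALSE)
  }
  k <- switch(tail,
    ge = sum(null_samples >= observed),
    le = sum(null_samples <= observed),
    two = sum(abs(null_samples) >= abs(observed))
  )
  (1 + k) / (length(null_samples) + 1)
}

# vectorized over observed values against a common null sample
permutation_pvalues <- function(observed, null_samples, tail = "ge") {
  vapply(observed, permutation_pvalue, numeric(1),
         null_samples = null_samples, tail = tail)
}
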