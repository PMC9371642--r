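#' Canonical edge indexing for a connectome
#'
#' Builds the bijection between node pairs \eqn{(i, j)}, \eqn{i < j}, and
#' linear edge indices \eqn{1, \ldots, E} with \eqn{E = V(V-1)/2}. The
#' enumeration is row-major over the upper triangle:
#' (1,2), (1,3), ..., (1,V), (2,3), ..., (V-1,V). Every other function in the
#' package consumes and emits edge vectors in this order.
#'
#' @param n_nodes Number of nodes \eqn{V} (a single positive integer).
#'
#' @return An object of class `edge_index`: a list with `n_nodes`, `n_edges`,
#'   and integer vectors `i`, `j` giving the endpoints of each linear edge.
#' @examples
#' idx <- edge_index(4)
#' idx$n_edges          # 6
#' edge_pairs(idx)      # tibble of (edge, i, j)
#' @export
edge_index <- function(n_nodes) {
  if (length(n_nodes) != 1L || is.na(n_nodes) || n_nodes < 1 ||
      n_nodes != round(n_nodes)) {
    stop("`n_nodes` must be a single positive integer", call. = FALSE)
  }
  v <- as.integer(n_nodes)
  if (v == 1L) {
    i <- integer(0)
    j <- integer(0)
  } else {
    # row-major over i < j
    i <- rep.int(seq_len(v - 1L), times = (v - 1L):1L)
    j <- unlist(lapply(seq_len(v - 1L), function(a) (a + 1L):v), use.names = FALSE)
  }
  structure(
    list(n_nodes = v, n_edges = as.integer(v * (v - 1L) / 2L),
         i = i, j = as.integer(j)),
    class = "edge_index"
  )
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("<edge_index: %d nodes, %d edges>\n", x$n_nodes, x$n_edges))
  invisible(x)
}

#' @rdname edge_index
#' @param index An `edge_index` object.
#' @export
edge_pairs <- function(index) {
  stopifnot(inherits(index, "edge_index"))
  tibble::tibble(edge = seq_len(index$n_edges), i = index$i, j = index$j)
}

#' Linear index of a node pair
#'
#' @param index An `edge_index`.
#' @param i,j Node indices (1-based); order does not matter, `i != j`.
#' @return Integer linear edge indices.
#' @export
pair_to_edge <- function(index, i, j) {
  stopifnot(inherits(index, "edge_index"))
  a <- pmin(i, j)
  b <- pmax(i, j)
  if (any(a == b) || any(a < 1) || any(b > index$n_nodes)) {
    stop("node pairs must satisfy 1 <= i != j <= V", call. = FALSE)
  }
  v <- index$n_nodes
  # edges before row a: sum_{r<a} (V - r); offset within row: b - a
  as.integer((a - 1L) * v - a * (a - 1L) / 2L + (b - a))
}

#' Extract the upper triangle of a symmetric matrix as an edge vector
#'
#' @param matrix A symmetric numeric `V x V` matrix. The diagonal is ignored
#'   (self-connections are undefined for correlation connectomes).
#' @param index An `edge_index` with matching `n_nodes`.
#' @param tol Symmetry tolerance; entries `|m - t(m)|` beyond it are an error.
#' @return Numeric vector of length `index$n_edges` in canonical edge order.
#' @export
vectorize_upper <- function(matrix, index, tol = 1e-8) {
  stopifnot(inherits(index, "edge_index"))
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix)) {
    stop("`matrix` must be square", call. = FALSE)
  }
  if (nrow(matrix) != index$n_nodes) {
    stop(sprintf("matrix is %d x %d but index has %d nodes",
                 nrow(matrix), ncol(matrix), index$n_nodes), call. = FALSE)
  }
  if (max(abs(matrix - t(matrix)), 0) > tol) {
    stop("matrix is not symmetric within tolerance", call. = FALSE)
  }
  # m[lower.tri(m)] walks the lower triangle column-major, which is exactly
  # the row-major upper triangle of a symmetric matrix
  unname(matrix[lower.tri(matrix)])
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_upper()]; the diagonal is filled with `diag_value`.
#'
#' @param values Numeric vector of length `index$n_edges`.
#' @param index An `edge_index`.
#' @param diag_value Value for the (undefined) diagonal, default 0.
#' @return A symmetric `V x V` numeric matrix.
#' @export
devectorize <- function(values, index, diag_value = 0) {
  stopifnot(inherits(index, "edge_index"))
  if (length(values) != index$n_edges) {
    stop("`values` length does not match index$n_edges", call. = FALSE)
  }
  v <- index$n_nodes
  m <- matrix(diag_value, v, v)
  m[lower.tri(m)] <- values
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Node partition into communities
#'
#' @param community Vector of community labels, one per node (integer,
#'   character or factor), in node order 1..V.
#' @return An object of class `node_partition`: list with `node_community`
#'   (factor of length V), `communities` (levels), `n_communities`.
#' @examples
#' node_partition(c("A", "A", "B", "B"))
#' @export
node_partition <- function(community) {
  if (length(community) < 1L || anyNA(community)) {
    stop("every node needs a community label", call. = FALSE)
  }
  f <- factor(community)
  structure(
    list(node_community = f,
         communities = levels(f),
         n_communities = nlevels(f)),
    class = "node_partition"
  )
}

#' @export
print.node_partition <- function(x, ...) {
  cat(sprintf("<node_partition: %d nodes, %d communities>\n",
              length(x$node_community), x$n_communities))
  invisible(x)
}

#' Map every edge to its network pair
#'
#' A network pair is an unordered pair of communities; with K communities
#' there are K(K+1)/2 possible pairs (within-community pairs (k,k) included).
#'
#' @param partition A `node_partition` covering all nodes of `index`.
#' @param index An `edge_index`.
#' @return A list of class `network_pair_map`: `pair_of_edge` (integer pair id
#'   per edge), `pairs` (tibble: pair, community_a, community_b, within,
#'   n_edges over non-empty pairs only), `n_pairs` (non-empty pair count),
#'   `n_possible_pairs` = K(K+1)/2.
#' @export
assign_network_pairs <- function(partition, index) {
  stopifnot(inherits(partition, "node_partition"), inherits(index, "edge_index"))
  if (length(partition$node_community) != index$n_nodes) {
    stop("partition labels do not cover all nodes of the index", call. = FALSE)
  }
  k <- partition$n_communities
  ci <- as.integer(partition$node_community)[index$i]
  cj <- as.integer(partition$node_community)[index$j]
  a <- pmin(ci, cj)
  b <- pmax(ci, cj)
  # canonical id over unordered community pairs, row-major like edges but
  # including (k, k)
  raw <- (a - 1L) * (2L * k - a + 2L) / 2L + (b - a + 1L)
  used <- sort(unique(raw))
  pair_of_edge <- match(raw, used)
  ka <- kb <- integer(length(used))
  for (u in seq_along(used)) {
    e1 <- which(raw == used[u])[1L]
    ka[u] <- a[e1]; kb[u] <- b[e1]
  }
  pairs <- tibble::tibble(
    pair = seq_along(used),
    community_a = partition$communities[ka],
    community_b = partition$communities[kb],
    within = ka == kb,
    n_edges = as.integer(tabulate(pair_of_edge, length(used)))
  )
  structure(
    list(pair_of_edge = as.integer(pair_of_edge), pairs = pairs,
         n_pairs = length(used),
         n_possible_pairs = as.integer(k * (k + 1L) / 2L)),
    class = "network_pair_map"
  )
}

#' @export
print.network_pair_map <- function(x, ...) {
  cat(sprintf("<network_pair_map: %d non-empty of %d possible network pairs>\n",
              x$n_pairs, x$n_possible_pairs))
  invisible(x)
}

#' Paired task/rest sample of connectomes
#'
#' @param condition_a,condition_b Numeric `n_subjects x n_edges` matrices
#'   (rows = subjects) of vectorized connectomes, e.g. task and rest.
#' @param index The shared `edge_index`.
#' @param condition_b2 Optional second null-run matrix (same shape as
#'   `condition_b`), required to build fake task contrasts.
#' @return Object of class `paired_sample`.
#' @export
paired_sample <- function(condition_a, condition_b, index, condition_b2 = NULL) {
  stopifnot(inherits(index, "edge_index"))
  if (!is.matrix(condition_a) || !is.matrix(condition_b) ||
      !all(dim(condition_a) == dim(condition_b))) {
    stop("conditions must be matrices of identical dimension", call. = FALSE)
  }
  if (ncol(condition_a) != index$n_edges) {
    stop("condition columns must equal index$n_edges", call. = FALSE)
  }
  if (!is.null(condition_b2) && !all(dim(condition_b2) == dim(condition_b))) {
    stop("`condition_b2` must match the other conditions' dimensions", call. = FALSE)
  }
  structure(
    list(condition_a = condition_a, condition_b = condition_b,
         condition_b2 = condition_b2, index = index,
         n_subjects = nrow(condition_a)),
    class = "paired_sample"
  )
}

#' @export
print.paired_sample <- function(x, ...) {
  cat(sprintf("<paired_sample: %d subjects, %d edges%s>\n", x$n_subjects,
              x$index$n_edges,
              if (!is.null(x$condition_b2)) ", second null run present" else ""))
  invisible(x)
}
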