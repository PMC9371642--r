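# Independent brute-force oracles used across tests.

# connected components of an edge set by repeated flood fill over nodes
oracle_components <- function(edge_ids, index) {
  if (length(edge_ids) == 0L) return(list())
  ei <- index$i[edge_ids]
  ej <- index$j[edge_ids]
  comp <- integer(length(edge_ids))
  next_label <- 0L
  for (k in seq_along(edge_ids)) {
    if (comp[k] > 0L) next
    next_label <- next_label + 1L
    nodes <- c(ei[k], ej[k])
    comp[k] <- next_label
    repeat {
      touch <- comp == 0L & (ei %in% nodes | ej %in% nodes)
      if (!any(touch)) break
      comp[touch] <- next_label
      nodes <- union(nodes, c(ei[touch], ej[touch]))
    }
  }
  split(edge_ids, comp)
}

# stepwise TFCE by explicit per-height component labelling
oracle_tfce <- function(tv, index, e_exp, h_exp, n_steps) {
  sc <- numeric(length(tv))
  hmax <- max(tv, 0)
  if (hmax <= 0) return(sc)
  dh <- hmax / n_steps
  for (k in seq_len(n_steps)) {
    h <- k * dh
    for (comp in oracle_components(which(tv >= h), index)) {
      sc[comp] <- sc[comp] + length(comp)^e_exp * h^h_exp * dh
    }
  }
  sc
}

# all 2^n sign assignments (columns) for exhaustive permutation nulls
all_sign_flips <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  dimnames(g) <- NULL
  t(g)
}

# a tiny paired population with a known block effect map
tiny_population <- function(v = 16L, k = 2L, n = 40L, seed = 5L,
                            rho = 0, null_effects = FALSE) {
  idx <- edge_index(v)
  part <- node_partition(rep(seq_len(k), each = v / k))
  delta <- if (null_effects) {
    structure(numeric(idx$n_edges), index = idx)
  } else {
    make_effect_map(idx, part, block = NULL, seed = seed)
  }
  spec <- generator_spec(idx, part, delta, n_subjects = n, rho = rho,
                         seed = seed)
  list(spec = spec, population = simulate_population(spec),
       index = idx, partition = part, delta = delta)
}
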