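#' Read a connectome from a text file
#'
#' Two formats: a full symmetric `V x V` matrix (whitespace- or
#' comma-delimited), or an edge-vector table with two columns (1-based
#' canonical linear edge index, value; header optional).
#'
#' @param path File path.
#' @param format `"auto"` (matrix when the file is square), `"matrix"` or
#'   `"edge_vector"`.
#' @param index Optional `edge_index` to validate an edge-vector file
#'   against; inferred from the matrix dimension otherwise.
#' @return Numeric edge vector in canonical order with the `edge_index`
#'   attached as attribute `index`.
#' @export
read_connectome <- function(path, format = c("auto", "matrix", "edge_vector"),
                            index = NULL) {
  format <- match.arg(format)
  tab <- read_delim_auto(path)
  if (format == "auto") {
    format <- if (nrow(tab) == ncol(tab) && ncol(tab) > 2L) "matrix"
      else "edge_vector"
  }
  if (format == "matrix") {
    m <- as.matrix(tab)
    if (!is.numeric(m)) {
      bad <- which(!vapply(tab, is.numeric, logical(1)))[1L]
      stop(sprintf("%s: column %d is not numeric", path, bad), call. = FALSE)
    }
    if (nrow(m) != ncol(m)) {
      stop(sprintf("%s: matrix is %d x %d, not square", path, nrow(m),
                   ncol(m)), call. = FALSE)
    }
    idx <- index %||% edge_index(nrow(m))
    if (idx$n_nodes != nrow(m)) {
      stop(sprintf("%s: matrix has %d nodes but index expects %d", path,
                   nrow(m), idx$n_nodes), call. = FALSE)
    }
    dimnames(m) <- NULL
    v <- vectorize_upper(m, idx)
  } else {
    if (ncol(tab) != 2L) {
      stop(sprintf("%s: edge-vector files need exactly 2 columns, found %d",
                   path, ncol(tab)), call. = FALSE)
    }
    lin <- tab[[1L]]
    val <- tab[[2L]]
    if (!is.numeric(lin) || !is.numeric(val)) {
      stop(sprintf("%s: non-numeric entries in edge-vector file", path),
           call. = FALSE)
    }
    idx <- index %||% edge_index_from_edges(length(val))
    if (length(val) != idx$n_edges ||
        !identical(sort(as.integer(lin)), seq_len(idx$n_edges))) {
      stop(sprintf("%s: expected the complete 1..%d linear edge indices",
                   path, idx$n_edges), call. = FALSE)
    }
    v <- numeric(idx$n_edges)
    v[as.integer(lin)] <- val
  }
  attr(v, "index") <- idx
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# V from E = V(V-1)/2, erroring when E is not triangular
edge_index_from_edges <- function(n_edges) {
  v <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(v - round(v)) > 1e-9) {
    stop(sprintf("%d values do not form the upper triangle of any matrix",
                 n_edges), call. = FALSE)
  }
  edge_index(round(v))
}

# whitespace/comma-delimited numeric table, header auto-detected
read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  fields <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1L]]
  # header row iff the leading field is non-numeric (node/edge id columns
  # are numeric in all data rows; label columns may legitimately be text)
  header <- is.na(suppressWarnings(as.numeric(fields[1L])))
  utils::read.table(path, sep = sep, header = header,
                    comment.char = "#", strip.white = TRUE)
}

#' Write a connectome
#'
#' @param values Edge vector (attribute `index` required unless given).
#' @param path Output path.
#' @param format `"matrix"` (full symmetric CSV) or `"edge_vector"`
#'   (two-column CSV with header `edge,value`).
#' @param index The `edge_index`.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(values, path,
                             format = c("matrix", "edge_vector"),
                             index = attr(values, "index")) {
  format <- match.arg(format)
  stopifnot(inherits(index, "edge_index"))
  if (format == "matrix") {
    m <- devectorize(as.numeric(values), index)
    utils::write.table(format(m, digits = 17, trim = TRUE, scientific = NA),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    df <- data.frame(edge = seq_len(index$n_edges),
                     value = format(as.numeric(values), digits = 17,
                                    trim = TRUE, scientific = NA))
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a node partition
#'
#' Two-column text: node id (1-based) and community label (integer or
#' string). Every node 1..V must appear exactly once.
#'
#' @param path File path.
#' @return A [node_partition()].
#' @export
read_partition <- function(path) {
  tab <- read_delim_auto(path)
  if (ncol(tab) != 2L) {
    stop(sprintf("%s: partition files need exactly 2 columns, found %d",
                 path, ncol(tab)), call. = FALSE)
  }
  node <- as.integer(tab[[1L]])
  lab <- as.character(tab[[2L]])
  if (anyNA(node)) stop(path, ": non-integer node ids", call. = FALSE)
  if (anyDuplicated(node)) {
    stop(sprintf("%s: duplicate node id %d", path,
                 node[duplicated(node)][1L]), call. = FALSE)
  }
  if (!setequal(node, seq_len(max(node)))) {
    missing <- setdiff(seq_len(max(node)), node)[1L]
    stop(sprintf("%s: node %d has no community label", path, missing),
         call. = FALSE)
  }
  node_partition(lab[order(node)])
}

#' Write a node partition
#'
#' @param partition A `node_partition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "node_partition"))
  df <- data.frame(node = seq_along(partition$node_community),
                   community = as.character(partition$node_community))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulated population to a directory
#'
#' One two-column edge-vector file per subject and condition
#' (`sub-<s>_<condition>.csv`), the partition, the injected effect map, and
#' a JSON manifest.
#'
#' @param population A [paired_sample()] (attribute `delta` written when
#'   present).
#' @param partition The `node_partition` used to generate it.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, partition, dir) {
  stopifnot(inherits(population, "paired_sample"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- population$index
  conds <- list(task = population$condition_a, rest1 = population$condition_b)
  if (!is.null(population$condition_b2)) {
    conds$rest2 <- population$condition_b2
  }
  for (cn in names(conds)) {
    for (s in seq_len(population$n_subjects)) {
      write_connectome(conds[[cn]][s, ],
                       file.path(dir, sprintf("sub-%04d_%s.csv", s, cn)),
                       "edge_vector", index = idx)
    }
  }
  write_partition(partition, file.path(dir, "partition.tsv"))
  delta <- attr(population, "delta")
  if (!is.null(delta)) {
    write_connectome(delta, file.path(dir, "delta.csv"), "edge_vector",
                     index = idx)
  }
  manifest <- list(n_nodes = idx$n_nodes, n_edges = idx$n_edges,
                   n_subjects = population$n_subjects,
                   conditions = names(conds),
                   package_version = as.character(utils::packageVersion("connbench")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read a population directory written by [write_population()]
#'
#' @param dir Directory path.
#' @return A [paired_sample()] (with attribute `delta` when `delta.csv` is
#'   present) and the partition as attribute `partition`.
#' @export
read_population <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  idx <- edge_index(mf$n_nodes)
  read_cond <- function(cn) {
    do.call(rbind, lapply(seq_len(mf$n_subjects), function(s) {
      as.numeric(read_connectome(
        file.path(dir, sprintf("sub-%04d_%s.csv", s, cn)),
        "edge_vector", index = idx))
    }))
  }
  task <- read_cond("task")
  rest1 <- read_cond("rest1")
  rest2 <- if ("rest2" %in% mf$conditions) read_cond("rest2")
  out <- paired_sample(task, rest1, idx, condition_b2 = rest2)
  dpath <- file.path(dir, "delta.csv")
  if (file.exists(dpath)) {
    attr(out, "delta") <- as.numeric(read_connectome(dpath, "edge_vector",
                                                     index = idx))
  }
  attr(out, "partition") <- read_partition(file.path(dir, "partition.tsv"))
  out
}

#' Write a detection table
#'
#' CSV with columns element, level, sign, p_or_q, n_implicated, plus a
#' companion full implicated-edge vector file (`<path>_edges.csv`, columns
#' edge, implicated with sign -1/0/+1).
#'
#' @param result A `detections` object.
#' @param path Output CSV path for the detection table.
#' @return `path`, invisibly.
#' @export
write_detections <- function(result, path) {
  stopifnot(inherits(result, "detections"))
  det <- result$detections
  df <- data.frame(
    element = as.character(det$element), level = result$level,
    sign = det$sign, p_or_q = format(det$p_or_q, digits = 17, trim = TRUE),
    n_implicated = if ("n_implicated" %in% names(det)) det$n_implicated
      else NA_integer_
  )
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  imp <- integer(result$n_edges)
  imp[result$neg_edges] <- -1L
  imp[result$pos_edges] <- 1L
  if (result$level == "whole_brain" && result$wb_detected) {
    imp[] <- 1L
  }
  edge_path <- sub("(\\.[^.]+)?$", "_edges.csv", path)
  utils::write.table(data.frame(edge = seq_along(imp), implicated = imp),
                     edge_path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON record sufficient to reproduce a run: configuration echo,
#' per-repetition seeds, package version, timestamp, and input file digests.
#'
#' @param path Output JSON path.
#' @param config Configuration list (echoed verbatim).
#' @param input_files Character vector of input paths to digest (md5).
#' @param extra Extra named entries.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, input_files = character(0),
                           extra = list()) {
  cfg <- config
  if (inherits(cfg, "benchmark_config")) {
    cfg <- unclass(cfg)
    cfg$tfce <- unclass(cfg$tfce)
    cfg$rep_seeds <- vapply(seq_len(cfg$repetitions), rep_seed_of,
                            integer(1), base_seed = cfg$seed)
  }
  manifest <- c(list(
    config = cfg,
    package_version = as.character(utils::packageVersion("connbench")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_digests = as.list(tools::md5sum(input_files))
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
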