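# Binary network construction: threshold a fiber-count connectivity matrix
# into the unweighted undirected simple graph the analysis works on, plus
# plain-text readers/writers for matrices and graphs.

check_counts_matrix <- function(counts) {
  if (!is.matrix(counts) || nrow(counts) != ncol(counts)) {
    abort("invalid matrix: connectivity must be a square matrix")
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("invalid matrix: connectivity counts must be non-negative")
  }
  if (!isTRUE(all.equal(counts, t(counts)))) {
    abort("invalid matrix: connectivity must be symmetric")
  }
  invisible(counts)
}

#' Threshold a connectivity matrix into a binary network
#'
#' Applies the global fiber-count threshold `T`: ROI pair \{i, j\} is
#' connected iff its count exceeds `T` (strict by default; thresholding
#' exists to remove weak, noise-level connections).  The diagonal is ignored
#' (no self-loops) and isolated nodes are retained, so the graph always has
#' one node per ROI.
#'
#' @param x A `connectivity_matrix` (from [generate_connectome()] /
#'   [read_connectivity()]) or a plain symmetric non-negative matrix.
#' @param threshold Non-negative threshold `T`, identical across subjects by
#'   design.
#' @param strict If `TRUE` (default), keep counts `> T`; if `FALSE`, `>= T`.
#' @return A simple undirected `igraph` graph with `n_rois` nodes.
#' @export
#' @examples
#' m <- matrix(c(0, 5, 1, 5, 0, 0, 1, 0, 0), 3, 3)
#' igraph::ecount(threshold_connectivity(m, threshold = 2)) # 1
threshold_connectivity <- function(x, threshold, strict = TRUE) {
  counts <- if (inherits(x, "connectivity_matrix")) x$counts else x
  check_counts_matrix(counts)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  A <- if (strict) counts > threshold else counts >= threshold
  diag(A) <- FALSE
  graph_from_adj(A * 1L)
}

#' Write / read a connectivity matrix as plain text
#'
#' Two loss-free on-disk forms: `"matrix"` (a square whitespace-delimited
#' integer matrix, one row per line) and `"edgelist"` (lines `i j count` with
#' 0-based ROI ids, upper triangle only, preceded by a `# n_rois: N` header
#' so isolated ROIs survive the round trip).
#'
#' @param x A `connectivity_matrix` or square matrix (writer).
#' @param path File path.
#' @param format `"matrix"` or `"edgelist"`.
#' @param subject_id,group Metadata restored on read.
#' @return `write_connectivity()` returns `path` invisibly;
#'   `read_connectivity()` returns a `connectivity_matrix`.
#' @export
write_connectivity <- function(x, path, format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  counts <- if (inherits(x, "connectivity_matrix")) x$counts else x
  check_counts_matrix(counts)
  if (format == "matrix") {
    writeLines(apply(counts, 1L, paste, collapse = " "), path)
  } else {
    idx <- which(upper.tri(counts) & counts > 0, arr.ind = TRUE)
    lines <- c(
      sprintf("# n_rois: %d", nrow(counts)),
      sprintf("%d %d %d", idx[, 1L] - 1L, idx[, 2L] - 1L, counts[idx])
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname write_connectivity
#' @export
read_connectivity <- function(path, format = c("matrix", "edgelist"),
                              subject_id = basename(path), group = NA_character_) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "matrix") {
    rows <- lapply(strsplit(trimws(lines), "[ ,\t]+"), as.numeric)
    n <- length(rows)
    if (any(lengths(rows) != n)) {
      abort("parse error: matrix file is not square")
    }
    counts <- do.call(rbind, rows)
  } else {
    n <- NA_integer_
    header <- grepl("^#", lines)
    hn <- regmatches(lines[header], regexpr("[0-9]+", lines[header]))
    if (length(hn)) n <- as.integer(hn[[1L]])
    body <- lines[!header & nzchar(trimws(lines))]
    parts <- strsplit(trimws(body), "[ ,\t]+")
    if (any(lengths(parts) != 3L)) {
      bad <- which(lengths(parts) != 3L)[1L]
      abort(sprintf("parse error at line '%s': expected 'i j count'", body[bad]))
    }
    rec <- matrix(as.numeric(unlist(parts)), ncol = 3L, byrow = TRUE)
    if (is.na(n)) n <- max(rec[, 1:2]) + 1L
    counts <- matrix(0, n, n)
    counts[rec[, 1:2, drop = FALSE] + 1L] <- rec[, 3L]
    counts[rec[, 2:1, drop = FALSE] + 1L] <- rec[, 3L]
  }
  storage.mode(counts) <- "integer"
  new_connectivity_matrix(counts, subject_id, group)
}

#' Write / read a binary network as plain text
#'
#' Edge-list format: one `i j` pair per line (0-based ids, each unordered
#' pair once) after a `# n_nodes: N` header line; adjacency format: `N`
#' lines of `N` space-separated 0/1 entries.  Both round-trip exactly,
#' including isolated nodes.  Readers reject self-loops, duplicate edges and
#' asymmetric adjacency input, naming the offending line.
#'
#' @param g A simple undirected `igraph` graph (writer).
#' @param path File path.
#' @param format `"edgelist"` or `"adjacency"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an `igraph` graph.
#' @export
write_network <- function(g, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  check_simple_graph(g)
  if (format == "edgelist") {
    e <- edge_matrix0(g)
    writeLines(c(
      sprintf("# n_nodes: %d", igraph::vcount(g)),
      sprintf("%d %d", e[, 1L], e[, 2L])
    ), path)
  } else {
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    writeLines(apply(A, 1L, paste, collapse = " "), path)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "edgelist") {
    n <- NA_integer_
    header <- grepl("^#", lines)
    hn <- regmatches(lines[header], regexpr("[0-9]+", lines[header]))
    if (length(hn)) n <- as.integer(hn[[1L]])
    body <- lines[!header & nzchar(trimws(lines))]
    if (length(body) == 0L) {
      if (is.na(n)) abort("parse error: empty edge list with no node-count header")
      return(igraph::make_empty_graph(n, directed = FALSE))
    }
    parts <- strsplit(trimws(body), "[ ,\t]+")
    if (any(lengths(parts) != 2L)) {
      bad <- which(lengths(parts) != 2L)[1L]
      abort(sprintf("parse error at line '%s': expected 'i j'", body[bad]))
    }
    e <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
    loop <- e[, 1L] == e[, 2L]
    if (any(loop)) {
      abort(sprintf("parse error at line '%s': self-loop", body[which(loop)[1L]]))
    }
    key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
    if (anyDuplicated(key)) {
      abort(sprintf("parse error at line '%s': duplicate edge",
                    body[which(duplicated(key))[1L]]))
    }
    if (is.na(n)) n <- max(e) + 1L
    if (max(e) + 1L > n) abort("parse error: node id exceeds declared node count")
    g <- igraph::graph_from_edgelist(e + 1L, directed = FALSE)
    igraph::add_vertices(g, n - igraph::vcount(g))
  } else {
    rows <- lapply(strsplit(trimws(lines), "[ ,\t]+"), as.integer)
    n <- length(rows)
    if (any(lengths(rows) != n)) {
      abort("parse error: adjacency file is not square")
    }
    A <- do.call(rbind, rows)
    if (!all(A %in% c(0L, 1L))) {
      abort("parse error: adjacency entries must be 0/1")
    }
    asym <- which(A != t(A), arr.ind = TRUE)
    if (nrow(asym) > 0L) {
      abort(sprintf("parse error: a[%d,%d] != a[%d,%d] (asymmetric adjacency)",
                    asym[1L, 1L], asym[1L, 2L], asym[1L, 2L], asym[1L, 1L]))
    }
    if (any(diag(A) != 0L)) {
      abort("parse error: self-loop on adjacency diagonal")
    }
    graph_from_adj(A)
  }
}
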