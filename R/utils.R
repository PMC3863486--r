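#' @importFrom rlang .data abort warn
#' @importFrom stats cor runif rnorm rlnorm sd setNames
#' @importFrom utils combn head modifyList
NULL

# Deterministic stream-splitting: derive a per-instance seed from a master
# seed and an index, staying inside the 32-bit integer range set.seed accepts.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647)
  v <- (s * 1103515245 + as.double(index) * 2246822519 + 3266489917) %% 2147483647
  as.integer(v %% 2147483646 + 1)
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

# Simple undirected graph from a 0/1 adjacency matrix, keeping isolated nodes.
graph_from_adj <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
}

# Validate an igraph object as a simple undirected graph.
check_simple_graph <- function(g, arg = "g") {
  if (!igraph::is_igraph(g)) {
    abort(sprintf("`%s` must be an igraph object", arg))
  }
  if (igraph::is_directed(g)) {
    abort(sprintf("`%s` must be undirected", arg))
  }
  if (igraph::any_loop(g) || igraph::any_multiple(g)) {
    abort(sprintf("`%s` must be simple (no self-loops or multi-edges)", arg))
  }
  invisible(g)
}

# 0-based integer edge matrix (m x 2, i < j) of a graph.
edge_matrix0 <- function(g) {
  e <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(e) == 0L) {
    return(matrix(integer(0), ncol = 2L))
  }
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])) - 1L
  storage.mode(e) <- "integer"
  e
}
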