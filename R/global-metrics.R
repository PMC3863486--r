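# Global graph properties: degree distributions and their correlation,
# characteristic path length, average clustering, the model-vs-real
# difference ratios, global efficiency and small-worldness.

#' Degree distribution of a graph
#'
#' @param g A simple undirected `igraph` graph.
#' @return A tibble with `degree` (0..max degree) and `prob`, the fraction of
#'   nodes with that degree; `prob` sums to 1.
#' @export
#' @examples
#' degree_distribution_tbl(igraph::make_full_graph(4))
degree_distribution_tbl <- function(g) {
  check_simple_graph(g)
  deg <- igraph::degree(g)
  kmax <- max(deg)
  p <- tabulate(deg + 1L, nbins = kmax + 1L) / length(deg)
  tibble::tibble(degree = 0:kmax, prob = p)
}

#' Pearson correlation between two graphs' degree distributions
#'
#' Aligns the two P(k) vectors on the union degree range 0..max(kmax),
#' padding with zeros, and returns their Pearson correlation.
#'
#' @param g,h Simple undirected `igraph` graphs.
#' @return A number in \eqn{[-1, 1]}.  Errors if either padded P(k) vector is
#'   constant (zero variance), in which case the correlation is undefined.
#' @export
pearson_degree_correlation <- function(g, h) {
  pg <- degree_distribution_tbl(g)
  ph <- degree_distribution_tbl(h)
  kmax <- max(max(pg$degree), max(ph$degree))
  v1 <- v2 <- numeric(kmax + 1L)
  v1[pg$degree + 1L] <- pg$prob
  v2[ph$degree + 1L] <- ph$prob
  s1 <- sd(v1)
  s2 <- sd(v2)
  if (is.na(s1) || is.na(s2) || s1 == 0 || s2 == 0) {
    abort("degree-distribution correlation undefined: a P(k) vector is constant")
  }
  cor(v1, v2)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all connected node pairs (unordered).
#' Disconnected pairs are excluded from the average; if no pair is connected
#' the result is `NA` with a warning.
#'
#' @param g A simple undirected `igraph` graph.
#' @param scope `"connected_pairs"` (default) averages finite distances over
#'   the whole graph; `"largest_component"` restricts to the largest
#'   connected component first.
#' @return A number >= 1, or `NA` for an edgeless graph.
#' @export
characteristic_path_length <- function(g,
                                       scope = c("connected_pairs",
                                                 "largest_component")) {
  scope <- match.arg(scope)
  check_simple_graph(g)
  if (scope == "largest_component") {
    comp <- igraph::components(g)
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  d <- igraph::distances(g)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (length(d) == 0L) {
    warn("no connected node pair; characteristic path length is undefined")
    return(NA_real_)
  }
  mean(d)
}

#' Average clustering coefficient
#'
#' Per node, \eqn{C_i = 2 E_{neighbor,i} / (k_i (k_i - 1))}, the fraction of
#' realized edges among the node's neighbors; nodes of degree < 2 contribute
#' \eqn{C_i = 0}.  Returns the mean over all nodes.
#'
#' @param g A simple undirected `igraph` graph.
#' @return A number in \eqn{[0, 1]}.
#' @export
average_clustering <- function(g) {
  check_simple_graph(g)
  if (igraph::vcount(g) == 0L) {
    return(0)
  }
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Shortest-path-length difference ratio (percent)
#'
#' \eqn{|Path_{model} - Path_{real}| / Path_{real} \times 100}.
#'
#' @param path_model,path_real Characteristic path lengths; `path_real` must
#'   be positive.
#' @return A non-negative percentage.
#' @export
path_diff <- function(path_model, path_real) {
  if (!is.numeric(path_real) || is.na(path_real) || path_real <= 0) {
    abort("`path_real` must be positive")
  }
  abs(path_model - path_real) / path_real * 100
}

#' Clustering-coefficient difference ratio (percent)
#'
#' \eqn{|C_{model} - C_{real}| / C_{real} \times 100}.
#'
#' @param c_model,c_real Average clustering coefficients; `c_real` must be
#'   positive.
#' @return A non-negative percentage.
#' @export
clust_diff <- function(c_model, c_real) {
  if (!is.numeric(c_real) || is.na(c_real) || c_real <= 0) {
    abort("`c_real` must be positive")
  }
  abs(c_model - c_real) / c_real * 100
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over all ordered node pairs, with
#' disconnected pairs contributing 0 (infinite path length).  1 for a
#' complete graph, 0 for a totally disconnected one.
#'
#' @param g A simple undirected `igraph` graph with at least 2 nodes.
#' @return A number in \eqn{[0, 1]}.
#' @export
global_efficiency <- function(g) {
  check_simple_graph(g)
  n <- igraph::vcount(g)
  if (n < 2L) {
    abort("global efficiency requires at least 2 nodes")
  }
  d <- igraph::distances(g)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  sum(inv) * 2 / (n * (n - 1))
}

#' Small-worldness index
#'
#' \eqn{\sigma = (C / C_{rand}) / (L / L_{rand})} where \eqn{C_{rand}} and
#' \eqn{L_{rand}} are means over `n_random` Erdos-Renyi G(N, m) reference
#' graphs with the same node and edge counts.  \eqn{\sigma > 1} indicates a
#' network more clustered than random at comparable path length, i.e.
#' small-world organization.
#'
#' @param g A simple undirected `igraph` graph.
#' @param n_random Number of random reference graphs (default 20).
#' @param seed RNG seed for the reference ensemble.
#' @return A positive number.
#' @export
small_worldness <- function(g, n_random = 20, seed = 1L) {
  check_simple_graph(g)
  stopifnot(is_count(n_random))
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  cc <- average_clustering(g)
  pl <- characteristic_path_length(g)
  refs <- lapply(seq_len(n_random), function(i) {
    with_seed(derive_seed(seed, i), igraph::sample_gnm(n, m))
  })
  c_rand <- mean(vapply(refs, average_clustering, numeric(1)))
  l_rand <- mean(vapply(refs, characteristic_path_length, numeric(1)))
  if (!is.finite(c_rand) || c_rand == 0 || !is.finite(l_rand) || l_rand == 0) {
    abort("small-worldness undefined: random reference has zero clustering or no paths")
  }
  if (!is.finite(pl)) {
    abort("small-worldness undefined: graph has no connected pair")
  }
  (cc / c_rand) / (pl / l_rand)
}

#' One-row summary of a graph's global properties
#'
#' @param g A simple undirected `igraph` graph.
#' @param n_random,seed Passed to [small_worldness()]; set `n_random = 0` to
#'   skip the small-worldness column.
#' @return A tibble with `n_nodes`, `n_edges`, `density`, `char_path_length`,
#'   `avg_clustering`, `global_efficiency`, and (optionally)
#'   `small_worldness`.
#' @export
global_summary <- function(g, n_random = 20, seed = 1L) {
  check_simple_graph(g)
  n <- igraph::vcount(g)
  out <- tibble::tibble(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    char_path_length = characteristic_path_length(g),
    avg_clustering = average_clustering(g),
    global_efficiency = global_efficiency(g)
  )
  if (n_random > 0) {
    out$small_worldness <- small_worldness(g, n_random = n_random, seed = seed)
  }
  out
}
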