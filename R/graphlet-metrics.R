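# Graphlet counting and the two graphlet-based similarity measures:
# relative graphlet frequency (RGF) distance over the 30 graphlets and
# graphlet degree distribution (GDD) agreement over the 73 orbits.

#' Exact graphlet and orbit counts for a graph
#'
#' Enumerates every connected induced subgraph on 2-5 nodes exactly once and
#' classifies it against the graphlet catalog.  Returns both the per-graphlet
#' occurrence counts and the per-node orbit touch counts in one pass.
#'
#' @param g A simple undirected `igraph` graph.
#' @param catalog A [graphlet_catalog()].
#' @return A list of class `graphlet_signature` with `counts` (numeric vector
#'   over graphlet ids 0-29) and `orbits` (numeric node-by-orbit matrix,
#'   columns `O0`..`O72`; column `O0` equals the degree sequence).
#' @export
graphlet_signature <- function(g, catalog = graphlet_catalog()) {
  check_simple_graph(g)
  n <- igraph::vcount(g)
  adj0 <- lapply(igraph::as_adj_list(g, mode = "all"), function(v) {
    as.integer(v) - 1L
  })
  res <- esu_count_cpp(
    n, adj0,
    catalog$lookup$glid, catalog$lookup$orbtab,
    catalog$n_graphlets, catalog$n_orbits
  )
  names(res$counts) <- paste0("G", seq_len(catalog$n_graphlets) - 1L)
  colnames(res$orbits) <- paste0("O", seq_len(catalog$n_orbits) - 1L)
  structure(res, class = "graphlet_signature")
}

#' Graphlet frequency counts
#'
#' Counts induced occurrences of each 2-5-node graphlet in `g` (each node
#' subset counted once).
#'
#' @inheritParams graphlet_signature
#' @return A tibble with one row per catalog graphlet: `graphlet_id`,
#'   `nodes`, `edges`, `count`.
#' @export
#' @examples
#' g <- igraph::make_ring(5)
#' count_graphlets(g)
count_graphlets <- function(g, catalog = graphlet_catalog()) {
  sig <- graphlet_signature(g, catalog)
  dplyr::mutate(
    dplyr::select(tidy.graphlet_catalog(catalog), -"n_orbits", -"orbit_ids"),
    count = as.numeric(sig$counts)
  )
}

#' Per-node orbit touch counts (graphlet degree vectors)
#'
#' For every node, the number of times it occurs in each of the 73
#' automorphism orbits across all induced graphlet occurrences.  Column `O0`
#' (edge endpoint) equals the node degree.
#'
#' @inheritParams graphlet_signature
#' @return A numeric matrix, nodes by orbits, with columns `O0`..`O72`.
#' @export
orbit_degree_vectors <- function(g, catalog = graphlet_catalog()) {
  graphlet_signature(g, catalog)$orbits
}

# RGF distance from two raw count vectors.
rgf_from_counts <- function(c1, c2, exclude_edge = FALSE) {
  if (sum(c1) == 0 || sum(c2) == 0) {
    abort("RGF distance is undefined for a graph with no graphlet occurrences")
  }
  # Zero counts are replaced by 1 before normalization so that all
  # negative-log frequencies stay finite.
  c1 <- pmax(c1, 1)
  c2 <- pmax(c2, 1)
  f1 <- -log(c1 / sum(c1))
  f2 <- -log(c2 / sum(c2))
  keep <- rep(TRUE, length(c1))
  if (exclude_edge) keep[1L] <- FALSE # drop the 2-node edge graphlet
  sum(abs(f1[keep] - f2[keep]))
}

#' Relative graphlet frequency (RGF) distance between two graphs
#'
#' Compares the relative frequencies of the 30 graphlets on 2-5 nodes:
#' \eqn{D(G,H) = \sum_i |F_i(G) - F_i(H)|} with
#' \eqn{F_i(X) = -\log(N_i(X)/T(X))}, where \eqn{N_i(X)} is the count of
#' graphlet \eqn{i} and \eqn{T(X)} the total count.  Zero counts are replaced
#' by 1 before normalization to keep the logarithm finite.  Smaller distance
#' means more similar graphlet composition; identical composition gives 0.
#'
#' @param g,h Simple undirected `igraph` graphs, each containing at least one
#'   graphlet occurrence (i.e. at least one edge).
#' @param catalog A [graphlet_catalog()].
#' @param exclude_edge If `TRUE`, drop the 2-node edge graphlet and sum over
#'   the 29 graphlets on 3-5 nodes instead of all 30.
#' @return A non-negative number; symmetric in its arguments.
#' @export
rgf_distance <- function(g, h, catalog = graphlet_catalog(),
                         exclude_edge = FALSE) {
  c1 <- graphlet_signature(g, catalog)$counts
  c2 <- graphlet_signature(h, catalog)$counts
  rgf_from_counts(c1, c2, exclude_edge = exclude_edge)
}

# Per-orbit normalized scaled touch-count distribution.  Returns the
# distribution over k = 1..kmax as a named numeric vector, or NULL when no
# node touches the orbit.
orbit_distribution <- function(touches) {
  touches <- touches[touches >= 1]
  if (length(touches) == 0L) {
    return(NULL)
  }
  tab <- table(touches)
  k <- as.numeric(names(tab))
  s <- as.numeric(tab) / k # scale by 1/k to damp heavy tails
  setNames(s / sum(s), names(tab))
}

# GDD agreement from two node-by-orbit matrices.
gdd_from_orbits <- function(m1, m2, mean_type = c("arithmetic", "geometric")) {
  mean_type <- match.arg(mean_type)
  n_orb <- ncol(m1)
  agree <- numeric(n_orb)
  for (j in seq_len(n_orb)) {
    d1 <- orbit_distribution(m1[, j])
    d2 <- orbit_distribution(m2[, j])
    if (is.null(d1) && is.null(d2)) {
      # orbit absent from both graphs: identical (empty) distributions
      agree[j] <- 1
      next
    }
    ks <- union(names(d1), names(d2))
    v1 <- setNames(rep(0, length(ks)), ks)
    v2 <- v1
    v1[names(d1)] <- d1
    v2[names(d2)] <- d2
    agree[j] <- 1 - sqrt(sum((v1 - v2)^2)) / sqrt(2)
  }
  if (mean_type == "arithmetic") mean(agree) else prod(agree)^(1 / n_orb)
}

#' Graphlet degree distribution (GDD) agreement between two graphs
#'
#' For each of the 73 automorphism orbits, builds the distribution of
#' per-node touch counts \eqn{d_X^j(k)} (number of nodes touching orbit
#' \eqn{j} exactly \eqn{k \ge 1} times), scales it by \eqn{1/k}, normalizes
#' it to total 1, and measures the Euclidean distance between the two graphs'
#' normalized distributions, rescaled by \eqn{1/\sqrt 2} to lie in
#' \eqn{[0,1]}.  Orbit agreement is 1 minus that distance; the total
#' agreement is the arithmetic (default) or geometric mean over orbits.
#' Orbits untouched in both graphs agree perfectly (1).  The result lies in
#' \eqn{[0,1]}, with 1 meaning all 73 distributions coincide.
#'
#' @param g,h Simple undirected `igraph` graphs.
#' @param catalog A [graphlet_catalog()].
#' @param mean_type How to average per-orbit agreements.
#' @return A number in \eqn{[0,1]}; symmetric in its arguments.
#' @export
gdd_agreement <- function(g, h, catalog = graphlet_catalog(),
                          mean_type = c("arithmetic", "geometric")) {
  m1 <- graphlet_signature(g, catalog)$orbits
  m2 <- graphlet_signature(h, catalog)$orbits
  gdd_from_orbits(m1, m2, mean_type = mean_type)
}
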