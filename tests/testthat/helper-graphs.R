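# Small graph fixtures, built in code.

k_n <- function(n) igraph::make_full_graph(n)
path_n <- function(n) igraph::make_lattice(n)
cycle_n <- function(n) igraph::make_ring(n)
star_leaves <- function(k) igraph::make_star(k + 1, mode = "undirected")
petersen <- function() igraph::make_graph("Petersen")

# K4 with one pendant node attached to vertex 4
k4_pendant <- function() {
  igraph::add_edges(igraph::add_vertices(igraph::make_full_graph(4), 1), c(4, 5))
}

# a calibration target from raw numbers (degree sequence defaults to a
# near-regular sequence consistent with the edge count)
make_target <- function(n, m, ds = NULL) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (is.null(ds)) {
    ds <- rep((2L * m) %/% n, n)
    r <- (2L * m) %% n
    if (r > 0) ds[seq_len(r)] <- ds[seq_len(r)] + 1L
  }
  structure(
    list(n_nodes = n, n_edges = m, degree_sequence = as.integer(ds)),
    class = "calibration_target"
  )
}

random_gnm <- function(n, m, seed) {
  withr::with_seed(seed, igraph::sample_gnm(n, m))
}
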