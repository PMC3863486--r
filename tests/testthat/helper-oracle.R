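# Brute-force oracle for graphlet counting: enumerate every node subset of
# size 2..5, test connectivity by reachability, identify the matching catalog
# graphlet and a node mapping by exhaustive permutation search (adjacency
# preservation), and accumulate counts and orbit touches.  Deliberately
# independent of the package's ESU + canonical-lookup path.

oracle_perms <- local({
  make_perms <- function(k) {
    m <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    m[apply(m, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  }
  stats::setNames(lapply(2:5, make_perms), 2:5)
})

oracle_signature <- function(g, cat) {
  n <- igraph::vcount(g)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  counts <- numeric(cat$n_graphlets)
  orbits <- matrix(0, n, cat$n_orbits)
  sizes <- vapply(cat$graphlets, function(e) e$nodes, integer(1))
  for (k in 2:min(5, n)) {
    idx <- which(sizes == k)
    subs <- utils::combn(n, k)
    P <- oracle_perms[[as.character(k)]]
    for (ci in seq_len(ncol(subs))) {
      S <- subs[, ci]
      B <- A[S, S]
      reach <- diag(k) + B
      for (t in seq_len(k)) reach <- 1 * ((reach %*% reach) > 0)
      if (any(reach[1, ] == 0)) next
      for (gi in idx) {
        ent <- cat$graphlets[[gi]]
        if (sum(B) / 2 != ent$edges) next
        hit <- NULL
        for (pi in seq_len(nrow(P))) {
          pp <- P[pi, ]
          if (all(B == ent$adj[pp, pp])) {
            hit <- pp
            break
          }
        }
        if (is.null(hit)) next
        counts[gi] <- counts[gi] + 1
        for (q in seq_len(k)) {
          orb <- ent$orbit_ids[ent$orbits[hit[q]] + 1L]
          orbits[S[q], orb + 1L] <- orbits[S[q], orb + 1L] + 1
        }
        break
      }
    }
  }
  list(counts = counts, orbits = orbits)
}

expect_signature_matches_oracle <- function(g, cat) {
  sig <- graphlet_signature(g, cat)
  ora <- oracle_signature(g, cat)
  expect_equal(unname(sig$counts), ora$counts)
  expect_equal(unname(sig$orbits), ora$orbits, ignore_attr = TRUE)
  invisible(list(sig = sig, ora = ora))
}
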