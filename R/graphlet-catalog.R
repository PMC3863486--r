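# Graphlet catalog: the canonical set of connected simple graphs on 2-5 nodes
# together with their automorphism orbits.  The catalog is the shared frame of
# reference for graphlet counting, RGF distance (one constraint per graphlet)
# and GDD agreement (one constraint per orbit).

# Edge-bit ordering for a k-node labelled graph: bit b corresponds to the
# (b+1)-th column of combn(k, 2), i.e. pairs (1,2),(1,3),...,(2,3),...
pair_index <- function(k) combn(k, 2)

mask_to_adj <- function(mask, k) {
  pairs <- pair_index(k)
  A <- matrix(0L, k, k)
  for (b in seq_len(ncol(pairs))) {
    if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) != 0L) {
      i <- pairs[1L, b]
      j <- pairs[2L, b]
      A[i, j] <- A[j, i] <- 1L
    }
  }
  A
}

adj_to_mask <- function(A) {
  k <- nrow(A)
  pairs <- pair_index(k)
  mask <- 0L
  for (b in seq_len(ncol(pairs))) {
    if (A[pairs[1L, b], pairs[2L, b]] != 0L) {
      mask <- bitwOr(mask, bitwShiftL(1L, b - 1L))
    }
  }
  mask
}

adj_is_connected <- function(A) {
  k <- nrow(A)
  seen <- logical(k)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier) > 0L) {
    nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# Canonical relabelling of a small labelled graph (BLISS, via igraph).  Two
# labelled graphs receive the same canonical mask iff they are isomorphic.
canonical_mask <- function(A) {
  g <- graph_from_adj(A)
  lab <- igraph::canonical_permutation(g)$labeling
  B <- matrix(0L, nrow(A), ncol(A))
  B[lab, lab] <- A
  list(mask = adj_to_mask(B), adj = B, labeling = lab)
}

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# Automorphism orbits by brute-force permutation testing (k <= 5, so at most
# 120 permutations).  Returns a per-node orbit label, orbits numbered 0-based
# in order of their smallest member node.
node_orbits <- function(A) {
  k <- nrow(A)
  rep_node <- seq_len(k)
  for (p in all_permutations(k)) {
    P <- as.integer(p)
    if (all(A[P, P] == A)) {
      rep_node <- pmin(rep_node, P)
    }
  }
  # rep_node[i] = smallest automorphism image of i, i.e. the smallest member
  # of i's orbit (exact after one pass: automorphisms form a group, so every
  # orbit member appears among the images of i).
  reps <- sort(unique(rep_node))
  match(rep_node, reps) - 1L
}

#' Enumerate the 2-5-node graphlet catalog from scratch
#'
#' Generates every simple labelled graph on 2, 3, 4 and 5 nodes, keeps the
#' connected ones, deduplicates them by graph isomorphism (canonical forms),
#' and computes the automorphism orbits of each surviving graphlet by testing
#' all node permutations.  The result is the catalog of 30 graphlets carrying
#' 73 orbits that underlies RGF distance and GDD agreement.
#'
#' Catalog order is canonical and documented: graphlets are sorted by node
#' count, then edge count, then canonical adjacency encoding; orbits are
#' numbered globally in catalog order, so orbit 0 is the endpoint of the
#' single 2-node graphlet (an edge) and a node's orbit-0 touch count equals
#' its degree.
#'
#' @return An object of class `graphlet_catalog`: a list with `graphlets`
#'   (per-graphlet records: node count, edge count, adjacency, orbit labels,
#'   global orbit ids), `n_graphlets`, `n_orbits`, and internal lookup tables
#'   used by the counting engine.
#' @seealso [graphlet_catalog()] for the cached accessor used by the other
#'   functions in the package.
#' @export
#' @examples
#' cat30 <- enumerate_graphlet_catalog()
#' cat30$n_graphlets # 30
#' cat30$n_orbits    # 73
enumerate_graphlet_catalog <- function() {
  entries <- list()
  seen <- character(0)
  for (k in 2:5) {
    nbits <- k * (k - 1L) / 2L
    for (mask in seq_len(bitwShiftL(1L, nbits)) - 1L) {
      A <- mask_to_adj(mask, k)
      if (!adj_is_connected(A)) next
      can <- canonical_mask(A)
      key <- paste(k, can$mask)
      if (key %in% seen) next
      seen <- c(seen, key)
      entries[[length(entries) + 1L]] <- list(
        nodes = k,
        edges = sum(A) / 2L,
        mask = can$mask,
        adj = can$adj
      )
    }
  }
  ord <- order(
    vapply(entries, `[[`, integer(1), "nodes"),
    vapply(entries, function(e) as.integer(e$edges), integer(1)),
    vapply(entries, `[[`, integer(1), "mask")
  )
  entries <- entries[ord]

  # Orbits, numbered globally in catalog order.
  next_orbit <- 0L
  for (i in seq_along(entries)) {
    orb <- node_orbits(entries[[i]]$adj)
    n_orb <- max(orb) + 1L
    entries[[i]]$orbits <- orb
    entries[[i]]$orbit_ids <- next_orbit + seq_len(n_orb) - 1L
    next_orbit <- next_orbit + n_orb
  }

  catalog <- structure(
    list(
      graphlets = entries,
      n_graphlets = length(entries),
      n_orbits = next_orbit
    ),
    class = "graphlet_catalog"
  )
  catalog$lookup <- build_lookup_tables(catalog)
  catalog
}

# Lookup tables mapping every connected labelled edge-mask on k nodes to its
# catalog graphlet id and, position-wise, to global orbit ids.  These give the
# counting engine O(1) classification of each enumerated induced subgraph.
build_lookup_tables <- function(catalog) {
  by_key <- new.env(parent = emptyenv())
  for (i in seq_along(catalog$graphlets)) {
    e <- catalog$graphlets[[i]]
    assign(paste(e$nodes, e$mask), i, envir = by_key)
  }
  glid <- list()
  orbtab <- list()
  for (k in 2:5) {
    nbits <- k * (k - 1L) / 2L
    nm <- bitwShiftL(1L, nbits)
    gv <- rep(-1L, nm)
    ot <- matrix(-1L, nrow = nm, ncol = k)
    for (mask in seq_len(nm) - 1L) {
      A <- mask_to_adj(mask, k)
      if (!adj_is_connected(A)) next
      can <- canonical_mask(A)
      gid <- get(paste(k, can$mask), envir = by_key)
      entry <- catalog$graphlets[[gid]]
      gv[mask + 1L] <- gid - 1L
      # node at position p maps to canonical node can$labeling[p]
      ot[mask + 1L, ] <- entry$orbit_ids[entry$orbits[can$labeling] + 1L]
    }
    glid[[k - 1L]] <- gv
    orbtab[[k - 1L]] <- ot
  }
  list(glid = glid, orbtab = orbtab)
}

the_catalog_cache <- new.env(parent = emptyenv())

#' The cached 2-5-node graphlet catalog
#'
#' Returns the package-wide graphlet catalog, building it on first use.
#' All counting and comparison functions default to this catalog.
#'
#' @param rebuild If `TRUE`, discard the cache and re-enumerate from scratch.
#' @return A `graphlet_catalog` object; see [enumerate_graphlet_catalog()].
#' @export
graphlet_catalog <- function(rebuild = FALSE) {
  if (rebuild || is.null(the_catalog_cache$catalog)) {
    the_catalog_cache$catalog <- enumerate_graphlet_catalog()
  }
  the_catalog_cache$catalog
}

#' @export
print.graphlet_catalog <- function(x, ...) {
  cat(sprintf(
    "Graphlet catalog: %d graphlets (2-5 nodes), %d automorphism orbits\n",
    x$n_graphlets, x$n_orbits
  ))
  invisible(x)
}

#' Tidy summary of a graphlet catalog
#'
#' @param x A `graphlet_catalog`.
#' @param ... Unused.
#' @return A tibble with one row per graphlet: `graphlet_id` (0-based),
#'   `nodes`, `edges`, `n_orbits`, and the global `orbit_ids` (list-column).
#' @export
tidy.graphlet_catalog <- function(x, ...) {
  tibble::tibble(
    graphlet_id = seq_along(x$graphlets) - 1L,
    nodes = vapply(x$graphlets, `[[`, integer(1), "nodes"),
    edges = vapply(x$graphlets, function(e) as.integer(e$edges), integer(1)),
    n_orbits = vapply(x$graphlets, function(e) length(e$orbit_ids), integer(1)),
    orbit_ids = lapply(x$graphlets, `[[`, "orbit_ids")
  )
}
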