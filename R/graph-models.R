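# The seven theoretical graph models fitted to each brain network: ER, ER-DD,
# GEO, GEO-GD, SF (Barabasi-Albert), SF-GD (duplication-divergence) and
# STICKY.  Every generator is calibrated to an input graph's node count and
# edge count (ER-DD: its full degree sequence).

MODEL_NAMES <- c("ER", "ERDD", "GEO", "GEOGD", "SF", "SFGD", "STICKY")

normalize_model_name <- function(name) {
  nm <- toupper(gsub("[-_ ]", "", name))
  if (!nm %in% MODEL_NAMES) {
    abort(sprintf(
      "unknown model '%s'; must be one of %s",
      name, paste(MODEL_NAMES, collapse = ", ")
    ))
  }
  nm
}

#' Calibration target extracted from a real graph
#'
#' The quantities every model generator matches: node count, edge count, and
#' the degree sequence.
#'
#' @param g A simple undirected `igraph` graph.
#' @return A list of class `calibration_target` with `n_nodes`, `n_edges`,
#'   `degree_sequence`.
#' @export
calibration_target <- function(g) {
  check_simple_graph(g)
  structure(
    list(
      n_nodes = igraph::vcount(g),
      n_edges = igraph::ecount(g),
      degree_sequence = as.integer(igraph::degree(g))
    ),
    class = "calibration_target"
  )
}

as_calibration_target <- function(x) {
  if (inherits(x, "calibration_target")) {
    stopifnot(sum(x$degree_sequence) == 2L * x$n_edges)
    return(x)
  }
  calibration_target(x)
}

#' Model specification
#'
#' @param name One of `"ER"`, `"ER-DD"`, `"GEO"`, `"GEO-GD"`, `"SF"`,
#'   `"SF-GD"`, `"STICKY"` (hyphens optional).
#' @param params Named list of model-specific parameters (e.g. `dim` for GEO,
#'   `epsilon` for GEO-GD, `p_link`/`q_delete` for SF-GD); parameters left
#'   unset use the generator defaults or are calibrated.
#' @param seed Integer master seed; per-instance seeds are derived from it.
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, params = list(), seed = 1L) {
  structure(
    list(name = normalize_model_name(name), params = params,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

#' The seven default model specifications
#'
#' @param seed Master seed shared by all specs (each model still draws an
#'   independent derived stream).
#' @return A named list of seven [model_spec()] objects in the canonical
#'   order ER, ERDD, GEO, GEOGD, SF, SFGD, STICKY.
#' @export
default_model_specs <- function(seed = 1L) {
  specs <- lapply(seq_along(MODEL_NAMES), function(i) {
    model_spec(MODEL_NAMES[i], seed = derive_seed(seed, i))
  })
  setNames(specs, MODEL_NAMES)
}

#' Erdos-Renyi G(N, m) random graph
#'
#' Uniformly random simple graph with exactly the target's node and edge
#' counts.
#'
#' @param target A [calibration_target()] (or a graph, from which one is
#'   taken).
#' @param seed Integer RNG seed.
#' @return A simple undirected `igraph` graph.
#' @export
generate_er <- function(target, seed = 1L) {
  t <- as_calibration_target(target)
  max_m <- t$n_nodes * (t$n_nodes - 1) / 2
  if (t$n_edges > max_m) {
    abort(sprintf("infeasible edge count: %d > %d", t$n_edges, max_m))
  }
  with_seed(seed, igraph::sample_gnm(t$n_nodes, t$n_edges))
}

# Erdos-Gallai graphicality test (even sum assumed checked by caller).
is_graphical_sequence <- function(d) {
  if (any(d < 0) || sum(d) %% 2 != 0) {
    return(FALSE)
  }
  n <- length(d)
  if (any(d > n - 1)) {
    return(FALSE)
  }
  d <- sort(d, decreasing = TRUE)
  csum <- cumsum(d)
  for (k in seq_len(n)) {
    tail_min <- if (k < n) sum(pmin(d[(k + 1):n], k)) else 0
    if (csum[k] > k * (k - 1) + tail_min) {
      return(FALSE)
    }
  }
  TRUE
}

#' Degree-matched random graph (ER-DD, "stubs method")
#'
#' Assigns each node a number of stubs equal to its target degree, joins
#' randomly picked stub pairs into edges, and repairs the self-loops and
#' duplicate edges this produces by random degree-preserving edge swaps, so
#' the returned simple graph realizes the target degree sequence exactly.
#'
#' @inheritParams generate_er
#' @param max_sweeps Repair budget; the generator errors if violations
#'   persist (essentially impossible for graphical sequences of real
#'   networks).
#' @return A simple undirected `igraph` graph whose degree sequence equals
#'   `target$degree_sequence`.
#' @export
generate_erdd <- function(target, seed = 1L, max_sweeps = 200L) {
  t <- as_calibration_target(target)
  d <- t$degree_sequence
  if (!is_graphical_sequence(d)) {
    abort("degree sequence is not graphical")
  }
  n <- t$n_nodes
  if (t$n_edges == 0L) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  with_seed(seed, {
    stubs <- rep.int(seq_len(n), d)
    stubs <- sample(stubs)
    m <- length(stubs) / 2L
    a <- stubs[seq_len(m)]
    b <- stubs[m + seq_len(m)]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    key <- function(i, j) (as.double(pmin(i, j)) - 1) * n + as.double(pmax(i, j))
    for (sweep in seq_len(max_sweeps)) {
      keys <- key(lo, hi)
      bad <- which(lo == hi | duplicated(keys))
      if (length(bad) == 0L) break
      if (sweep == max_sweeps) {
        abort("stub repair failed: could not remove all self-loops/multi-edges")
      }
      have <- new.env(parent = emptyenv(), size = 2L * m)
      for (kk in keys[-bad]) assign(as.character(kk), TRUE, envir = have)
      exists_edge <- function(i, j) {
        !is.null(have[[as.character(key(i, j))]])
      }
      for (e in bad) {
        u <- lo[e]
        v <- hi[e]
        for (try in seq_len(50L)) {
          o <- sample.int(m, 1L)
          if (o == e) next
          x <- lo[o]
          y <- hi[o]
          # swap (u,v),(x,y) -> (u,x),(v,y); valid if simple and new
          if (u != x && v != y && key(u, x) != key(v, y) &&
              !exists_edge(u, x) && !exists_edge(v, y) &&
              !(key(x, y) %in% keys[bad])) {
            rm(list = as.character(key(x, y)), envir = have)
            lo[e] <- min(u, x); hi[e] <- max(u, x)
            lo[o] <- min(v, y); hi[o] <- max(v, y)
            assign(as.character(key(u, x)), TRUE, envir = have)
            assign(as.character(key(v, y)), TRUE, envir = have)
            break
          }
        }
      }
    }
    igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE) |>
      igraph::add_vertices(max(0L, n - max(c(lo, hi))))
  })
}

# Edges of the n_edges nearest point pairs (rank-based cutoff, exact count).
nearest_pair_graph <- function(pts, n_edges) {
  n <- nrow(pts)
  max_m <- n * (n - 1) / 2
  stopifnot(n_edges <= max_m)
  if (n_edges == 0L) {
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  D <- as.matrix(stats::dist(pts))
  ut <- which(upper.tri(D))
  ord <- ut[order(D[ut])][seq_len(n_edges)]
  ij <- arrayInd(ord, dim(D))
  g <- igraph::graph_from_edgelist(ij, directed = FALSE)
  igraph::add_vertices(g, n - igraph::vcount(g))
}

#' Geometric random graph (GEO)
#'
#' Nodes are uniform points in the unit cube; edges join the closest pairs.
#' The distance cutoff is calibrated on the realized point set by taking
#' exactly the `n_edges` nearest pairs (rank-based cutoff), so the edge count
#' matches the target exactly.
#'
#' @inheritParams generate_er
#' @param dim Dimension of the embedding space (default 3).
#' @return A simple undirected `igraph` graph.
#' @export
generate_geo <- function(target, seed = 1L, dim = 3L) {
  t <- as_calibration_target(target)
  stopifnot(t$n_nodes >= 2L)
  with_seed(seed, {
    pts <- matrix(runif(t$n_nodes * dim), ncol = dim)
    nearest_pair_graph(pts, t$n_edges)
  })
}

#' Geometric gene-duplication model (GEO-GD)
#'
#' Grows a point cloud by duplication with mutation: starting from a small
#' seed of uniform points, each new node copies a uniformly chosen existing
#' node's location and perturbs it by a uniform offset of magnitude at most
#' `epsilon` per coordinate, wrapped back into the unit cube so the point set
#' stays inside the model's metric space.  After all points are placed, edges
#' join the `n_edges` nearest pairs (same rank-based cutoff as
#' [generate_geo()]).
#'
#' @inheritParams generate_geo
#' @param epsilon Mutation radius; small values produce tight clusters of
#'   duplicated points, while `epsilon >= 1` makes the wrapped offsets
#'   uniform on the cube, recovering the plain geometric model exactly.
#' @param seed_size Number of initial uniform points (default 5, capped at
#'   the node count).
#' @return A simple undirected `igraph` graph.
#' @export
generate_geo_gd <- function(target, seed = 1L, epsilon = 0.15, dim = 3L,
                            seed_size = 5L) {
  t <- as_calibration_target(target)
  stopifnot(t$n_nodes >= 2L, epsilon > 0)
  n0 <- min(as.integer(seed_size), t$n_nodes)
  with_seed(seed, {
    pts <- matrix(NA_real_, nrow = t$n_nodes, ncol = dim)
    pts[seq_len(n0), ] <- runif(n0 * dim)
    if (t$n_nodes > n0) {
      for (i in (n0 + 1L):t$n_nodes) {
        parent <- sample.int(i - 1L, 1L)
        pts[i, ] <- (pts[parent, ] + runif(dim, -epsilon, epsilon)) %% 1
      }
    }
    nearest_pair_graph(pts, t$n_edges)
  })
}

#' Barabasi-Albert scale-free model (SF)
#'
#' Preferential-attachment growth: a seed clique of `m + 1` nodes, then each
#' new node attaches `m` edges to distinct existing nodes chosen with
#' probability proportional to their current degree.  The final edge count is
#' exactly `m0(m0-1)/2 + m (N - m0)`.
#'
#' @inheritParams generate_er
#' @param m Edges added per new node; defaults to `round(n_edges / n_nodes)`
#'   and must be at least 1 (the model cannot match sparser targets).
#' @return A simple undirected `igraph` graph.
#' @export
generate_sf <- function(target, seed = 1L, m = NULL) {
  t <- as_calibration_target(target)
  if (is.null(m)) {
    m <- round(t$n_edges / t$n_nodes)
  }
  if (m < 1) {
    abort("graph too sparse for preferential attachment: m = round(|E|/N) < 1")
  }
  m <- as.integer(m)
  m0 <- m + 1L
  if (t$n_nodes < m0) {
    abort(sprintf("need at least m + 1 = %d nodes", m0))
  }
  with_seed(seed, {
    edges <- combn(m0, 2L)
    deg <- rep.int(m0 - 1L, m0)
    extra <- vector("list", max(0L, t$n_nodes - m0))
    if (t$n_nodes > m0) {
      deg <- c(deg, integer(t$n_nodes - m0))
      for (v in (m0 + 1L):t$n_nodes) {
        targets <- sample.int(v - 1L, m, prob = deg[seq_len(v - 1L)])
        extra[[v - m0]] <- rbind(rep.int(v, m), targets)
        deg[targets] <- deg[targets] + 1L
        deg[v] <- m
      }
    }
    el <- t(cbind(edges, do.call(cbind, extra)))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::add_vertices(g, t$n_nodes - igraph::vcount(g))
  })
}

# Duplication-divergence growth from a connected 2-node seed.
sfgd_grow <- function(n, p_link, q_delete, seed) {
  with_seed(seed, {
    adj <- vector("list", n)
    adj[[1L]] <- 2L
    adj[[2L]] <- 1L
    if (n > 2L) {
      for (v in 3L:n) {
        u <- sample.int(v - 1L, 1L)
        nb <- adj[[u]]
        adj[[v]] <- nb
        for (w in nb) adj[[w]] <- c(adj[[w]], v)
        if (runif(1) < p_link) {
          adj[[u]] <- c(adj[[u]], v)
          adj[[v]] <- c(adj[[v]], u)
        }
        if (q_delete > 0 && length(nb) > 0L) {
          for (w in nb) {
            if (runif(1) < q_delete) {
              # drop one of the two redundant edges {u,w}, {v,w}
              drop_u <- runif(1) < 0.5
              a <- if (drop_u) u else v
              adj[[a]] <- adj[[a]][adj[[a]] != w]
              adj[[w]] <- adj[[w]][adj[[w]] != a]
            }
          }
        }
      }
    }
    el <- do.call(rbind, lapply(seq_len(n), function(i) {
      js <- adj[[i]][adj[[i]] > i]
      if (length(js)) cbind(i, js) else NULL
    }))
    if (is.null(el)) {
      igraph::make_empty_graph(n, directed = FALSE)
    } else {
      igraph::add_vertices(
        igraph::graph_from_edgelist(el, directed = FALSE),
        n - max(el)
      )
    }
  })
}

# Calibrate q_delete (p_link fixed) so the mean SF-GD edge count matches the
# target within `tol`.  The population mean decreases monotonically in
# q_delete but single-instance edge counts have a relative sd around 1/3, so
# the search brackets the target on a coarse grid and then bisects on
# replicate means, stopping at the first estimate inside the tolerance.
calibrate_sfgd <- function(n, m_target, p_link = 0.3, seed = 1L,
                           n_rep = 20L, tol = 0.05, max_iter = 30L) {
  mean_edges <- function(q, salt, reps) {
    mean(vapply(seq_len(reps), function(i) {
      igraph::ecount(sfgd_grow(n, p_link, q, derive_seed(seed, salt * 1000 + i)))
    }, numeric(1)))
  }
  grid <- seq(0.05, 0.95, by = 0.15)
  gm <- vapply(seq_along(grid), function(i) mean_edges(grid[i], i, 5L),
               numeric(1))
  best <- list(q_delete = grid[which.min(abs(gm - m_target))],
               p_link = p_link,
               mean_edges = gm[which.min(abs(gm - m_target))])
  above <- which(gm >= m_target)
  below <- which(gm <= m_target)
  lo <- if (length(above)) grid[max(above)] - 0.15 else 0
  hi <- if (length(below)) grid[min(below)] + 0.15 else 1
  lo <- max(lo, 0)
  hi <- min(hi, 1)
  for (it in seq_len(max_iter)) {
    q <- (lo + hi) / 2
    m <- mean_edges(q, 100L + it, n_rep)
    if (abs(m - m_target) < abs(best$mean_edges - m_target)) {
      best <- list(q_delete = q, p_link = p_link, mean_edges = m)
    }
    if (abs(m - m_target) / m_target <= tol) {
      return(best)
    }
    if (m > m_target) lo <- q else hi <- q
  }
  abort(sprintf(
    "SF-GD calibration failed: nearest achievable mean edge count %.1f vs target %d",
    best$mean_edges, m_target
  ))
}

#' Scale-free gene-duplication model (SF-GD)
#'
#' Duplication-divergence growth from a connected 2-node seed: at each step a
#' uniformly chosen node `u` is duplicated into a new node `v` that inherits
#' `u`'s full neighbor set; the edge `{u, v}` is added with probability
#' `p_link`; then, for each common neighbor `w`, one of the redundant edges
#' `{u, w}` / `{v, w}` (chosen uniformly) is deleted with probability
#' `q_delete`.  When `q_delete` is not supplied it is calibrated by bisection
#' so the mean instance edge count matches the target within 5%.
#'
#' @inheritParams generate_er
#' @param p_link Probability of linking the duplicate to its parent.
#' @param q_delete Divergence (edge-loss) probability; `NULL` to calibrate.
#' @return A simple undirected `igraph` graph; calibrated parameters are
#'   attached as attributes `p_link` and `q_delete`.
#' @export
generate_sf_gd <- function(target, seed = 1L, p_link = NULL, q_delete = NULL) {
  t <- as_calibration_target(target)
  stopifnot(t$n_nodes >= 2L)
  if (is.null(p_link)) p_link <- 0.3
  if (is.null(q_delete)) {
    cal <- calibrate_sfgd(t$n_nodes, t$n_edges, p_link = p_link,
                          seed = derive_seed(seed, 999L))
    q_delete <- cal$q_delete
  }
  stopifnot(is_prob(p_link), is_prob(q_delete))
  g <- sfgd_grow(t$n_nodes, p_link, q_delete, seed)
  attr(g, "p_link") <- p_link
  attr(g, "q_delete") <- q_delete
  g
}

#' Stickiness-index model (STICKY)
#'
#' Parameter-free degree-driven random graph: node `i` gets stickiness index
#' \eqn{\theta_i = d_i / \sqrt{\sum_k d_k}} from the target degree sequence,
#' and each pair `{i, j}` is joined independently with probability
#' \eqn{\min(\theta_i \theta_j, 1)}, which reproduces the degree sequence in
#' expectation when no clipping occurs.
#'
#' @inheritParams generate_er
#' @return A simple undirected `igraph` graph; the number of clipped pair
#'   probabilities is attached as attribute `n_clipped`.
#' @export
generate_sticky <- function(target, seed = 1L) {
  t <- as_calibration_target(target)
  d <- t$degree_sequence
  n <- t$n_nodes
  if (sum(d) == 0) {
    warn("all-zero degree sequence: STICKY graph is empty")
    return(igraph::make_empty_graph(n, directed = FALSE))
  }
  theta <- d / sqrt(sum(d))
  P <- outer(theta, theta)
  n_clipped <- sum(P[upper.tri(P)] > 1)
  P <- pmin(P, 1)
  with_seed(seed, {
    ut <- upper.tri(P)
    hit <- ut & matrix(runif(n * n), n, n) < P
    g <- graph_from_adj(hit | t(hit))
    attr(g, "n_clipped") <- n_clipped
    g
  })
}

#' Generate repeated instances of one model calibrated to a real graph
#'
#' Calibrates the named model to `g_real` (node/edge counts; full degree
#' sequence for ER-DD and STICKY; for SF-GD the divergence rate is calibrated
#' once and reused for all instances) and draws `n_instances` independent
#' instances with seeds derived deterministically from `spec$seed`.
#'
#' @param g_real A simple undirected `igraph` graph.
#' @param spec A [model_spec()].
#' @param n_instances Number of instances (default 10).
#' @return A list of `igraph` graphs with attribute `model_spec`.
#' @export
generate_instances <- function(g_real, spec, n_instances = 10L) {
  stopifnot(inherits(spec, "model_spec"), is_count(n_instances))
  target <- calibration_target(g_real)
  p <- spec$params
  if (spec$name == "SFGD" && is.null(p$q_delete)) {
    if (is.null(p$p_link)) p$p_link <- 0.3
    cal <- calibrate_sfgd(target$n_nodes, target$n_edges, p_link = p$p_link,
                          seed = derive_seed(spec$seed, 999L))
    p$q_delete <- cal$q_delete
  }
  gen <- function(seed) {
    switch(spec$name,
      ER = generate_er(target, seed),
      ERDD = generate_erdd(target, seed),
      GEO = do.call(generate_geo, c(list(target, seed), p)),
      GEOGD = do.call(generate_geo_gd, c(list(target, seed), p)),
      SF = do.call(generate_sf, c(list(target, seed), p)),
      SFGD = generate_sf_gd(target, seed, p_link = p$p_link,
                            q_delete = p$q_delete),
      STICKY = generate_sticky(target, seed)
    )
  }
  out <- lapply(seq_len(n_instances), function(i) {
    gen(derive_seed(spec$seed, i))
  })
  attr(out, "model_spec") <- modifyList(spec, list(params = p))
  out
}
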