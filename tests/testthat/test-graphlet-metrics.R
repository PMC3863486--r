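cat30 <- graphlet_catalog()

test_that("counts on hand-enumerable graphs are exact", {
  # triangle: 3 edges, 1 triangle, nothing else
  tri <- count_graphlets(k_n(3), cat30)
  expect_equal(tri$count[tri$graphlet_id == 0], 3)
  expect_equal(tri$count[tri$nodes == 3 & tri$edges == 3], 1)
  expect_equal(sum(tri$count), 4)
  # C5: 5 edges, 5 induced 3-paths, 5 induced 4-paths, 1 five-cycle
  c5 <- count_graphlets(cycle_n(5), cat30)
  nonzero <- c5[c5$count > 0, ]
  expect_equal(nonzero$count, c(5, 5, 5, 1))
  expect_equal(nonzero$nodes, c(2L, 3L, 4L, 5L))
  expect_equal(nonzero$edges, c(1L, 2L, 3L, 5L))
  # edge-graphlet count always equals |E|
  g <- random_gnm(20, 50, 11)
  cg <- count_graphlets(g, cat30)
  expect_equal(cg$count[cg$graphlet_id == 0], igraph::ecount(g))
})

test_that("counts and orbit vectors match the brute-force oracle", {
  expect_signature_matches_oracle(petersen(), cat30)
  withr::with_seed(202, {
    for (i in 1:25) {
      n <- sample(6:12, 1)
      m <- sample(n:round(1.6 * n), 1)
      expect_signature_matches_oracle(igraph::sample_gnm(n, m), cat30)
    }
  })
})

test_that("orbit touches satisfy the count-times-orbit-size identity", {
  for (seed in c(5, 6)) {
    g <- random_gnm(25, 60, seed)
    sig <- graphlet_signature(g, cat30)
    sums <- colSums(sig$orbits)
    for (gi in seq_len(cat30$n_graphlets)) {
      ent <- cat30$graphlets[[gi]]
      for (oi in seq_along(ent$orbit_ids)) {
        orb_size <- sum(ent$orbits == (oi - 1L))
        expect_equal(sums[[ent$orbit_ids[oi] + 1L]],
                     sig$counts[[gi]] * orb_size)
      }
    }
  }
})

test_that("orbit-0 touch vector equals the degree sequence", {
  g <- random_gnm(40, 90, 7)
  sig <- graphlet_signature(g, cat30)
  expect_equal(unname(sig$orbits[, 1L]), unname(igraph::degree(g)))
  # K3: every node has 2 edge-endpoint touches and 1 triangle touch
  s3 <- graphlet_signature(k_n(3), cat30)
  expect_equal(unname(s3$orbits[, 1L]), rep(2, 3))
  expect_equal(unname(s3$orbits[, 4L]), rep(1, 3)) # triangle orbit is O3
})

test_that("star center touches the 3-path middle orbit once per leaf pair", {
  s <- star_leaves(3)
  sig <- graphlet_signature(s, cat30)
  ora <- oracle_signature(s, cat30)
  expect_equal(unname(sig$orbits), ora$orbits, ignore_attr = TRUE)
  # center is vertex 1; middle orbit of the 3-path is O2
  expect_equal(sig$orbits[1, "O2"][[1]], 3)
})

test_that("isomorphic graphs get identical counts and sorted orbit rows", {
  g <- random_gnm(12, 22, 3)
  perm <- withr::with_seed(4, sample(igraph::vcount(g)))
  h <- igraph::permute(g, perm)
  sg <- graphlet_signature(g, cat30)
  sh <- graphlet_signature(h, cat30)
  expect_equal(sg$counts, sh$counts)
  row_order <- function(m) do.call(order, as.data.frame(m))
  expect_equal(sg$orbits[row_order(sg$orbits), ],
               sh$orbits[row_order(sh$orbits), ],
               ignore_attr = TRUE)
})

test_that("RGF distance is zero on identical composition and symmetric", {
  for (seed in c(1, 2, 3)) {
    g <- random_gnm(15, 30, seed)
    expect_equal(rgf_distance(g, g, cat30), 0)
  }
  # isolated nodes carry no graphlets
  k3 <- k_n(3)
  k3_iso <- igraph::add_vertices(k3, 1)
  expect_equal(rgf_distance(k3, k3_iso, cat30), 0)
  g <- random_gnm(15, 30, 4)
  h <- random_gnm(15, 40, 5)
  expect_equal(rgf_distance(g, h, cat30), rgf_distance(h, g, cat30))
  expect_gt(rgf_distance(g, h, cat30), 0)
})

test_that("RGF distance matches direct formula on oracle counts", {
  g <- cycle_n(5)
  h <- k_n(5)
  cg <- pmax(oracle_signature(g, cat30)$counts, 1)
  ch <- pmax(oracle_signature(h, cat30)$counts, 1)
  expected <- sum(abs(-log(cg / sum(cg)) + log(ch / sum(ch))))
  expect_equal(rgf_distance(g, h, cat30), expected)
  # 29-graphlet variant drops the edge term
  expected29 <- expected - abs(-log(cg[1] / sum(cg)) + log(ch[1] / sum(ch)))
  expect_equal(rgf_distance(g, h, cat30, exclude_edge = TRUE), expected29)
})

test_that("RGF distance errors on graphlet-free input", {
  empty <- igraph::make_empty_graph(4, directed = FALSE)
  expect_error(rgf_distance(empty, k_n(3), cat30), "undefined")
})

test_that("GDD agreement is 1 on identity and bounded in [0, 1]", {
  for (seed in c(1, 2)) {
    g <- random_gnm(15, 30, seed)
    expect_equal(gdd_agreement(g, g, cat30), 1)
  }
  withr::with_seed(99, {
    for (i in 1:10) {
      g <- igraph::sample_gnm(12, sample(12:25, 1))
      h <- igraph::sample_gnm(12, sample(12:25, 1))
      a <- gdd_agreement(g, h, cat30)
      expect_gte(a, 0)
      expect_lte(a, 1)
      expect_equal(a, gdd_agreement(h, g, cat30))
    }
  })
})

test_that("GDD agreement matches a step-by-step oracle computation", {
  g <- cycle_n(5)
  h <- star_leaves(4)
  og <- oracle_signature(g, cat30)$orbits
  oh <- oracle_signature(h, cat30)$orbits
  per_orbit <- vapply(seq_len(ncol(og)), function(j) {
    dist_of <- function(m) {
      touch <- m[, j]
      touch <- touch[touch >= 1]
      if (length(touch) == 0) return(NULL)
      tab <- table(touch)
      s <- as.numeric(tab) / as.numeric(names(tab))
      stats::setNames(s / sum(s), names(tab))
    }
    d1 <- dist_of(og)
    d2 <- dist_of(oh)
    if (is.null(d1) && is.null(d2)) return(1)
    ks <- union(names(d1), names(d2))
    v1 <- stats::setNames(rep(0, length(ks)), ks)
    v2 <- v1
    v1[names(d1)] <- d1
    v2[names(d2)] <- d2
    1 - sqrt(sum((v1 - v2)^2) / 2)
  }, numeric(1))
  expect_equal(gdd_agreement(g, h, cat30), mean(per_orbit))
  expect_equal(gdd_agreement(g, h, cat30, mean_type = "geometric"),
               prod(per_orbit)^(1 / length(per_orbit)))
})
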