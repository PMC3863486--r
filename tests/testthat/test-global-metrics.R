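test_that("degree distribution sums to 1 and matches hand counts", {
  d <- degree_distribution_tbl(k_n(4))
  expect_equal(d$prob[d$degree == 3], 1)
  expect_equal(sum(d$prob), 1)
  empty5 <- igraph::make_empty_graph(5, directed = FALSE)
  expect_equal(degree_distribution_tbl(empty5)$prob, 1)
  # C5 plus a disjoint edge: P(1) = 2/7, P(2) = 5/7
  g <- igraph::disjoint_union(cycle_n(5), k_n(2))
  dd <- degree_distribution_tbl(g)
  expect_equal(dd$prob[dd$degree == 1], 2 / 7)
  expect_equal(dd$prob[dd$degree == 2], 5 / 7)
})

test_that("degree-distribution correlation handles identity, padding, errors", {
  g <- random_gnm(30, 80, 1)
  expect_equal(pearson_degree_correlation(g, g), 1)
  # K4 vs empty 4-node graph, aligned over k = 0..3: cor((0,0,0,1),(1,0,0,0))
  expect_equal(
    pearson_degree_correlation(k_n(4), igraph::make_empty_graph(4, directed = FALSE)),
    -1 / 3
  )
  # 1-node graphs have constant P(k): undefined
  one <- igraph::make_empty_graph(1, directed = FALSE)
  expect_error(pearson_degree_correlation(one, one), "constant")
})

test_that("characteristic path length follows the connected-pairs convention", {
  expect_equal(characteristic_path_length(k_n(6)), 1)
  expect_equal(characteristic_path_length(path_n(3)), 4 / 3)
  two_edges <- igraph::disjoint_union(k_n(2), k_n(2))
  expect_equal(characteristic_path_length(two_edges), 1)
  empty <- igraph::make_empty_graph(3, directed = FALSE)
  expect_warning(res <- characteristic_path_length(empty), "undefined")
  expect_true(is.na(res))
})

test_that("average clustering matches hand-enumerated values", {
  expect_equal(average_clustering(k_n(4)), 1)
  expect_equal(average_clustering(star_leaves(3)), 0)
  # K4 + pendant: three untouched K4 nodes C=1, attachment node C=1/2,
  # pendant C=0 -> mean 0.7
  expect_equal(average_clustering(k4_pendant()), 0.7)
})

test_that("difference ratios are percentages anchored at the real value", {
  expect_equal(path_diff(2.5, 2.5), 0)
  expect_equal(path_diff(1.5, 1.0), 50)
  expect_false(isTRUE(all.equal(path_diff(1.5, 1.0), path_diff(1.0, 1.5))))
  expect_equal(clust_diff(0.2, 0.4), 50)
  expect_equal(clust_diff(0, 0.3), 100)
  expect_error(path_diff(1, 0), "positive")
  expect_error(clust_diff(0.1, -1), "positive")
})

test_that("global efficiency matches closed forms and bounds", {
  expect_equal(global_efficiency(k_n(5)), 1)
  expect_equal(global_efficiency(igraph::make_empty_graph(4, directed = FALSE)), 0)
  expect_equal(global_efficiency(path_n(3)), 5 / 6)
  expect_error(global_efficiency(igraph::make_empty_graph(1, directed = FALSE)),
               "at least 2")
})

test_that("efficiency is monotone non-decreasing under edge addition", {
  withr::with_seed(31, {
    g <- igraph::sample_gnm(20, 25)
    eff <- global_efficiency(g)
    for (i in 1:10) {
      missing <- which(!as.matrix(igraph::as_adjacency_matrix(g)) &
                         upper.tri(diag(20)), arr.ind = TRUE)
      pick <- missing[sample(nrow(missing), 1), ]
      g <- igraph::add_edges(g, pick)
      eff2 <- global_efficiency(g)
      expect_gte(eff2, eff)
      eff <- eff2
    }
  })
})

test_that("clustering and efficiency stay within [0, 1] on random graphs", {
  withr::with_seed(77, {
    for (i in 1:15) {
      g <- igraph::sample_gnm(30, sample(20:150, 1))
      expect_gte(average_clustering(g), 0)
      expect_lte(average_clustering(g), 1)
      expect_gte(global_efficiency(g), 0)
      expect_lte(global_efficiency(g), 1)
    }
  })
})

test_that("small-worldness is ~1 for ER graphs and >1 in the WS regime", {
  # self-consistency: an ER graph against its own reference ensemble
  sigmas <- vapply(1:20, function(s) {
    g <- random_gnm(200, 1000, 400 + s)
    small_worldness(g, n_random = 20, seed = 500 + s)
  }, numeric(1))
  expect_gte(mean(sigmas > 0.7 & sigmas < 1.4), 0.95)
  # ring lattice with 5% rewiring (N = 200, k = 10) is small-world
  ws_sigmas <- vapply(1:20, function(s) {
    ws <- withr::with_seed(600 + s, igraph::sample_smallworld(1, 200, 5, 0.05))
    small_worldness(ws, n_random = 10, seed = 700 + s)
  }, numeric(1))
  expect_true(all(ws_sigmas > 1))
})

test_that("complete graph equals its own ER reference exactly", {
  expect_equal(small_worldness(k_n(10), n_random = 3, seed = 1), 1)
})

test_that("global_summary collects all fields", {
  gs <- global_summary(random_gnm(50, 200, 9), n_random = 5, seed = 2)
  expect_named(gs, c("n_nodes", "n_edges", "density", "char_path_length",
                     "avg_clustering", "global_efficiency", "small_worldness"))
  expect_equal(gs$n_nodes, 50)
  expect_equal(gs$n_edges, 200)
})
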