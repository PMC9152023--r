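test_that("thresholding keeps only significant positive correlations", {
  # 5-region mixed fixture checked pair-by-pair against the rule
  r <- matrix(c(1, 0.999, -0.999, 0.2, 0.98,
                0.999, 1, 0.5, -0.8, 0.97,
                -0.999, 0.5, 1, 0.1, 0,
                0.2, -0.8, 0.1, 1, 0.96,
                0.98, 0.97, 0, 0.96, 1), 5, 5,
              dimnames = list(paste0("R", 1:5), paste0("R", 1:5)))
  n <- 4
  t_stat <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  corr <- structure(list(group = "male.naive", n_animals = n, r = r, p = p,
                         region_order = rownames(r),
                         undefined_regions = character(0)),
                    class = "group_correlation_matrix")
  net <- threshold_network(corr, 0.05)
  for (i in 1:5) for (j in 1:5) {
    expected <- i != j && r[i, j] > 0 && p[i, j] < 0.05
    expect_equal(net$adjacency[i, j] == 1, expected)
  }
  # a strong negative correlation is never an edge
  expect_equal(net$adjacency["R1", "R3"], 0, ignore_attr = TRUE)
  expect_error(threshold_network(corr, 0), "p_thresh")
  expect_error(threshold_network(corr, 1), "p_thresh")
})

test_that("degree matches closed forms and sums to twice the edges", {
  expect_equal(unname(net_degree(net_star(4))), c(4, 1, 1, 1, 1))
  expect_equal(unname(net_degree(net_complete(5))), rep(4, 5))
  expect_equal(unname(net_degree(net_path(4))), c(1, 2, 2, 1))
  for (net in list(net_star(6), net_barbell(4), net_random(12, 0.3, 2))) {
    expect_equal(sum(net_degree(net)), 2 * n_edges(net))
  }
})

test_that("betweenness matches the exhaustive path-enumeration oracle", {
  expect_equal(unname(net_betweenness(net_star(4))), c(1, 0, 0, 0, 0))
  b5 <- net_betweenness(net_cycle(5))
  expect_true(all(b5 == b5[1]))

  net <- net_random(8, 0.35, seed = 71)
  raw <- oracle_betweenness(net$adjacency)
  n_act <- sum(rowSums(net$adjacency) > 0)
  expected <- raw / ((n_act - 1) * (n_act - 2) / 2)
  expect_equal(unname(net_betweenness(net)), expected)
})

test_that("transitivity matches brute-force triangle counting", {
  expect_equal(net_transitivity(net_complete(4)), 1)
  expect_equal(net_transitivity(net_star(5)), 0)
  # square plus one diagonal: 2 triangles, 8 connected triples
  sq <- functional_network(adj_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4),
                                                  c(4, 1), c(1, 3))))
  expect_equal(net_transitivity(sq), 0.75)
  expect_equal(net_transitivity(sq), oracle_transitivity(sq$adjacency))
  # no connected triples -> undefined
  pair <- functional_network(adj_from_edges(4, list(c(1, 2), c(3, 4))))
  expect_true(is.na(net_transitivity(pair)))
})

test_that("assortativity matches the edge-list degree-pair correlation", {
  expect_equal(net_assortativity(net_star(5)), -1)
  expect_true(is.na(net_assortativity(net_cycle(6))))  # degree-regular
  net <- net_random(10, 0.35, seed = 72)
  expect_equal(net_assortativity(net), oracle_assortativity(net$adjacency))
})

test_that("characteristic path length averages reachable pairs only", {
  expect_equal(char_path_length(net_complete(6)), 1)
  expect_equal(char_path_length(net_path(3)), 4 / 3)
  two_tri <- functional_network(
    adj_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6))))
  expect_equal(char_path_length(two_tri), 1)
  net <- net_random(9, 0.3, seed = 73)
  expect_equal(char_path_length(net), oracle_cpl(net$adjacency))
})

test_that("small-worldness self-normalizes, detects clique rings, repeats", {
  # an ER draw is its own null: S near 1
  er <- net_random(40, 0.15, seed = 74)
  s_er <- small_worldness(er, n_random = 100, seed = 75)
  expect_gt(s_er, 0.8)
  expect_lt(s_er, 1.25)

  # ring of 10 K6 cliques joined by single bridges: strongly small-world
  k <- 6; n_cliq <- 10
  a <- matrix(0L, k * n_cliq, k * n_cliq)
  for (c_ in 0:(n_cliq - 1)) {
    idx <- (c_ * k + 1):(c_ * k + k)
    a[idx, idx] <- 1L
  }
  diag(a) <- 0L
  for (c_ in 0:(n_cliq - 1)) {
    from <- c_ * k + k
    to <- ((c_ + 1) %% n_cliq) * k + 1
    a[from, to] <- a[to, from] <- 1L
  }
  ring <- functional_network(a)
  expect_gt(small_worldness(ring, n_random = 50, seed = 76), 1)

  # deterministic under a fixed seed
  expect_identical(small_worldness(er, n_random = 20, seed = 77),
                   small_worldness(er, n_random = 20, seed = 77))
})

test_that("graph summaries and exports carry consistent structure", {
  net <- net_random(15, 0.25, seed = 78)
  gs <- graph_summary(net, n_random = 20, seed = 79)
  expect_equal(gs$n_edges, n_edges(net))
  expect_equal(gs$n_active_nodes, length(active_nodes(net)))
  expect_true(gs$transitivity >= 0 && gs$transitivity <= 1)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g_back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g_back), n_edges(net))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network_edgelist(net, tsv)
  el <- read.delim(tsv)
  expect_equal(nrow(el), n_edges(net))
})

test_that("adding an edge never decreases a degree", {
  net <- net_random(10, 0.3, seed = 80)
  adj <- net$adjacency
  off <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
  pick <- off[1, ]
  adj2 <- adj
  adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1L
  net2 <- functional_network(adj2)
  expect_true(all(net_degree(net2) >= net_degree(net)))
  expect_equal(net_transitivity(net_complete(7)), 1)
})
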