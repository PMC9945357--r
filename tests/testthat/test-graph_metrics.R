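test_that("shortest paths use 1/|w| lengths, detours included", {
  W <- matrix(0, 2, 2); W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(shortest_path_lengths(ggm_network(W, c("a", "b")))[1, 2], 2)

  # triangle: direct 1-2 edge is weak (length 10); the detour via 3 is 2+2
  W3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 0.1
  W3[1, 3] <- W3[3, 1] <- 0.5
  W3[3, 2] <- W3[2, 3] <- 0.5
  D <- shortest_path_lengths(ggm_network(W3, c("a", "a", "b")))
  expect_equal(D[1, 2], 4)

  # disconnected components
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- W4[2, 1] <- 0.5; W4[3, 4] <- W4[4, 3] <- 0.5
  D4 <- shortest_path_lengths(ggm_network(W4, c("a", "a", "b", "b")))
  expect_true(is.infinite(D4[1, 3]))
  expect_equal(D4[1, 2], 2)
})

test_that("star-graph centrality matches exhaustive enumeration", {
  W <- matrix(0, 5, 5); W[1, 2:5] <- W[2:5, 1] <- 0.25
  net <- ggm_network(W, c("a", "a", "a", "b", "b"))
  cent <- node_centrality(net)
  expect_equal(cent$strength[1], 1)
  expect_equal(cent$betweenness[1], 6)  # all C(4,2) leaf pairs pass the hub
  expect_equal(cent$betweenness, brute_betweenness(W))
  expect_equal(cent$expected_influence[1], 1)
  expect_equal(cent$closeness[1], 1 / 16)
})

test_that("signed edges split between strength and expected influence", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.3
  W[1, 3] <- W[3, 1] <- -0.3
  cent <- node_centrality(ggm_network(W, c("a", "b", "b")))
  expect_equal(cent$strength[1], 0.6)
  expect_equal(cent$expected_influence[1], 0)
})

test_that("all indices coincide on a fully symmetric network", {
  W <- matrix(0.2, 4, 4); diag(W) <- 0
  cent <- node_centrality(ggm_network(W, c("a", "a", "b", "b")))
  for (ix in c("strength", "closeness", "betweenness", "expected_influence"))
    expect_equal(diff(range(cent[[ix]])), 0)
})

test_that("max-scaling pins the argmax at 1 and warns on all-zero indices", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 0.5
  cent <- node_centrality(ggm_network(W, c("a", "b", "c")))
  scaled <- scale_relative_to_max(cent)
  expect_equal(max(scaled$strength_scaled), 1)
  expect_equal(sort(scaled$strength_scaled), c(1/3, 2/3, 1))
  zero <- cent; zero$betweenness <- c(0, 0, 0)
  expect_warning(z <- scale_relative_to_max(zero), "betweenness")
  expect_equal(z$betweenness_scaled, c(0, 0, 0))
})

test_that("bridge indices: hand case, sign property, single community fatal", {
  # communities {A1, A2}, {B1}; edges A1-A2 (0.5), A2-B1 (0.25)
  W <- matrix(0, 3, 3, dimnames = list(c("A1", "A2", "B1"), c("A1", "A2", "B1")))
  W["A1", "A2"] <- W["A2", "A1"] <- 0.5
  W["A2", "B1"] <- W["B1", "A2"] <- 0.25
  net <- ggm_network(W, c("A", "A", "B"))
  br <- bridge_centrality(net)
  expect_equal(br$bridge_strength, c(0, 0.25, 0.25))
  expect_equal(br$bridge_betweenness, c(0, 1, 0))
  expect_equal(br$bridge_expected_influence, c(0, 0.25, 0.25))

  neg <- ggm_network(-W, c("A", "A", "B"))
  brn <- bridge_centrality(neg)
  expect_equal(brn$bridge_strength, br$bridge_strength)
  expect_equal(brn$bridge_expected_influence, -br$bridge_expected_influence)

  expect_error(bridge_centrality(net, partition = c("A", "A", "A")),
               "single community")
})

test_that("a node with only within-community edges has zero bridge strength", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 0.4   # within community a
  W[2, 3] <- W[3, 2] <- 0.3   # a -> b
  W[3, 4] <- W[4, 3] <- 0.2   # within community b
  br <- bridge_centrality(ggm_network(W, c("a", "a", "b", "b")))
  expect_equal(br$bridge_strength[1], 0)
  expect_equal(br$bridge_expected_influence[1], 0)
})

test_that("betweenness and bridge betweenness match brute-force enumeration", {
  set.seed(99)
  for (rep in 1:30) {
    p <- sample(4:7, 1)
    net <- random_small_network(p)
    part <- net$nodes$community
    cent <- suppressWarnings(node_centrality(net))
    br <- tryCatch(suppressWarnings(bridge_centrality(net)),
                   error = function(e) NULL)
    expect_equal(cent$betweenness, brute_betweenness(net$weights),
                 tolerance = 1e-8)
    D <- shortest_path_lengths(net)
    expect_equal(unname(D), brute_distances(net$weights), tolerance = 1e-10)
    if (!is.null(br))
      expect_equal(br$bridge_betweenness,
                   brute_betweenness(net$weights, part), tolerance = 1e-8)
    # conservation: bridge strength + within-community strength = strength
    within <- vapply(seq_len(p), function(i)
      sum(abs(net$weights[i, part == part[i]])), numeric(1))
    expect_equal(br$bridge_strength + within, cent$strength)
  }
})

test_that("centrality is equivariant under node relabeling", {
  set.seed(4)
  net <- random_small_network(6)
  perm <- sample(6)
  Wp <- net$weights[perm, perm]
  netp <- ggm_network(Wp, net$nodes$community[perm])
  c1 <- suppressWarnings(node_centrality(net))
  c2 <- suppressWarnings(node_centrality(netp))
  for (ix in c("strength", "closeness", "betweenness", "expected_influence"))
    expect_equal(c2[[ix]], c1[[ix]][perm], tolerance = 1e-10)
})

test_that("adding an incident edge never decreases strength", {
  set.seed(6)
  for (rep in 1:10) {
    net <- random_small_network(5)
    W <- net$weights
    absent <- which(W == 0 & upper.tri(W), arr.ind = TRUE)
    if (!nrow(absent)) next
    e <- absent[sample(nrow(absent), 1), ]
    W2 <- W; W2[e[1], e[2]] <- W2[e[2], e[1]] <- runif(1, 0.1, 0.5)
    s1 <- node_centrality(net)$strength
    s2 <- node_centrality(ggm_network(W2, net$nodes$community))$strength
    expect_true(all(s2 - s1 >= 0))
  }
})

test_that("distances agree with igraph's weighted shortest paths", {
  set.seed(13)
  net <- random_small_network(7, edge_prob = 0.6)
  g <- igraph::graph_from_adjacency_matrix(abs(net$weights) > 0,
                                           mode = "undirected")
  idx <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- 1 / abs(net$weights[idx])
  expect_equal(unname(shortest_path_lengths(net)),
               unname(igraph::distances(g)), tolerance = 1e-12)
})
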