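continuous_cfg <- function(...) {
  synthetic_config(likert = c(anxiety = 0, depression = 0, DER = 0), ...)
}

test_that("empty edge probabilities give the identity precision", {
  cfg <- synthetic_config(p_within = 0, p_between = 0, bridge_edges = list(),
                          seed = 1)
  tr <- generate_true_network(cfg)
  expect_equal(tr$precision, diag(20), ignore_attr = TRUE)
  expect_equal(sum(tr$adjacency), 0)
  expect_equal(tr$sigma, diag(20), ignore_attr = TRUE)
})

test_that("ground truth is reproducible and positive definite across seeds", {
  cfg <- synthetic_config(seed = 5)
  expect_identical(generate_true_network(cfg), generate_true_network(cfg))
  for (s in 1:100) {
    tr <- generate_true_network(synthetic_config(seed = s))
    ev <- min(eigen(tr$precision, symmetric = TRUE, only.values = TRUE)$values)
    expect_gte(ev, 0.05)
    expect_true(isSymmetric(tr$adjacency))
    expect_true(all(diag(tr$partials) == 0))
  }
})

test_that("forced bridge edges are present and cross communities", {
  tr <- generate_true_network(synthetic_config(seed = 3))
  for (e in tr$config$bridge_edges) {
    expect_true(tr$adjacency[e[1], e[2]])
    c1 <- tr$nodes$community[match(e[1], tr$nodes$node)]
    c2 <- tr$nodes$community[match(e[2], tr$nodes$node)]
    expect_false(c1 == c2)
  }
  expect_error(
    generate_true_network(
      synthetic_config(bridge_edges = list(c("Tns", "Wrr")), seed = 1)),
    "within a community")
})

test_that("sampled correlations converge to the truth-implied ones", {
  cfg <- continuous_cfg(n = 50000, seed = 2)
  tr <- generate_true_network(cfg)
  sc <- sample_responses(tr)
  expect_lt(max(abs(cor(sc$scores) - tr$sigma)), 0.02)
})

test_that("Likert discretization keeps the sign of non-trivial correlations", {
  cfg <- synthetic_config(n = 50000, seed = 4)
  tr <- generate_true_network(cfg)
  sc <- sample_responses(tr)
  R <- cor(sc$scores)
  big <- which(abs(tr$sigma) > 0.1 & upper.tri(tr$sigma))
  expect_true(all(sign(R[big]) == sign(tr$sigma[big])))
  # HADS-like nodes take the 4 configured levels, DER nodes stay continuous
  hads_cols <- tr$nodes$community %in% c("anxiety", "depression")
  expect_true(all(sc$scores[, hads_cols] %in% 0:3))
})

test_that("a single sampled participant still has valid shape and levels", {
  tr <- generate_true_network(synthetic_config(n = 1, seed = 6))
  sc <- sample_responses(tr)
  expect_equal(dim(sc$scores), c(1, 20))
  expect_true(all(sc$scores[, tr$nodes$community == "anxiety"] %in% 0:3))
})

test_that("recovery metrics: identity, empty estimate, hand-built fractions", {
  tr <- generate_true_network(continuous_cfg(seed = 11))
  self <- ggm_network(tr$partials, tr$nodes$community)
  expect_equal(unlist(recovery_metrics(self, tr)),
               c(sensitivity = 1, specificity = 1, weight_correlation = 1))

  empty <- ggm_network(tr$partials * 0, tr$nodes$community)
  rm0 <- recovery_metrics(empty, tr)
  expect_equal(rm0$sensitivity, 0)
  expect_equal(rm0$specificity, 1)

  # 4-node truth with edges (1,2) and (3,4); estimate finds (1,2), adds a
  # false (1,3), misses (3,4): sensitivity 1/2, specificity 3/4
  small_truth <- list(
    partials = rbind(c(0, .3, 0, 0), c(.3, 0, 0, 0),
                     c(0, 0, 0, .2), c(0, 0, .2, 0)),
    adjacency = rbind(c(F, T, F, F), c(T, F, F, F),
                      c(F, F, F, T), c(F, F, T, F)))
  est <- rbind(c(0, .25, .1, 0), c(.25, 0, 0, 0),
               c(.1, 0, 0, 0), c(0, 0, 0, 0))
  rm1 <- recovery_metrics(est, structure(small_truth, class = "ground_truth"))
  expect_equal(rm1$sensitivity, 0.5)
  expect_equal(rm1$specificity, 0.75)
  expect_equal(rm1$weight_correlation,
               cor(c(.25, .1, 0), c(.3, 0, .2)))

  no_edges <- list(partials = matrix(0, 3, 3),
                   adjacency = matrix(FALSE, 3, 3))
  expect_true(is.na(recovery_metrics(matrix(0, 3, 3),
                                     structure(no_edges, class = "ground_truth"))$sensitivity))
})

test_that("estimated strength ranks track the true network's", {
  cfg <- continuous_cfg(n = 2000, seed = 42)
  tr <- generate_true_network(cfg)
  net <- estimate_network(sample_responses(tr))
  true_net <- ggm_network(tr$partials, tr$nodes$community)
  s_true <- suppressWarnings(node_centrality(true_net))$strength
  s_est <- suppressWarnings(node_centrality(net))$strength
  expect_gte(cor(s_true, s_est, method = "spearman"), 0.8)
})

test_that("forced bridge nodes rank near the top of estimated bridge strength", {
  ranks <- c()
  for (s in 1:20) {
    cfg <- continuous_cfg(n = 2000, seed = s)
    tr <- generate_true_network(cfg)
    net <- estimate_network(sample_responses(tr))
    br <- suppressWarnings(bridge_centrality(net))
    bridge_nodes <- unique(unlist(tr$config$bridge_edges))
    rk <- rank(-br$bridge_strength)[match(bridge_nodes, br$node)]
    ranks <- c(ranks, rk)
  }
  expect_lte(stats::median(ranks), 5)
})

test_that("item-level export round-trips through scoring with coherent structure", {
  cfg <- synthetic_config(n = 300, seed = 10)
  tr <- generate_true_network(cfg)
  path <- file.path(tempdir(), "items.csv")
  write_synthetic_items(tr, path)
  defs <- list(hads_definition(), ders_definition())
  sc <- score_nodes(load_responses(path, defs))
  expect_equal(dim(sc$scores), c(300, 20))
  expect_setequal(colnames(sc$scores), tr$nodes$node)
  # subscale scores built from correlated items must correlate with the
  # generating factor's community partners more than chance
  R <- cor(sc$scores[, tr$nodes$node])
  str_gol <- R["STR", "GOL"]
  expect_true(is.finite(str_gol))
})
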