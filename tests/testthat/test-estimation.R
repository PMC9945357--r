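test_that("pearson_correlation matches the hand formula and flags constants", {
  # 4-participant toy, correlation computed from the raw product-moment sums
  X <- cbind(a = c(1, 2, 4, 7), b = c(3, 1, 5, 6), c = c(2, 2, 1, 9))
  S <- pearson_correlation(X)
  hand_r <- function(x, y) {
    n <- length(x)
    (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  }
  expect_equal(S$S["a", "b"], hand_r(X[, 1], X[, 2]))
  expect_equal(S$S["a", "c"], hand_r(X[, 1], X[, 3]))
  expect_equal(S$S["b", "c"], hand_r(X[, 2], X[, 3]))
  expect_equal(S$n, 4)

  expect_equal(pearson_correlation(cbind(X, d = X[, "a"]))$S["a", "d"], 1)
  expect_error(pearson_correlation(cbind(X, e = rep(2, 4))), "e")
  expect_error(pearson_correlation(X[1:2, ]), "3 observations")

  set.seed(11)
  Z <- matrix(rnorm(20000), ncol = 2)
  expect_lt(abs(pearson_correlation(Z)$S[1, 2]), 0.05)
})

test_that("lambda grid is log-uniform between forced endpoints", {
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(lambda_grid(S, n_lambda = 2, min_ratio = 0.01), c(0.5, 0.005))
  g <- lambda_grid(S, n_lambda = 30)
  expect_true(all(diff(g) < 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 29))
  expect_warning(g0 <- lambda_grid(diag(3)), "zero")
  expect_identical(g0, 0)
})

test_that("graphical lasso limits: unpenalized inverse and full shrinkage", {
  S <- matrix(c(1, .3, .1, .3, 1, .2, .1, .2, 1), 3)
  expect_lt(max(abs(graphical_lasso(S, 0)$K - solve(S))), 1e-6)
  f <- graphical_lasso(S, 0.3)  # lambda >= max |s_ij|
  expect_true(all(f$K[upper.tri(f$K)] == 0))
  expect_equal(diag(f$K), 1 / diag(S))
})

test_that("p = 2 closed form: off-diagonal covariance is soft-thresholded", {
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  f <- graphical_lasso(S, 0.2)
  expect_equal(f$W[1, 2], 0.4, tolerance = 1e-8)  # sign(s12) * (|s12| - lambda)
  expect_lt(max(abs(f$K - solve(matrix(c(1, 0.4, 0.4, 1), 2)))), 1e-6)
  # numerical-optimizer oracle agrees
  expect_lt(max(abs(f$K - ista_glasso(S, 0.2))), 1e-4)
})

test_that("glasso satisfies the KKT conditions of the penalized objective", {
  set.seed(21)
  for (rep in 1:5) {
    p <- sample(3:4, 1)
    X <- matrix(rnorm(60 * p), ncol = p) %*% matrix(rnorm(p * p), p)
    S <- cor(X)
    lam <- runif(1, 0.05, 0.4)
    f <- graphical_lasso(S, lam)
    expect_lt(kkt_violation(f$K, S, lam), 1e-4)
  }
})

test_that("edge count is non-increasing in lambda and partials stay in [-1,1]", {
  set.seed(5)
  X <- MASS::mvrnorm(200, rep(0, 6), 0.5 * diag(6) + 0.5)
  S <- pearson_correlation(X)
  grid <- lambda_grid(S, n_lambda = 40)
  edges <- numeric(40)
  warm <- NULL
  for (i in seq_along(grid)) {
    warm <- graphical_lasso(S, grid[i], warm = warm)
    edges[i] <- sum(warm$K[upper.tri(warm$K)] != 0)
    W <- precision_to_partial(warm$K)
    expect_true(all(abs(W) <= 1 + 1e-12))
  }
  expect_true(all(diff(edges) >= 0))  # grid descends, so edges grow
})

test_that("EBIC formula: BIC limit, per-edge increment, hand evaluation", {
  S <- matrix(c(1, .2, 0, .2, 1, .3, 0, .3, 1), 3)
  n <- 100
  # K with one structural zero; K2 adds that edge
  K <- rbind(c(2, -0.5, 0), c(-0.5, 2, -0.5), c(0, -0.5, 2))
  K2 <- K; K2[1, 3] <- K2[3, 1] <- 0.05
  hand <- function(K, gamma) {
    E <- sum(abs(K[upper.tri(K)]) > 1e-8)
    ll <- (n / 2) * (log(det(K)) - sum(S * K))
    -2 * ll + E * log(n) + 4 * E * gamma * log(3)
  }
  expect_equal(ebic_score(K, S, n, gamma = 0.5), hand(K, 0.5))
  expect_equal(ebic_score(K, S, n, gamma = 0), hand(K, 0))
  # the extra edge contributes exactly log n + 4 gamma log p on top of the
  # likelihood change
  delta_ll <- -2 * (n / 2) * (log(det(K2)) - sum(S * K2)) +
    2 * (n / 2) * (log(det(K)) - sum(S * K))
  expect_equal(ebic_score(K2, S, n, 0.5) - ebic_score(K, S, n, 0.5),
               delta_ll + log(n) + 4 * 0.5 * log(3))
})

test_that("partial correlations match the regression-residual oracle", {
  expect_equal(precision_to_partial(matrix(c(2, -1, -1, 2), 2))[1, 2], 0.5)
  expect_equal(precision_to_partial(diag(c(2, 3, 4))),
               matrix(0, 3, 3))
  set.seed(8)
  X <- MASS::mvrnorm(500, rep(0, 3), matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3))
  S <- cov(X)
  W <- precision_to_partial(solve(S))
  r12.3 <- cor(resid(lm(X[, 1] ~ X[, 3])), resid(lm(X[, 2] ~ X[, 3])))
  expect_equal(W[1, 2], r12.3, tolerance = 1e-10)
})

test_that("EBIC selection: consistency on null and strong-pair data, tie rule", {
  set.seed(31)
  X <- matrix(rnorm(5000 * 20), ncol = 20)
  net0 <- estimate_network(X)
  expect_equal(net0$sparsity, 1)

  Z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, .8, .8, 1), 2))
  net2 <- suppressWarnings(estimate_network(Z))
  expect_equal(sum(net2$weights[upper.tri(net2$weights)] != 0), 1)
  expect_gt(net2$weights[1, 2], 0)

  # exact EBIC tie goes to the larger (sparser) penalty
  path <- data.frame(lambda = c(0.5, 0.3, 0.1), edges = c(1, 2, 3),
                     ebic = c(10, 5, 5))
  expect_equal(bridgenet:::select_ebic(path), 2)
  expect_equal(path$lambda[bridgenet:::select_ebic(path)], 0.3)
})

test_that("network bookkeeping: sparsity matches the weight matrix", {
  set.seed(12)
  cfg <- synthetic_config(n = 400, likert = c(anxiety = 0, depression = 0, DER = 0),
                          seed = 9)
  net <- estimate_network(sample_responses(generate_true_network(cfg)))
  E <- sum(net$weights[upper.tri(net$weights)] != 0)
  expect_equal(net$sparsity, 1 - E / 190)
  expect_true(isSymmetric(net$weights))
  expect_true(all(diag(net$weights) == 0))
})
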