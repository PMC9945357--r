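# Independent oracles used across the suite. These deliberately take naive
# routes (proximal gradient, exhaustive path enumeration, residual
# regressions) so they share no code with the implementations they check.

# proximal-gradient (ISTA) solver for the off-diagonal-penalized Gaussian
# likelihood; slow but independent of the coordinate-descent path
ista_glasso <- function(S, lambda, step = 0.01, iters = 100000, tol = 1e-10) {
  p <- nrow(S)
  K <- diag(p)
  for (i in seq_len(iters)) {
    G <- S - solve(K)
    K1 <- K - step * G
    off <- K1; diag(off) <- 0
    off <- sign(off) * pmax(abs(off) - step * lambda, 0)
    diag(off) <- diag(K1)
    K1 <- (off + t(off)) / 2
    if (min(eigen(K1, symmetric = TRUE, only.values = TRUE)$values) <= 1e-8) {
      step <- step / 2
      next
    }
    if (max(abs(K1 - K)) < tol) return(K1)
    K <- K1
  }
  K
}

# KKT residual of the penalized objective at K (0 at the optimum):
# W = K^-1 must satisfy w_ij = s_ij + lambda*sign(k_ij) on active edges,
# |w_ij - s_ij| <= lambda on zeros, and w_ii = s_ii.
kkt_violation <- function(K, S, lambda, zero_tol = 1e-8) {
  W <- solve(K)
  p <- nrow(K)
  v <- max(abs(diag(W) - diag(S)))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (abs(K[i, j]) > zero_tol) {
      v <- max(v, abs(W[i, j] - S[i, j] - lambda * sign(K[i, j])))
    } else {
      v <- max(v, max(0, abs(W[i, j] - S[i, j]) - lambda))
    }
  }
  v
}

# exhaustive shortest-path enumeration on a small weighted graph
# (lengths 1/|w|); returns per-pair shortest length, count of tied shortest
# paths, and fractional interior-node credits
enumerate_paths <- function(W, tol = 1e-10) {
  p <- nrow(W)
  out <- list()
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      u <- path[length(path)]
      if (u == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (v in which(W[u, ] != 0)) if (!v %in% path) walk(c(path, v))
    }
    walk(s)
    paths
  }
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    paths <- all_paths(s, t)
    if (!length(paths)) {
      out[[paste(s, t)]] <- list(dist = Inf, nshort = 0, credit = numeric(p))
      next
    }
    lens <- vapply(paths, function(pa)
      sum(1 / abs(W[cbind(pa[-length(pa)], pa[-1])])), numeric(1))
    dmin <- min(lens)
    short <- paths[lens <= dmin + tol]
    credit <- numeric(p)
    for (pa in short) {
      interior <- setdiff(pa, c(s, t))
      credit[interior] <- credit[interior] + 1 / length(short)
    }
    out[[paste(s, t)]] <- list(dist = dmin, nshort = length(short),
                               credit = credit)
  }
  out
}

brute_betweenness <- function(W, partition = NULL) {
  p <- nrow(W)
  enum <- enumerate_paths(W)
  bc <- numeric(p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p) {
    if (!is.null(partition) && partition[s] == partition[t]) next
    bc <- bc + enum[[paste(s, t)]]$credit
  }
  bc
}

brute_distances <- function(W) {
  p <- nrow(W)
  enum <- enumerate_paths(W)
  D <- matrix(0, p, p)
  for (s in seq_len(p - 1)) for (t in (s + 1):p)
    D[s, t] <- D[t, s] <- enum[[paste(s, t)]]$dist
  D
}

# random small weighted network for oracle comparisons
random_small_network <- function(p, edge_prob = 0.5, communities = NULL) {
  W <- matrix(0, p, p)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (stats::runif(1) < edge_prob) {
      w <- stats::runif(1, 0.1, 0.9) * sample(c(-1, 1), 1)
      W[i, j] <- W[j, i] <- w
    }
  }
  if (is.null(communities))
    communities <- sample(c("a", "b"), p, replace = TRUE)
  # bridge indices need >= 2 communities present
  if (length(unique(communities)) < 2) communities[1] <- setdiff(c("a", "b"), communities[1])[1]
  colnames(W) <- rownames(W) <- paste0("V", seq_len(p))
  ggm_network(W, communities)
}

# a hand-constructible stability result for CS-rule tests
make_stability_result <- function(grid, cor_matrices,
                                  indices = names(cor_matrices)) {
  structure(list(indices = indices, grid = grid,
                 correlations = cor_matrices,
                 failures = integer(length(grid)),
                 full = NULL, B = nrow(cor_matrices[[1]]), seed = 0L),
            class = "stability_result")
}
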