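#' Correlation matrix of node scores
#'
#' Product-moment correlations by default; a rank-based (Spearman) switch is
#' provided for ordinal node scores.
#'
#' @param scores a `node_score_matrix`, or a plain numeric matrix.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a `correlation_matrix`: list with `S` (p x p), `n`, `ids`,
#'   `method`.
#' @export
pearson_correlation <- function(scores, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(scores, "node_score_matrix")) scores$scores else as.matrix(scores)
  if (nrow(X) < 3) stop("need at least 3 observations")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant node score column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  S <- stats::cor(X, method = method)
  structure(list(S = S, n = nrow(X), ids = colnames(X), method = method),
            class = "correlation_matrix")
}

#' Penalty grid for the graphical lasso path
#'
#' Log-spaced, strictly decreasing grid from the smallest penalty that zeroes
#' every edge (the largest absolute off-diagonal correlation) down to
#' `min_ratio` times that value.
#'
#' @param S a `correlation_matrix` or p x p matrix.
#' @param n_lambda number of grid points (>= 2).
#' @param min_ratio smallest penalty as a fraction of the largest.
#' @return numeric vector of penalties, descending.
#' @export
lambda_grid <- function(S, n_lambda = 100, min_ratio = 0.01) {
  stopifnot(n_lambda >= 2, min_ratio > 0, min_ratio < 1)
  M <- if (inherits(S, "correlation_matrix")) S$S else S
  lambda_max <- max(abs(M[upper.tri(M)]))
  if (lambda_max == 0) {
    warning("all off-diagonal correlations are zero; degenerate grid {0}")
    return(0)
  }
  exp(seq(log(lambda_max), log(min_ratio * lambda_max), length.out = n_lambda))
}

#' Graphical lasso at a single penalty
#'
#' L1-penalized Gaussian maximum likelihood for the precision matrix, with
#' the penalty on off-diagonal entries only, solved by blockwise coordinate
#' descent (compiled). Sweeps stop when the maximum absolute change of the
#' working covariance falls below `tol`.
#'
#' @param S a `correlation_matrix` or p x p covariance/correlation matrix.
#' @param lambda penalty, >= 0 (at 0 the estimate is the inverse of `S`,
#'   which must then be invertible).
#' @param tol convergence tolerance on the working covariance (default 1e-6).
#' @param max_iter maximum number of full sweeps.
#' @param warm optional previous fit (list with `W`, `B`) for path warm
#'   starts.
#' @return a `precision_matrix`: list with `K` (p x p, symmetric positive
#'   definite, exact off-diagonal zeros), `W` (estimated covariance),
#'   `lambda`, `iterations`, `converged`.
#' @export
graphical_lasso <- function(S, lambda, tol = 1e-6, max_iter = 1000,
                            warm = NULL) {
  M <- if (inherits(S, "correlation_matrix")) S$S else as.matrix(S)
  stopifnot(lambda >= 0, nrow(M) == ncol(M))
  W0 <- if (!is.null(warm)) warm$W else NULL
  B0 <- if (!is.null(warm)) warm$B else NULL
  fit <- glasso_cd(M, lambda, tol, as.integer(max_iter), W0, B0)
  if (!fit$converged)
    stop(sprintf("graphical lasso did not converge in %d sweeps (lambda=%.4g, p=%d)",
                 max_iter, lambda, nrow(M)))
  dimnames(fit$K) <- dimnames(M)
  structure(list(K = fit$K, W = fit$W, B = fit$B, lambda = lambda,
                 iterations = fit$iterations, converged = fit$converged),
            class = "precision_matrix")
}

# nonzero off-diagonal count of the upper triangle (edges)
edge_count <- function(K, tol = 1e-8) {
  sum(abs(K[upper.tri(K)]) > tol)
}

#' Extended Bayesian information criterion of a fitted precision matrix
#'
#' EBIC = -2 l(K) + E log n + 4 E gamma log p, with Gaussian log-likelihood
#' l(K) = (n/2)(log det K - tr(S K)) and E the number of nonzero
#' off-diagonal entries in the upper triangle. Lower is better; `gamma = 0`
#' reduces to the ordinary BIC.
#'
#' @param K a `precision_matrix` or p x p positive-definite matrix.
#' @param S the sample correlation/covariance matrix (or
#'   `correlation_matrix`).
#' @param n sample size.
#' @param gamma EBIC hyperparameter, >= 0 (default 0.5).
#' @return scalar EBIC value.
#' @export
ebic_score <- function(K, S, n, gamma = 0.5) {
  Km <- if (inherits(K, "precision_matrix")) K$K else K
  Sm <- if (inherits(S, "correlation_matrix")) S$S else S
  p <- nrow(Km)
  E <- edge_count(Km)
  logdet <- determinant(Km, logarithm = TRUE)
  if (logdet$sign <= 0) stop("precision matrix is not positive definite")
  ll <- (n / 2) * (as.numeric(logdet$modulus) - sum(Sm * Km))
  -2 * ll + E * log(n) + 4 * E * gamma * log(p)
}

#' Partial correlations from a precision matrix
#'
#' w_ij = -k_ij / sqrt(k_ii k_jj), diagonal set to zero; the edge (zero)
#' pattern of the precision matrix carries over exactly.
#'
#' @param K a `precision_matrix` or p x p positive-definite matrix.
#' @return symmetric p x p weight matrix with zero diagonal.
#' @export
precision_to_partial <- function(K) {
  Km <- if (inherits(K, "precision_matrix")) K$K else K
  d <- sqrt(diag(Km))
  W <- -Km / tcrossprod(d)
  diag(W) <- 0
  W
}

# EBIC path selection; exact ties go to the larger (sparser) penalty.
# `path` must be ordered by descending lambda.
select_ebic <- function(path) {
  stopifnot(all(diff(path$lambda) <= 0))
  which.min(path$ebic)
}

#' Estimate a regularized partial-correlation network
#'
#' Fits the graphical lasso over a descending penalty path (warm starts),
#' scores each fit by EBIC, keeps the minimizer (ties broken toward the
#' larger penalty, i.e. the sparser model), and converts the selected
#' precision matrix to partial-correlation edge weights.
#'
#' @param scores a `node_score_matrix`, or a `correlation_matrix` (then `n`
#'   is taken from it), or a plain matrix of scores.
#' @param gamma EBIC hyperparameter (default 0.5).
#' @param n_lambda,min_ratio penalty-path settings, see [lambda_grid()].
#' @param method correlation type passed to [pearson_correlation()].
#' @param communities optional per-node community labels (taken from the
#'   `node_score_matrix` when available).
#' @return a `ggm_network`: list with `nodes` (node, label, community),
#'   `weights` (p x p partial correlations, zero diagonal),
#'   `lambda_selected`, `gamma`, `n`, `path` (lambda, edges, ebic),
#'   `sparsity` (fraction of absent edges).
#' @export
estimate_network <- function(scores, gamma = 0.5, n_lambda = 100,
                             min_ratio = 0.01,
                             method = c("pearson", "spearman"),
                             communities = NULL) {
  method <- match.arg(method)
  if (inherits(scores, "correlation_matrix")) {
    S <- scores
    nodes <- data.frame(node = S$ids, label = S$ids,
                        community = communities %||% rep("all", length(S$ids)),
                        stringsAsFactors = FALSE)
  } else {
    if (inherits(scores, "node_score_matrix")) {
      nodes <- scores$nodes
    } else {
      scores <- as.matrix(scores)
      nodes <- data.frame(node = colnames(scores) %||%
                            paste0("V", seq_len(ncol(scores))),
                          label = NA_character_,
                          community = communities %||% rep("all", ncol(scores)),
                          stringsAsFactors = FALSE)
    }
    S <- pearson_correlation(scores, method = method)
  }
  p <- length(S$ids)
  if (S$n <= p)
    warning(sprintf("n (%d) <= p (%d): estimates may be unstable", S$n, p))

  grid <- lambda_grid(S, n_lambda = n_lambda, min_ratio = min_ratio)
  fits <- vector("list", length(grid))
  path <- data.frame(lambda = grid, edges = NA_integer_, ebic = NA_real_)
  warm <- NULL
  for (i in seq_along(grid)) {
    fit <- graphical_lasso(S, grid[i], warm = warm)
    warm <- fit
    fits[[i]] <- fit
    path$edges[i] <- edge_count(fit$K)
    path$ebic[i] <- ebic_score(fit, S, S$n, gamma = gamma)
  }
  best <- select_ebic(path)
  K <- fits[[best]]$K
  W <- precision_to_partial(K)
  dimnames(W) <- list(S$ids, S$ids)
  E <- edge_count(K)
  structure(list(
    nodes = nodes, weights = W,
    lambda_selected = grid[best], gamma = gamma, n = S$n,
    correlation = S, path = path,
    sparsity = 1 - E / (p * (p - 1) / 2)
  ), class = "ggm_network")
}

#' Wrap an edge-weight matrix as a network object
#'
#' For analysing a network whose weights are already known (e.g. a synthetic
#' ground truth) with the centrality, bridge and layout machinery.
#'
#' @param weights symmetric p x p matrix, zero diagonal.
#' @param communities per-node community labels.
#' @return a `ggm_network` (without estimation metadata).
#' @export
ggm_network <- function(weights, communities) {
  weights <- as.matrix(weights)
  stopifnot(isSymmetric(unname(weights)), all(diag(weights) == 0),
            ncol(weights) == length(communities))
  if (is.null(colnames(weights)))
    dimnames(weights) <- list(paste0("V", seq_len(ncol(weights))),
                              paste0("V", seq_len(ncol(weights))))
  p <- ncol(weights)
  structure(list(
    nodes = data.frame(node = colnames(weights), label = colnames(weights),
                       community = communities, stringsAsFactors = FALSE),
    weights = weights, lambda_selected = NA_real_, gamma = NA_real_,
    n = NA_integer_, correlation = NULL, path = NULL,
    sparsity = 1 - edge_count(weights) / (p * (p - 1) / 2)
  ), class = "ggm_network")
}

#' @export
print.ggm_network <- function(x, ...) {
  p <- nrow(x$nodes)
  E <- edge_count(x$weights)
  cat(sprintf("ggm_network: %d nodes, %d/%d edges (sparsity %.1f%%)\n",
              p, E, p * (p - 1) / 2, 100 * x$sparsity))
  if (!is.na(x$lambda_selected))
    cat(sprintf("  lambda = %.4g (EBIC, gamma = %.2g), n = %d\n",
                x$lambda_selected, x$gamma, x$n))
  invisible(x)
}
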