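#' Deterministic grouped-circle layout
#'
#' Community centers sit equally spaced on a master circle of radius 1
#' (first center at 90 degrees, proceeding counter-clockwise); each
#' community's nodes sit equally spaced on a sub-circle of radius 0.45
#' around their center, starting at the sub-circle's 0-degree point, in the
#' order the nodes are given. No randomness is involved.
#'
#' @param nodes node ids (character) or a `ggm_network`.
#' @param partition per-node community labels.
#' @return a `layout_coordinates` object: data.frame `coords` (node, x, y),
#'   `layout_kind = "circle_grouped"`.
#' @export
circular_group_layout <- function(nodes, partition = NULL) {
  if (inherits(nodes, "ggm_network")) {
    partition <- partition %||% nodes$nodes$community
    nodes <- nodes$nodes$node
  }
  stopifnot(length(nodes) == length(partition))
  comms <- unique(partition)
  K <- length(comms)
  x <- y <- numeric(length(nodes))
  for (k in seq_len(K)) {
    theta <- pi / 2 + 2 * pi * (k - 1) / K
    cx <- cos(theta); cy <- sin(theta)
    members <- which(partition == comms[k])
    m <- length(members)
    for (j in seq_len(m)) {
      phi <- 2 * pi * (j - 1) / m
      x[members[j]] <- cx + 0.45 * cos(phi)
      y[members[j]] <- cy + 0.45 * sin(phi)
    }
  }
  structure(list(
    coords = data.frame(node = nodes, x = x, y = y, stringsAsFactors = FALSE),
    layout_kind = "circle_grouped"
  ), class = "layout_coordinates")
}

# one SMACOF run: alternate monotone (or linear) regression of configuration
# distances on the dissimilarity order with the Guttman transform; the
# tracked criterion sqrt(sigma / m), with disparities normalized to
# sum-of-squares m, is non-increasing across iterations
smacof_engine <- function(delta_vec, X0, type, max_iter, tol) {
  p <- nrow(X0)
  m <- length(delta_vec)
  X <- X0

  disparities <- function(d) {
    if (type == "ordinal") {
      ord <- order(delta_vec, d)       # primary approach to ties
      dhat <- numeric(m)
      dhat[ord] <- stats::isoreg(d[ord])$yf
    } else {
      dhat <- delta_vec * sum(delta_vec * d) / sum(delta_vec^2)
    }
    dhat * sqrt(m / sum(dhat^2))
  }

  d <- as.vector(stats::dist(X))
  if (any(d == 0)) { X <- X + 1e-6 * seq_len(p * 2); d <- as.vector(stats::dist(X)) }
  dhat <- disparities(d)
  trace <- sqrt(sum((dhat - d)^2) / m)
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    # Guttman transform
    Bv <- ifelse(d > 0, -dhat / d, 0)
    B <- matrix(0, p, p)
    B[lower.tri(B)] <- Bv
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    X <- B %*% X / p
    d <- as.vector(stats::dist(X))
    dhat <- disparities(d)
    s <- sqrt(sum((dhat - d)^2) / m)
    trace <- c(trace, s)
    if (trace[it] - s < tol) break
  }
  # Kruskal stress-1 of the final configuration (unnormalized monotone fit)
  if (type == "ordinal") {
    ord <- order(delta_vec, d)
    dh <- numeric(m); dh[ord] <- stats::isoreg(d[ord])$yf
  } else {
    dh <- delta_vec * sum(delta_vec * d) / sum(delta_vec^2)
  }
  stress1 <- sqrt(sum((d - dh)^2) / sum(d^2))
  list(X = X, stress1 = stress1, trace = trace, iterations = it)
}

#' Non-metric MDS layout of a network
#'
#' Places nodes in the plane so that inter-node distance reflects
#' association strength: dissimilarities are max|w| - |w_ij| (pairs with no
#' edge get the maximal dissimilarity), embedded by 2-D ordinal MDS
#' minimizing Kruskal stress-1 via iterative majorization with monotone
#' regression (primary treatment of ties). The best of `n_init` starts is
#' kept: the first start is the classical (Torgerson) solution, the rest are
#' random.
#'
#' @param net a `ggm_network`.
#' @param seed integer seed for the random starts.
#' @param n_init number of starts (>= 1).
#' @param dissimilarity `"weights"` (default: from |edge weight|) or
#'   `"correlations"` (from the zero-order correlation matrix, when the
#'   network carries one).
#' @param type `"ordinal"` (default) or `"metric"`.
#' @param max_iter,tol per-start iteration cap and convergence tolerance on
#'   the stress decrease.
#' @return a `layout_coordinates` object: `coords` (node, x, y, centered at
#'   the origin), `layout_kind = "mds"`, `stress1`, `iterations`, `trace`
#'   (stress values of the winning start), `start_used`, `seed`.
#' @export
mds_layout <- function(net, seed, n_init = 10,
                       dissimilarity = c("weights", "correlations"),
                       type = c("ordinal", "metric"),
                       max_iter = 500, tol = 1e-12) {
  dissimilarity <- match.arg(dissimilarity)
  type <- match.arg(type)
  p <- nrow(net$nodes)
  stopifnot(p >= 3, n_init >= 1)
  A <- switch(dissimilarity,
              weights = abs(net$weights),
              correlations = {
                if (is.null(net$correlation))
                  stop("network carries no correlation matrix")
                abs(net$correlation$S)
              })
  diag(A) <- 0
  amax <- max(A)
  Dm <- amax - A; diag(Dm) <- 0
  if (max(Dm) == 0) {
    # all association magnitudes equal: any spacing is rank-consistent,
    # so fall back to unit dissimilarities (regular-simplex geometry)
    warning("all association magnitudes are equal; using unit dissimilarities")
    Dm <- matrix(1, p, p); diag(Dm) <- 0
  }
  delta_vec <- Dm[lower.tri(Dm)]

  set.seed(as.integer(seed))
  # Torgerson start, padded/jittered if the double-centered matrix is rank-deficient
  Xt <- tryCatch(stats::cmdscale(stats::as.dist(Dm), k = 2), error = function(e) NULL)
  if (is.null(Xt) || ncol(Xt) < 2 || any(!is.finite(Xt))) {
    Xt <- matrix(stats::rnorm(p * 2, sd = 0.1), p, 2)
  } else if (all(Xt[, 2] == 0)) {
    Xt[, 2] <- stats::rnorm(p, sd = 1e-4)
  }
  starts <- c(list(Xt),
              lapply(seq_len(max(0, n_init - 1)),
                     function(i) matrix(stats::rnorm(p * 2), p, 2)))

  best <- NULL; best_idx <- NA_integer_
  for (i in seq_along(starts)) {
    run <- smacof_engine(delta_vec, starts[[i]], type, max_iter, tol)
    if (is.null(best) || run$stress1 < best$stress1 - 1e-15) {
      best <- run; best_idx <- i
    }
  }
  if (any(diff(best$trace) > 1e-8))
    warning("stress increased during majorization; result may be unreliable")

  X <- best$X
  X <- sweep(X, 2, colMeans(X))
  # perturb exact coordinate ties so no two nodes coincide
  key <- paste(round(X[, 1], 12), round(X[, 2], 12))
  dup <- duplicated(key)
  if (any(dup)) X[dup, ] <- X[dup, ] + 1e-8 * seq_len(sum(dup))

  structure(list(
    coords = data.frame(node = net$nodes$node, x = X[, 1], y = X[, 2],
                        stringsAsFactors = FALSE),
    layout_kind = "mds",
    stress1 = best$stress1,
    iterations = best$iterations,
    trace = best$trace,
    start_used = best_idx,
    seed = as.integer(seed),
    dissimilarity = dissimilarity,
    type = type
  ), class = "layout_coordinates")
}
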