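# Weighted shortest-path machinery.
#
# Edges carry length 1/|w| (the convention of the psychometric-network
# tradition: stronger associations are "shorter"). A single Dijkstra pass per
# source also counts shortest paths and keeps predecessor lists, so Brandes'
# accumulation yields betweenness with fractional credit for ties, and a
# community-restricted variant yields bridge betweenness. Ties in path length
# are recognised up to a small absolute tolerance.

.path_tol <- 1e-10

# single-source Dijkstra with path counting on a length matrix (Inf = absent)
sssp <- function(L, s) {
  p <- nrow(L)
  dist <- rep(Inf, p); dist[s] <- 0
  sigma <- rep(0, p); sigma[s] <- 1
  preds <- vector("list", p)
  done <- rep(FALSE, p)
  order_settled <- integer(0)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    order_settled <- c(order_settled, u)
    nb <- which(is.finite(L[u, ]) & !done)
    for (v in nb) {
      alt <- dist[u] + L[u, v]
      if (alt < dist[v] - .path_tol) {
        dist[v] <- alt
        sigma[v] <- sigma[u]
        preds[[v]] <- u
      } else if (abs(alt - dist[v]) <= .path_tol) {
        sigma[v] <- sigma[v] + sigma[u]
        preds[[v]] <- c(preds[[v]], u)
      }
    }
  }
  list(dist = dist, sigma = sigma, preds = preds, order = order_settled)
}

length_matrix <- function(W, edge_tol = 1e-12) {
  L <- 1 / abs(W)
  L[abs(W) <= edge_tol] <- Inf
  diag(L) <- Inf
  L
}

#' All-pairs shortest-path distances of a weighted network
#'
#' Edge lengths are the reciprocal absolute edge weights (1/|w|); pairs with
#' no connecting path are `Inf`.
#'
#' @param net a `ggm_network`.
#' @return symmetric p x p distance matrix with zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  W <- net$weights
  p <- ncol(W)
  L <- length_matrix(W)
  D <- matrix(Inf, p, p, dimnames = dimnames(W))
  for (s in seq_len(p)) D[s, ] <- sssp(L, s)$dist
  D
}

# Brandes accumulation over all sources. `pair_filter(s, t)` says whether the
# (s, t) dependency counts; both orderings of an unordered pair are visited,
# hence the final halving.
brandes_betweenness <- function(L, pair_filter = NULL) {
  p <- nrow(L)
  bc <- numeric(p)
  for (s in seq_len(p)) {
    sp <- sssp(L, s)
    delta <- numeric(p)
    for (w in rev(sp$order)) {
      if (w == s) next
      counts <- if (is.null(pair_filter)) 1 else as.numeric(pair_filter(s, w))
      for (v in sp$preds[[w]])
        delta[v] <- delta[v] + sp$sigma[v] / sp$sigma[w] * (counts + delta[w])
      bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2
}

#' Node centrality indices
#'
#' Strength (sum of absolute incident edge weights), expected influence
#' (signed sum), closeness (reciprocal of the summed shortest-path distance
#' to all reachable peers; 0 for an isolated node), and betweenness (Brandes,
#' fractional credit shared among tied shortest paths).
#'
#' @param net a `ggm_network`.
#' @return a `centrality_table` data.frame: node, community, strength,
#'   closeness, betweenness, expected_influence.
#' @export
node_centrality <- function(net) {
  W <- net$weights
  p <- ncol(W)
  L <- length_matrix(W)
  D <- shortest_path_lengths(net)
  closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]
    reach <- is.finite(d)
    if (!any(reach)) return(0)
    1 / sum(d[reach])
  }, numeric(1))
  if (any(!is.finite(D[upper.tri(D)])))
    warning("network is disconnected; closeness computed over reachable peers only")
  out <- data.frame(
    node = net$nodes$node,
    community = net$nodes$community,
    strength = rowSums(abs(W)),
    closeness = closeness,
    betweenness = brandes_betweenness(L),
    expected_influence = rowSums(W),
    stringsAsFactors = FALSE)
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Scale centrality indices relative to their maximum
#'
#' Each index column is divided by its maximum absolute value across nodes,
#' so the most central node scores 1 (expected influence may reach -1). An
#' all-zero index scales to all zeros with a warning.
#'
#' @param table a `centrality_table` or `bridge_table`.
#' @param cols columns to scale (default: every numeric index column).
#' @return the table with `<index>_scaled` columns appended.
#' @export
scale_relative_to_max <- function(table, cols = NULL) {
  if (is.null(cols))
    cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                    grep("_scaled$", names(table), value = TRUE))
  for (cl in cols) {
    m <- max(abs(table[[cl]]))
    if (m == 0) {
      warning("index '", cl, "' is identically zero; scaled values set to 0")
      table[[paste0(cl, "_scaled")]] <- table[[cl]]
    } else {
      table[[paste0(cl, "_scaled")]] <- table[[cl]] / m
    }
  }
  table
}

#' Bridge centrality indices for a community partition
#'
#' Restricts each centrality notion to a node's connections toward other
#' communities: bridge strength sums absolute cross-community edge weights,
#' bridge expected influence sums them with sign, bridge closeness is the
#' reciprocal summed distance to all nodes of other communities (0, with a
#' warning, if any is unreachable), and bridge betweenness counts (with
#' fractional credit) shortest paths between nodes of two different
#' communities passing through the node.
#'
#' @param net a `ggm_network`.
#' @param partition per-node community labels (default: the network's).
#' @return a `bridge_table` data.frame: node, community, bridge_strength,
#'   bridge_closeness, bridge_betweenness, bridge_expected_influence.
#' @export
bridge_centrality <- function(net, partition = net$nodes$community) {
  W <- net$weights
  p <- ncol(W)
  stopifnot(length(partition) == p)
  if (length(unique(partition)) < 2)
    stop("bridge indices undefined: partition has a single community")
  L <- length_matrix(W)
  D <- shortest_path_lengths(net)
  other <- outer(partition, partition, FUN = "!=")

  bridge_strength <- vapply(seq_len(p), function(i)
    sum(abs(W[i, other[i, ]])), numeric(1))
  bridge_ei <- vapply(seq_len(p), function(i)
    sum(W[i, other[i, ]]), numeric(1))
  bridge_closeness <- vapply(seq_len(p), function(i) {
    d <- D[i, other[i, ]]
    if (any(!is.finite(d))) return(0)
    1 / sum(d)
  }, numeric(1))
  if (any(bridge_closeness == 0))
    warning("some nodes cannot reach every other community; their bridge closeness is 0")
  bridge_btw <- brandes_betweenness(L, pair_filter = function(s, t) other[s, t])

  out <- data.frame(
    node = net$nodes$node,
    community = partition,
    bridge_strength = bridge_strength,
    bridge_closeness = bridge_closeness,
    bridge_betweenness = bridge_btw,
    bridge_expected_influence = bridge_ei,
    stringsAsFactors = FALSE)
  class(out) <- c("bridge_table", "data.frame")
  out
}
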