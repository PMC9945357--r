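# Default node set mirroring the study design: 7 anxiety symptoms, 7
# depression symptoms, 6 emotion-regulation components.
default_nodes <- function() {
  data.frame(
    node = c("Tns", "Fgt", "Wrr", "Rlx", "Btt", "Rst", "Pnc",
             "Enj", "Fnn", "Chr", "Slw", "App", "Frw", "Bok",
             "NNC", "GOL", "IMP", "AWR", "STR", "CLR"),
    community = rep(c("anxiety", "depression", "DER"), times = c(7, 7, 6)),
    stringsAsFactors = FALSE)
}

#' Configuration of the synthetic questionnaire generator
#'
#' Describes a ground-truth sparse partial-correlation network over 20 nodes
#' in three communities (7 anxiety, 7 depression, 6 emotion-regulation) and
#' how participants are sampled from it. Defaults emulate the study design:
#' 209 participants, dense within-community structure with rare
#' cross-community edges, four designated bridge edges, moderate edge
#' magnitudes with occasional negative signs, and 4-level Likert responses
#' for the symptom nodes (the emotion-regulation nodes are subscale sums and
#' stay continuous).
#'
#' @param community_sizes named integer vector of community sizes.
#' @param p_within,p_between edge probabilities inside / across communities.
#' @param bridge_edges list of node-id pairs forced present across
#'   communities.
#' @param weight_range magnitude range of the true partial correlations.
#' @param p_negative probability of a negative edge sign.
#' @param n participants.
#' @param likert response levels per community (0 = continuous).
#' @param seed integer seed for the ground-truth draw.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(community_sizes = c(anxiety = 7, depression = 7, DER = 6),
                             p_within = 0.3, p_between = 0.03,
                             bridge_edges = list(c("STR", "Wrr"), c("STR", "Slw"),
                                                 c("Rlx", "Chr"), c("Wrr", "Chr")),
                             weight_range = c(0.15, 0.35),
                             p_negative = 0.2,
                             n = 209,
                             likert = c(anxiety = 4, depression = 4, DER = 0),
                             seed = 1) {
  stopifnot(p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            length(weight_range) == 2, weight_range[1] <= weight_range[2],
            n >= 1)
  if (identical(unname(community_sizes), c(7L, 7L, 6L)) ||
      identical(unname(community_sizes), c(7, 7, 6))) {
    nodes <- default_nodes()
  } else {
    nodes <- data.frame(
      node = unlist(lapply(seq_along(community_sizes), function(k)
        paste0(names(community_sizes)[k] %||% paste0("C", k), "_",
               seq_len(community_sizes[k])))),
      community = rep(names(community_sizes) %||%
                        paste0("C", seq_along(community_sizes)),
                      times = community_sizes),
      stringsAsFactors = FALSE)
  }
  structure(list(
    community_sizes = community_sizes, nodes = nodes,
    p_within = p_within, p_between = p_between,
    bridge_edges = bridge_edges, weight_range = weight_range,
    p_negative = p_negative, n = n, likert = likert,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Draw a ground-truth sparse partial-correlation network
#'
#' Samples a community-structured adjacency (edge probability `p_within`
#' inside and `p_between` across communities), forces the configured bridge
#' edges, draws edge magnitudes uniformly in `weight_range` with random
#' signs, and shrinks all off-diagonal partials proportionally until the
#' implied unit-diagonal precision matrix is positive definite with smallest
#' eigenvalue at least 0.05.
#'
#' @param config a `synthetic_config`.
#' @return a `ground_truth`: list with `partials` (p x p true partial
#'   correlations, zero diagonal), `adjacency` (logical), `sigma` (implied
#'   correlation matrix), `precision`, `nodes`, `shrink_factor`, `config`.
#' @export
generate_true_network <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nodes <- config$nodes
  p <- nrow(nodes)
  comm <- nodes$community
  A <- matrix(FALSE, p, p, dimnames = list(nodes$node, nodes$node))
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    pr <- if (comm[i] == comm[j]) config$p_within else config$p_between
    A[i, j] <- A[j, i] <- stats::runif(1) < pr
  }
  for (e in config$bridge_edges) {
    stopifnot(all(e %in% nodes$node))
    if (comm[match(e[1], nodes$node)] == comm[match(e[2], nodes$node)])
      stop("bridge edge ", paste(e, collapse = "-"), " is within a community")
    A[e[1], e[2]] <- A[e[2], e[1]] <- TRUE
  }
  P <- matrix(0, p, p, dimnames = dimnames(A))
  ut <- which(upper.tri(A) & A, arr.ind = TRUE)
  if (nrow(ut)) {
    mag <- stats::runif(nrow(ut), config$weight_range[1], config$weight_range[2])
    sgn <- ifelse(stats::runif(nrow(ut)) < config$p_negative, -1, 1)
    for (k in seq_len(nrow(ut))) {
      P[ut[k, 1], ut[k, 2]] <- P[ut[k, 2], ut[k, 1]] <- mag[k] * sgn[k]
    }
  }
  # unit-diagonal precision implied by the partials: k_ij = -p_ij
  shrink <- 1
  for (step in seq_len(200)) {
    K <- diag(p) - shrink * P
    if (min(eigen(K, symmetric = TRUE, only.values = TRUE)$values) >= 0.05) break
    shrink <- shrink * 0.95
    if (step == 200) stop("could not reach positive definiteness by shrinkage")
  }
  P <- shrink * P
  K <- diag(p) - P
  sigma <- stats::cov2cor(solve(K))
  dimnames(sigma) <- dimnames(A)
  structure(list(partials = P, adjacency = A, sigma = sigma, precision = K,
                 nodes = nodes, shrink_factor = shrink, config = config),
            class = "ground_truth")
}

# equal-probability thresholds on a standard-normal latent
discretize_likert <- function(z, levels) {
  cutpoints <- stats::qnorm(seq_len(levels - 1) / levels)
  findInterval(z, cutpoints)  # 0 .. levels-1
}

#' Sample participant node scores from a ground truth
#'
#' Draws multivariate-normal latent scores with the truth's implied
#' correlation matrix and discretizes each node configured with L >= 2
#' Likert levels by equal-probability standard-normal thresholds (codes
#' 0..L-1); nodes configured continuous (level 0) pass through.
#'
#' @param truth a `ground_truth`.
#' @param config its `synthetic_config` (defaults to the one stored on the
#'   truth).
#' @param seed sampling seed (default: the config seed + 1, so truth and
#'   sample streams stay distinct).
#' @return a `node_score_matrix` with the truth attached as attribute
#'   `ground_truth`.
#' @export
sample_responses <- function(truth, config = truth$config,
                             seed = config$seed + 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(as.integer(seed))
  p <- nrow(truth$nodes)
  Z <- MASS::mvrnorm(config$n, mu = rep(0, p), Sigma = truth$sigma)
  if (config$n == 1) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- truth$nodes$node
  X <- Z
  for (k in seq_len(p)) {
    cm <- truth$nodes$community[k]
    L <- if (cm %in% names(config$likert)) config$likert[[cm]] else 0
    if (L >= 2) X[, k] <- discretize_likert(Z[, k], L)
  }
  rownames(X) <- paste0("P", seq_len(config$n))
  out <- node_score_matrix(X, truth$nodes$community)
  attr(out, "ground_truth") <- truth
  out
}

#' Write an item-level synthetic questionnaire CSV
#'
#' Expands synthetic node scores to raw item responses in the CSV schema
#' [load_responses()] reads: each symptom node becomes its single
#' questionnaire item (0-3), and each emotion-regulation subscale node is
#' decomposed into its items as subscale-factor-plus-noise latents
#' discretized to the 1-5 response scale, with reverse-coded items stored in
#' raw (uncorrected) direction. Synthetic demographics (sex, age,
#' family_structure, location, economic_status, the last two with missing
#' values) are included so the descriptives stage can be exercised too.
#' Exists to test the scoring stage end to end; network-level analyses
#' consume node scores directly.
#'
#' @param truth a `ground_truth` over the default 20-node set.
#' @param path output CSV path.
#' @param seed sampling seed.
#' @param loading correlation between an item latent and its subscale factor.
#' @return invisibly, the path.
#' @export
write_synthetic_items <- function(truth, path, seed = truth$config$seed + 2L,
                                  loading = 0.7) {
  config <- truth$config
  stopifnot(identical(truth$nodes$node, default_nodes()$node))
  set.seed(as.integer(seed))
  hads <- hads_definition()
  ders <- ders_definition()
  p <- nrow(truth$nodes)
  Z <- MASS::mvrnorm(config$n, mu = rep(0, p), Sigma = truth$sigma)
  if (config$n == 1) Z <- matrix(Z, nrow = 1)
  colnames(Z) <- truth$nodes$node

  out <- data.frame(
    participant_id = paste0("P", seq_len(config$n)),
    sex = sample(c("female", "male"), config$n, replace = TRUE),
    age = sample(12:18, config$n, replace = TRUE),
    family_structure = sample(c("regular", "irregular"), config$n,
                              replace = TRUE, prob = c(0.7, 0.3)),
    location = sample(c("urban", "rural", NA), config$n,
                      replace = TRUE, prob = c(0.3, 0.5, 0.2)),
    economic_status = sample(c("wealthy", "normal_poor", NA), config$n,
                             replace = TRUE, prob = c(0.2, 0.6, 0.2)),
    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(hads$items))) {
    it <- hads$items[k, ]
    out[[it$item_id]] <- discretize_likert(Z[, it$node], 4L)
  }
  for (sub in names(ders$subscales)) {
    f <- Z[, sub]
    for (item in ders$subscales[[sub]]) {
      latent <- loading * f + sqrt(1 - loading^2) * stats::rnorm(config$n)
      v <- discretize_likert(latent, 5L) + 1L  # 1..5
      if (item %in% ders$reverse_coded) v <- 6L - v
      out[[item]] <- v
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Edge-recovery metrics of an estimated network against a ground truth
#'
#' Sensitivity (recovered true edges / true edges), specificity (correctly
#' absent / truly absent), and the product-moment correlation between
#' estimated and true edge weights over the union of true and estimated
#' edges.
#'
#' @param estimated a `ggm_network` (or weight matrix) on the truth's nodes.
#' @param truth a `ground_truth`.
#' @param edge_tol magnitude below which an estimated weight counts as zero.
#' @return list with `sensitivity` (NA when the truth has no edges),
#'   `specificity`, `weight_correlation`.
#' @export
recovery_metrics <- function(estimated, truth, edge_tol = 1e-8) {
  W <- if (inherits(estimated, "ggm_network")) estimated$weights else estimated
  stopifnot(all(dim(W) == dim(truth$partials)))
  ut <- upper.tri(W)
  est_edge <- abs(W[ut]) > edge_tol
  true_edge <- truth$adjacency[ut]
  union_edge <- est_edge | true_edge
  list(
    sensitivity = if (!any(true_edge)) NA_real_ else
      sum(est_edge & true_edge) / sum(true_edge),
    specificity = if (!any(!true_edge)) NA_real_ else
      sum(!est_edge & !true_edge) / sum(!true_edge),
    weight_correlation = if (sum(union_edge) < 2) NA_real_ else
      stats::cor(W[ut][union_edge], truth$partials[ut][union_edge])
  )
}
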