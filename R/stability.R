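#' Case-dropping bootstrap for centrality stability
#'
#' For every drop proportion q in `grid` and every replicate, a subsample of
#' ceiling((1 - q) * n) participants is drawn without replacement, the whole
#' estimation pipeline (correlation -> graphical lasso path -> EBIC selection
#' -> centrality) is re-run on it, and each centrality index vector is
#' correlated (product-moment by default) with the full-sample vector. A
#' replicate whose fit fails, or whose index vector is constant, is recorded
#' as undefined and excluded from later certainty fractions.
#'
#' @param scores a `node_score_matrix`.
#' @param grid ascending drop proportions in (0, 1); the default 0.05..0.75
#'   spans the range conventionally plotted.
#' @param B replicates per proportion (default 1000).
#' @param seed integer seed; the same seed reproduces the result exactly.
#' @param indices which centrality indices to track.
#' @param cor_method correlation between subsample and full-sample centrality
#'   vectors.
#' @param gamma,n_lambda,min_ratio,method estimation settings, as in
#'   [estimate_network()].
#' @return a `stability_result`: list with `indices`, `grid`, `correlations`
#'   (per index a B x length(grid) matrix, NA = undefined), `failures`
#'   (failed fits per proportion), `full` (full-sample centrality table),
#'   `B`, `seed`.
#' @export
case_drop_bootstrap <- function(scores, grid = seq(0.05, 0.75, by = 0.05),
                                B = 1000, seed,
                                indices = c("strength", "closeness",
                                            "betweenness", "expected_influence"),
                                cor_method = c("pearson", "spearman"),
                                gamma = 0.5, n_lambda = 100, min_ratio = 0.01,
                                method = "pearson") {
  stopifnot(inherits(scores, "node_score_matrix"), B >= 1,
            all(grid >= 0), all(grid < 1), !is.unsorted(grid))
  cor_method <- match.arg(cor_method)
  n <- nrow(scores$scores)
  p <- ncol(scores$scores)
  if (any(ceiling((1 - grid) * n) < p + 1))
    stop("largest drop proportion leaves fewer than p + 1 cases")

  fit_centrality <- function(idx) {
    sub <- scores
    sub$scores <- scores$scores[idx, , drop = FALSE]
    net <- suppressWarnings(
      estimate_network(sub, gamma = gamma, n_lambda = n_lambda,
                       min_ratio = min_ratio, method = method))
    suppressWarnings(node_centrality(net))
  }
  full <- fit_centrality(seq_len(n))

  set.seed(as.integer(seed))
  cors <- lapply(indices, function(i) matrix(NA_real_, B, length(grid)))
  names(cors) <- indices
  failures <- integer(length(grid))
  for (g in seq_along(grid)) {
    m <- ceiling((1 - grid[g]) * n)
    for (b in seq_len(B)) {
      idx <- sample.int(n, m)
      cent <- tryCatch(fit_centrality(idx), error = function(e) NULL)
      if (is.null(cent)) { failures[g] <- failures[g] + 1L; next }
      for (ix in indices) {
        x <- cent[[ix]]; y <- full[[ix]]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # stays NA
        cors[[ix]][b, g] <- stats::cor(x, y, method = cor_method)
      }
    }
  }
  if (any(failures / B > 0.05))
    warning("estimator failure rate above 5% at drop proportion(s) ",
            paste(grid[failures / B > 0.05], collapse = ", "),
            " (failures: ", paste(failures[failures / B > 0.05], collapse = ", "), ")")
  undef <- vapply(cors, function(m) sum(is.na(m)), integer(1))
  if (any(undef > 0))
    warning("undefined correlations (constant centrality vectors or failed fits): ",
            paste(sprintf("%s=%d", names(undef[undef > 0]), undef[undef > 0]),
                  collapse = ", "))
  structure(list(indices = indices, grid = grid, correlations = cors,
                 failures = failures, full = full, B = B,
                 seed = as.integer(seed)),
            class = "stability_result")
}

#' Correlation-stability (CS) coefficient
#'
#' The largest drop proportion q on the grid such that, at q and at every
#' smaller grid proportion, at least `certainty` of the defined bootstrap
#' correlations are >= `threshold`; 0 when no proportion qualifies. The
#' monotone-prefix requirement makes the value unique even when the
#' qualifying fraction dips and recovers along the grid.
#'
#' @param result a `stability_result`.
#' @param threshold correlation retained (default 0.7).
#' @param certainty required fraction of qualifying replicates (default
#'   0.95).
#' @return named numeric vector, one CS value per index.
#' @export
cs_coefficient <- function(result, threshold = 0.7, certainty = 0.95) {
  stopifnot(inherits(result, "stability_result"))
  vapply(result$indices, function(ix) cs_one(result, ix, threshold, certainty),
         numeric(1))
}

cs_one <- function(result, ix, threshold, certainty) {
  M <- result$correlations[[ix]]
  frac <- vapply(seq_along(result$grid), function(g) {
    v <- M[, g]
    defined <- !is.na(v)
    if (!any(defined))
      stop("all correlations undefined for index '", ix,
           "' at drop proportion ", result$grid[g])
    mean(v[defined] >= threshold)
  }, numeric(1))
  ok <- frac >= certainty
  qualifying <- which(cumprod(ok) == 1)
  if (!length(qualifying)) 0 else result$grid[max(qualifying)]
}

#' Quantile bands of the stability correlations
#'
#' Per index and drop proportion: mean and the 2.5%/97.5% quantiles of the
#' defined bootstrap correlations, for drop-proportion stability plots.
#'
#' @param result a `stability_result`.
#' @return data.frame: index, drop_proportion, mean, q025, q975, n_defined.
#' @export
stability_bands <- function(result) {
  rows <- list()
  for (ix in result$indices) {
    M <- result$correlations[[ix]]
    for (g in seq_along(result$grid)) {
      v <- M[, g]; v <- v[!is.na(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        index = ix, drop_proportion = result$grid[g],
        mean = mean(v), q025 = unname(stats::quantile(v, 0.025)),
        q975 = unname(stats::quantile(v, 0.975)), n_defined = length(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# long-format export used by the pipeline writer
stability_long <- function(result) {
  rows <- list()
  for (ix in result$indices) {
    M <- result$correlations[[ix]]
    rows[[length(rows) + 1L]] <- data.frame(
      index = ix,
      drop_proportion = rep(result$grid, each = result$B),
      replicate = rep(seq_len(result$B), times = length(result$grid)),
      correlation = as.vector(M),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
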