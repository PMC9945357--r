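write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Export a network as GraphML
#'
#' Nonzero edges with their weights, plus node community attributes.
#'
#' @param net a `ggm_network`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$community <- net$nodes$community
  igraph::V(g)$label <- net$nodes$label
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

edge_list <- function(net, edge_tol = 1e-8) {
  W <- net$weights
  idx <- which(upper.tri(W) & abs(W) > edge_tol, arr.ind = TRUE)
  data.frame(node_i = rownames(W)[idx[, 1]],
             node_j = colnames(W)[idx[, 2]],
             weight = W[idx],
             stringsAsFactors = FALSE)[order(-abs(W[idx])), ]
}

stage_log <- function(stage, detail, t0) {
  message(sprintf("[%s] %s (%.2fs)", stage, detail,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full network-analysis pipeline
#'
#' Load (or simulate) questionnaire data, score nodes, estimate the
#' regularized partial-correlation network, compute centrality, bridge
#' centrality and both layouts, run the case-dropping stability bootstrap,
#' and write every tabular artifact plus a run manifest to `out_dir`. All
#' randomness flows from `config$seed`, expanded into per-stage seeds that
#' the manifest records; the same config and seed reproduce every output
#' byte (the manifest's timestamp aside).
#'
#' @param config a list (or path to a YAML file) with fields:
#'   `seed`; either `input_csv` (item-level CSV read with the shipped HADS +
#'   DERS definitions) or `synthetic` (arguments for [synthetic_config()]);
#'   optional `estimation` (gamma, n_lambda, min_ratio, method), `stability`
#'   (grid, B, threshold, certainty), `layout` (n_init, dissimilarity, type),
#'   `grouping` (demographic fields for descriptives).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  est <- utils::modifyList(list(gamma = 0.5, n_lambda = 100, min_ratio = 0.01,
                                method = "pearson"), config$estimation %||% list())
  stab <- utils::modifyList(list(grid = seq(0.05, 0.75, by = 0.05), B = 1000,
                                 threshold = 0.7, certainty = 0.95),
                            config$stability %||% list())
  lay <- utils::modifyList(list(n_init = 10, dissimilarity = "weights",
                                type = "ordinal"), config$layout %||% list())
  set.seed(as.integer(config$seed))
  stage_seeds <- sample.int(.Machine$integer.max, 4)
  names(stage_seeds) <- c("truth", "sample", "stability", "layout")
  t0 <- as.numeric(Sys.time())

  # --- data stage ---------------------------------------------------------
  truth <- NULL
  input_hash <- NULL
  if (!is.null(config$input_csv)) {
    defs <- list(hads_definition(), ders_definition())
    tab <- load_responses(config$input_csv, defs)
    scores <- score_nodes(tab, defs)
    input_hash <- unname(tools::md5sum(config$input_csv))
    stage_log("load", sprintf("%d participants x %d items, %d dropped",
                              length(tab$participant_id), ncol(tab$responses),
                              tab$dropped), t0)
  } else {
    syn_args <- config$synthetic %||% list()
    if (inherits(syn_args, "synthetic_config")) {
      syn <- syn_args
    } else {
      if (is.null(syn_args$seed)) syn_args$seed <- stage_seeds[["truth"]]
      syn <- do.call(synthetic_config, syn_args)
    }
    truth <- generate_true_network(syn)
    scores <- sample_responses(truth, seed = stage_seeds[["sample"]])
    write_table(data.frame(node = truth$nodes$node, truth$partials,
                           check.names = FALSE),
                file.path(out_dir, "true_weight_matrix.csv"))
    jsonlite::write_json(
      list(seed = syn$seed, n = syn$n, p_within = syn$p_within,
           p_between = syn$p_between, weight_range = syn$weight_range,
           p_negative = syn$p_negative,
           bridge_edges = syn$bridge_edges,
           shrink_factor = truth$shrink_factor),
      file.path(out_dir, "synthetic_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stage_log("simulate", sprintf("%d participants x %d nodes",
                                  nrow(scores$scores), ncol(scores$scores)), t0)
  }
  write_table(data.frame(participant_id = scores$participant_id,
                         scores$scores, check.names = FALSE),
              file.path(out_dir, "node_scores.csv"))
  if (!is.null(scores$totals) && !is.null(scores$demographics)) {
    groupings <- config$grouping %||%
      intersect(c("sex", "family_structure", "location", "economic_status", "age"),
                names(scores$demographics))
    desc <- do.call(rbind, lapply(groupings, function(g) {
      d <- summarize_by_group(scores, g)
      if (nrow(d)) cbind(grouping = g, d) else NULL
    }))
    if (!is.null(desc))
      write_table(desc, file.path(out_dir, "descriptives.csv"))
  }

  # --- estimation ---------------------------------------------------------
  net <- estimate_network(scores, gamma = est$gamma, n_lambda = est$n_lambda,
                          min_ratio = est$min_ratio, method = est$method)
  write_table(edge_list(net), file.path(out_dir, "edge_list.csv"))
  write_table(data.frame(node = rownames(net$weights), net$weights,
                         check.names = FALSE),
              file.path(out_dir, "weight_matrix.csv"))
  write_table(net$path, file.path(out_dir, "path.csv"))
  write_graphml(net, file.path(out_dir, "network.graphml"))
  stage_log("estimate", sprintf("lambda=%.4g, %d edges, sparsity %.1f%%",
                                net$lambda_selected,
                                edge_count(net$weights), 100 * net$sparsity), t0)

  # --- centrality + bridge ------------------------------------------------
  cent <- scale_relative_to_max(suppressWarnings(node_centrality(net)))
  cent <- cent[order(-cent$expected_influence_scaled), ]
  write_table(cent, file.path(out_dir, "centrality.csv"))
  bridge <- scale_relative_to_max(suppressWarnings(bridge_centrality(net)))
  bridge <- bridge[order(-bridge$bridge_expected_influence_scaled), ]
  write_table(bridge, file.path(out_dir, "bridge.csv"))
  stage_log("centrality", sprintf("top strength: %s",
                                  cent$node[which.max(cent$strength)]), t0)

  # --- layouts ------------------------------------------------------------
  circ <- circular_group_layout(net)
  write_table(cbind(circ$coords, layout_kind = circ$layout_kind),
              file.path(out_dir, "layout_circle.csv"))
  mds <- mds_layout(net, seed = stage_seeds[["layout"]], n_init = lay$n_init,
                    dissimilarity = lay$dissimilarity, type = lay$type)
  write_table(cbind(mds$coords, layout_kind = mds$layout_kind),
              file.path(out_dir, "layout_mds.csv"))
  jsonlite::write_json(
    list(stress1 = mds$stress1, iterations = mds$iterations,
         start_used = mds$start_used, seed = mds$seed,
         dissimilarity = mds$dissimilarity, type = mds$type),
    file.path(out_dir, "mds_meta.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  stage_log("layout", sprintf("MDS stress-1 = %.4f", mds$stress1), t0)

  # --- stability ----------------------------------------------------------
  boot <- suppressWarnings(
    case_drop_bootstrap(scores, grid = stab$grid, B = stab$B,
                        seed = stage_seeds[["stability"]],
                        gamma = est$gamma, n_lambda = est$n_lambda,
                        min_ratio = est$min_ratio, method = est$method))
  cs <- vapply(boot$indices, function(ix) {
    tryCatch(cs_one(boot, ix, stab$threshold, stab$certainty),
             error = function(e) {
               warning("CS undefined for index '", ix, "': ",
                       conditionMessage(e), call. = FALSE)
               NA_real_
             })
  }, numeric(1))
  write_table(stability_long(boot), file.path(out_dir, "stability_long.csv"))
  write_table(stability_bands(boot), file.path(out_dir, "stability_bands.csv"))
  jsonlite::write_json(as.list(cs), file.path(out_dir, "cs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_log("stability", paste(sprintf("CS(%s)=%.2f", names(cs), cs),
                               collapse = ", "), t0)

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("bridgenet")),
    seed = config$seed, stage_seeds = as.list(stage_seeds),
    input_csv = config$input_csv, input_md5 = input_hash,
    synthetic = if (!is.null(truth)) truth$config$seed,
    estimation = est,
    stability = stab[c("B", "threshold", "certainty")],
    stability_grid = stab$grid,
    layout = lay,
    n_participants = nrow(scores$scores), n_nodes = ncol(scores$scores),
    lambda_selected = net$lambda_selected, sparsity = net$sparsity,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(scores = scores, network = net, centrality = cent,
                 bridge = bridge, layouts = list(circle = circ, mds = mds),
                 stability = boot, cs = cs, truth = truth,
                 manifest = manifest))
}
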