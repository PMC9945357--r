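#' Read an instrument definition
#'
#' An instrument definition declares the items of a questionnaire (ids,
#' labels, response ranges), how items group into subscales, which items are
#' reverse-coded, and whether the instrument contributes one network node per
#' item or one per subscale. Definitions are shipped as editable YAML files so
#' that item-to-subscale assignments are data, not code.
#'
#' @param path path to a YAML definition file. The file must contain
#'   `instrument`, `node_granularity` (`per_item` or `per_subscale`),
#'   `community`, `items` (list of `id`, `label`, `min`, `max` and, for
#'   per-item instruments, `node`), `subscales` (list of `id`, `label`,
#'   `items`) and optionally `reverse` (item ids).
#' @return an object of class `instrument_definition`.
#' @export
read_instrument <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(raw$items, function(it) {
    data.frame(item_id = it$id, label = it$label,
               min_response = as.integer(it$min),
               max_response = as.integer(it$max),
               node = if (!is.null(it$node)) it$node else NA_character_,
               stringsAsFactors = FALSE)
  }))
  subscales <- lapply(raw$subscales, function(s) s$items)
  names(subscales) <- vapply(raw$subscales, function(s) s$id, character(1))
  subscale_labels <- vapply(raw$subscales, function(s) s$label, character(1))
  names(subscale_labels) <- names(subscales)
  def <- structure(list(
    instrument_name = raw$instrument,
    items = items,
    subscales = subscales,
    subscale_labels = subscale_labels,
    reverse_coded = as.character(raw$reverse %||% character(0)),
    node_granularity = raw$node_granularity,
    community = raw$community
  ), class = "instrument_definition")
  validate_instrument(def)
  def
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_instrument <- function(def) {
  stopifnot(inherits(def, "instrument_definition"))
  ids <- def$items$item_id
  if (anyDuplicated(ids)) stop("duplicate item ids in ", def$instrument_name)
  if (!def$node_granularity %in% c("per_item", "per_subscale"))
    stop("node_granularity must be per_item or per_subscale")
  sub_items <- unlist(def$subscales, use.names = FALSE)
  if (!all(sub_items %in% ids))
    stop("subscale references unknown item(s): ",
         paste(setdiff(sub_items, ids), collapse = ", "))
  if (def$node_granularity == "per_subscale") {
    if (anyDuplicated(sub_items))
      stop("per_subscale instrument: items must belong to exactly one subscale")
    if (!setequal(sub_items, ids))
      stop("per_subscale instrument: every item must belong to a subscale")
  }
  if (!all(def$reverse_coded %in% ids))
    stop("reverse_coded contains unknown item id(s)")
  if (any(def$items$min_response >= def$items$max_response))
    stop("item response range degenerate (min >= max)")
  invisible(def)
}

#' Shipped definition of the Hospital Anxiety and Depression Scale
#'
#' 14 items scored 0-3, seven on the anxiety subscale and seven on the
#' depression subscale; every item becomes its own network node. Responses
#' are assumed to be recorded already in scored direction (0 = least
#' symptomatic), so the default reverse set is empty; edit the YAML if your
#' data stores raw item endorsements instead.
#'
#' @return an `instrument_definition`.
#' @export
hads_definition <- function() {
  read_instrument(system.file("extdata", "hads.yaml", package = "bridgenet",
                              mustWork = TRUE))
}

#' Shipped definition of the Difficulties in Emotion Regulation Scale
#'
#' 36 items scored 1-5, partitioned into the six published subscales
#' (Nonacceptance, Goals, Impulse, Awareness, Strategies, Clarity); each
#' subscale sum becomes one network node. The standard reverse-coded item
#' list is pre-filled and editable.
#'
#' @return an `instrument_definition`.
#' @export
ders_definition <- function() {
  read_instrument(system.file("extdata", "ders.yaml", package = "bridgenet",
                              mustWork = TRUE))
}

#' Load participant item responses
#'
#' Reads a delimited text file (CSV, header row, one row per participant)
#' holding every item of the supplied instrument definitions plus optional
#' demographic columns. Participants with any missing item response are
#' dropped (listwise deletion) and counted; missing demographics are kept.
#'
#' @param path CSV file path.
#' @param defs list of `instrument_definition` objects.
#' @param id_col name of the participant id column (default `participant_id`;
#'   created as `P1..Pn` when absent).
#' @return an `item_response_table`: list with `responses` (participants x
#'   items integer data.frame), `demographics`, `participant_id`, `dropped`
#'   (count of listwise-deleted rows) and `defs`.
#' @export
load_responses <- function(path, defs,
                           id_col = "participant_id") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  item_ids <- unlist(lapply(defs, function(d) d$items$item_id), use.names = FALSE)
  missing_cols <- setdiff(item_ids, names(df))
  if (length(missing_cols))
    stop("input is missing item column(s): ", paste(missing_cols, collapse = ", "))
  pid <- if (id_col %in% names(df)) as.character(df[[id_col]]) else
    paste0("P", seq_len(nrow(df)))
  if (anyDuplicated(pid)) stop("participant ids are not unique")

  resp <- df[, item_ids, drop = FALSE]
  # range validation on observed values
  lims <- do.call(rbind, lapply(defs, function(d)
    d$items[, c("item_id", "min_response", "max_response")]))
  for (it in item_ids) {
    v <- resp[[it]]
    lim <- lims[lims$item_id == it, ]
    bad <- which(!is.na(v) & (v < lim$min_response | v > lim$max_response))
    if (length(bad))
      stop(sprintf("response out of range [%d,%d] for item '%s', participant '%s' (value %s)",
                   lim$min_response, lim$max_response, it, pid[bad[1]], v[bad[1]]))
  }
  complete <- stats::complete.cases(resp)
  dropped <- sum(!complete)
  if (dropped > 0)
    warning(sprintf("%d participant(s) dropped for missing item responses", dropped))

  demo_cols <- intersect(c("sex", "age", "family_structure", "location",
                           "economic_status"), names(df))
  structure(list(
    participant_id = pid[complete],
    responses = resp[complete, , drop = FALSE],
    demographics = df[complete, demo_cols, drop = FALSE],
    dropped = dropped,
    defs = defs
  ), class = "item_response_table")
}

reverse_correct <- function(values, min_response, max_response) {
  (min_response + max_response) - values
}

corrected_items <- function(table, def) {
  out <- table$responses[, def$items$item_id, drop = FALSE]
  rev_ids <- intersect(def$reverse_coded, names(out))
  for (it in rev_ids) {
    lim <- def$items[def$items$item_id == it, ]
    out[[it]] <- reverse_correct(out[[it]], lim$min_response, lim$max_response)
  }
  out
}

#' Score item responses into network node variables
#'
#' Per-item instruments contribute each (reverse-corrected) item as a node;
#' per-subscale instruments contribute each subscale's sum of
#' reverse-corrected items. Reverse correction maps a response r on a
#' [min, max] scale to (min + max) - r.
#'
#' @param table an `item_response_table` from [load_responses()].
#' @param defs list of `instrument_definition` objects (defaults to those
#'   stored on the table).
#' @return a `node_score_matrix`: list with `scores` (participants x nodes
#'   numeric matrix), `nodes` (data.frame: node, label, community),
#'   `totals` (per-instrument/subscale total scores used for descriptives),
#'   `participant_id` and `demographics`.
#' @export
score_nodes <- function(table, defs = table$defs) {
  stopifnot(inherits(table, "item_response_table"))
  score_cols <- list()
  node_meta <- list()
  totals <- list()
  for (def in defs) {
    corr <- corrected_items(table, def)
    if (def$node_granularity == "per_item") {
      for (k in seq_len(nrow(def$items))) {
        it <- def$items[k, ]
        node_id <- if (!is.na(it$node)) it$node else it$item_id
        score_cols[[node_id]] <- corr[[it$item_id]]
        node_meta[[node_id]] <- data.frame(
          node = node_id, label = it$label,
          community = item_community(def, it$item_id),
          stringsAsFactors = FALSE)
      }
      for (sub in names(def$subscales)) {
        sub_items <- def$subscales[[sub]]
        totals[[paste0(def$instrument_name, "_", sub)]] <-
          rowSums(corr[, sub_items, drop = FALSE])
      }
    } else {
      for (sub in names(def$subscales)) {
        sub_items <- def$subscales[[sub]]
        missing <- setdiff(sub_items, names(corr))
        if (length(missing))
          stop("subscale ", sub, " references absent item(s): ",
               paste(missing, collapse = ", "))
        score_cols[[sub]] <- rowSums(corr[, sub_items, drop = FALSE])
        node_meta[[sub]] <- data.frame(
          node = sub, label = def$subscale_labels[[sub]],
          community = def$community, stringsAsFactors = FALSE)
      }
      totals[[def$instrument_name]] <- rowSums(corr)
    }
  }
  scores <- do.call(cbind, score_cols)
  rownames(scores) <- table$participant_id
  structure(list(
    scores = scores,
    nodes = do.call(rbind, c(node_meta, make.row.names = FALSE)),
    totals = do.call(cbind, totals),
    participant_id = table$participant_id,
    demographics = table$demographics
  ), class = "node_score_matrix")
}

# community of a per-item node: the subscale it belongs to, mapped through the
# definition's community field (a named mapping when subscales differ)
item_community <- function(def, item_id) {
  for (sub in names(def$subscales)) {
    if (item_id %in% def$subscales[[sub]]) {
      if (length(def$community) > 1 || !is.null(names(def$community))) {
        cm <- unlist(def$community)
        if (sub %in% names(cm)) return(cm[[sub]])
      }
      return(def$community[[1]])
    }
  }
  def$community[[1]]
}

#' Build a node-score matrix directly from scores and metadata
#'
#' Wraps an already-computed participants x nodes matrix (e.g. synthetic
#' node-level data) in the container the estimation and stability stages
#' consume.
#'
#' @param scores numeric matrix, participants in rows, nodes in columns.
#' @param communities character vector, one community per node.
#' @param labels optional full node labels.
#' @return a `node_score_matrix`.
#' @export
node_score_matrix <- function(scores, communities,
                              labels = colnames(scores)) {
  stopifnot(is.matrix(scores), ncol(scores) == length(communities))
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("V", seq_len(ncol(scores)))
  structure(list(
    scores = scores,
    nodes = data.frame(node = colnames(scores), label = labels,
                       community = communities, stringsAsFactors = FALSE),
    totals = NULL,
    participant_id = rownames(scores) %||% paste0("P", seq_len(nrow(scores))),
    demographics = NULL
  ), class = "node_score_matrix")
}

#' Descriptive statistics by demographic group
#'
#' One row per measure and observed group level with N, mean and SD
#' (n - 1 denominator). Participants missing the grouping field are excluded
#' and counted; a single-participant group reports SD as NA rather than zero.
#'
#' @param scores a `node_score_matrix` carrying `totals` and `demographics`
#'   (i.e. produced by [score_nodes()]).
#' @param grouping name of the demographic field to group by.
#' @return data.frame with columns measure, group, n, mean, sd; the number of
#'   participants excluded for a missing grouping value is attached as
#'   attribute `n_missing_group`.
#' @export
summarize_by_group <- function(scores, grouping) {
  stopifnot(inherits(scores, "node_score_matrix"))
  if (is.null(scores$totals) || is.null(scores$demographics))
    stop("scores carries no totals/demographics; use score_nodes() output")
  if (!grouping %in% names(scores$demographics))
    stop("unknown grouping field: ", grouping)
  g <- scores$demographics[[grouping]]
  keep <- !is.na(g) & g != ""
  n_missing <- sum(!keep)
  if (!any(keep)) {
    warning("all values of grouping '", grouping, "' are missing")
    out <- data.frame(measure = character(0), group = character(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0))
    attr(out, "n_missing_group") <- n_missing
    return(out)
  }
  g <- as.character(g[keep])
  tot <- scores$totals[keep, , drop = FALSE]
  rows <- list()
  for (m in colnames(tot)) {
    for (lev in sort(unique(g))) {
      v <- tot[g == lev, m]
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, group = lev, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_missing_group") <- n_missing
  out
}
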