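# A 4-item toy instrument (two 2-item subscales, one reverse-coded item)
# plus a writer for item-response CSVs built in code.

toy_instrument_yaml <- function(dir = tempdir()) {
  path <- file.path(dir, "toy.yaml")
  writeLines(c(
    "instrument: TOY",
    "node_granularity: per_subscale",
    "community: toy",
    "items:",
    "  - {id: T1, label: first,  min: 1, max: 5}",
    "  - {id: T2, label: second, min: 1, max: 5}",
    "  - {id: T3, label: third,  min: 1, max: 5}",
    "  - {id: T4, label: fourth, min: 1, max: 5}",
    "subscales:",
    "  - {id: S1, label: sub one, items: [T1, T2]}",
    "  - {id: S2, label: sub two, items: [T3, T4]}",
    "reverse: [T2]"), path)
  path
}

write_response_csv <- function(df, dir = tempdir(),
                               name = "responses.csv") {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# complete valid HADS+DERS response frame with n participants
full_response_frame <- function(n, seed = 1) {
  set.seed(seed)
  hads <- hads_definition(); ders <- ders_definition()
  df <- data.frame(participant_id = paste0("P", seq_len(n)))
  for (id in hads$items$item_id) df[[id]] <- sample(0:3, n, replace = TRUE)
  for (id in ders$items$item_id) df[[id]] <- sample(1:5, n, replace = TRUE)
  df$sex <- sample(c("female", "male"), n, replace = TRUE)
  df$age <- sample(12:18, n, replace = TRUE)
  df
}
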