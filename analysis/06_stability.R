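#!/usr/bin/env Rscript
# Case-dropping bootstrap: how far can the sample shrink before subsample
# centralities stop tracking the full-sample ones? Summarized by the CS
# coefficient (threshold 0.7, certainty 95%).

library(bridgenet)

out <- "results/study"
scores_df <- read.csv(file.path(out, "node_scores.csv"), check.names = FALSE)
nodes <- read.csv(file.path(out, "nodes.csv"))
X <- as.matrix(scores_df[, -1])
scores <- node_score_matrix(X, nodes$community[match(colnames(X), nodes$node)])

boot <- suppressWarnings(
  case_drop_bootstrap(scores, grid = seq(0.05, 0.75, by = 0.05), B = 250,
                      seed = 20240209))
write.csv(bridgenet:::stability_long(boot),
          file.path(out, "stability_long.csv"), row.names = FALSE)
write.csv(stability_bands(boot), file.path(out, "stability_bands.csv"),
          row.names = FALSE)

cs <- vapply(boot$indices, function(ix)
  tryCatch(bridgenet:::cs_one(boot, ix, 0.7, 0.95),
           error = function(e) NA_real_), numeric(1))
jsonlite::write_json(as.list(cs), file.path(out, "cs.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("CS coefficients (max drop proportion keeping r >= 0.7 in >= 95% of runs):\n")
print(round(cs, 3))
failed <- sum(boot$failures)
if (failed > 0)
  cat(sprintf("note: %d of %d refits failed (small subsamples)\n",
              failed, boot$B * length(boot$grid)))
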