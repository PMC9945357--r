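#!/usr/bin/env Rscript
# Simulate the study cohort: a known sparse partial-correlation network over
# 20 nodes (7 anxiety / 7 depression / 6 emotion-regulation) with four
# designated bridge edges, and 209 participants drawn from it.
#
# Two artifacts come out: the node scores the network stages consume
# (symptom nodes as 0-3 Likert, emotion-regulation nodes continuous), and a
# raw item-level questionnaire CSV (14 HADS + 36 DERS items plus
# demographics) used in 02 to exercise the scoring stage.

library(bridgenet)

out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(seed = 20240209)
truth <- generate_true_network(cfg)

scores <- sample_responses(truth)
write.csv(data.frame(participant_id = scores$participant_id, scores$scores,
                     check.names = FALSE),
          file.path(out, "node_scores.csv"), row.names = FALSE)
write.csv(scores$nodes, file.path(out, "nodes.csv"), row.names = FALSE)

write_synthetic_items(truth, file.path(out, "responses.csv"))

write.csv(data.frame(node = truth$nodes$node, truth$partials,
                     check.names = FALSE),
          file.path(out, "true_weight_matrix.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = cfg$seed, n = cfg$n, p_within = cfg$p_within,
       p_between = cfg$p_between, weight_range = cfg$weight_range,
       bridge_edges = cfg$bridge_edges, shrink_factor = truth$shrink_factor),
  file.path(out, "synthetic_manifest.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

n_true <- sum(truth$adjacency[upper.tri(truth$adjacency)])
cat(sprintf("simulated %d participants; true network has %d of 190 edges (%.1f%% sparse)\n",
            cfg$n, n_true, 100 * (1 - n_true / 190)))
cat("bridge edges:",
    paste(vapply(cfg$bridge_edges, paste, "", collapse = "-"), collapse = ", "),
    "\n")
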