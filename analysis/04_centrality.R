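#!/usr/bin/env Rscript
# Node centrality (strength, closeness, betweenness, expected influence) and
# the four bridge-centrality indices for the anxiety/depression/DER
# partition, max-scaled and ordered by expected influence.

library(bridgenet)

out <- "results/study"
W_df <- read.csv(file.path(out, "weight_matrix.csv"), check.names = FALSE)
nodes <- read.csv(file.path(out, "nodes.csv"))
W <- as.matrix(W_df[, -1])
rownames(W) <- W_df$node
net <- ggm_network(W, nodes$community[match(colnames(W), nodes$node)])

cent <- scale_relative_to_max(suppressWarnings(node_centrality(net)))
cent <- cent[order(-cent$expected_influence_scaled), ]
write.csv(cent, file.path(out, "centrality.csv"), row.names = FALSE)

bridge <- scale_relative_to_max(suppressWarnings(bridge_centrality(net)))
bridge <- bridge[order(-bridge$bridge_expected_influence_scaled), ]
write.csv(bridge, file.path(out, "bridge.csv"), row.names = FALSE)

cat("most central nodes (by scaled expected influence):\n")
print(head(cent[, c("node", "community", "strength_scaled",
                    "expected_influence_scaled")], 5), row.names = FALSE)
cat("strongest bridge nodes (by bridge strength):\n")
b2 <- bridge[order(-bridge$bridge_strength), ]
print(head(b2[, c("node", "community", "bridge_strength")], 5),
      row.names = FALSE)
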