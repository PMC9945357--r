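#!/usr/bin/env Rscript
# The two node-placement schemes: a deterministic grouped-circle layout and
# a non-metric MDS embedding in which distance reflects association
# strength.

library(bridgenet)

out <- "results/study"
W_df <- read.csv(file.path(out, "weight_matrix.csv"), check.names = FALSE)
nodes <- read.csv(file.path(out, "nodes.csv"))
W <- as.matrix(W_df[, -1]); rownames(W) <- W_df$node
net <- ggm_network(W, nodes$community[match(colnames(W), nodes$node)])

circ <- circular_group_layout(net)
write.csv(cbind(circ$coords, layout_kind = circ$layout_kind),
          file.path(out, "layout_circle.csv"), row.names = FALSE)

mds <- mds_layout(net, seed = 20240209, n_init = 10)
write.csv(cbind(mds$coords, layout_kind = mds$layout_kind),
          file.path(out, "layout_mds.csv"), row.names = FALSE)
jsonlite::write_json(
  list(stress1 = mds$stress1, iterations = mds$iterations,
       start_used = mds$start_used, dissimilarity = mds$dissimilarity),
  file.path(out, "mds_meta.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("MDS converged in %d iterations (start %d), stress-1 = %.4f\n",
            mds$iterations, mds$start_used, mds$stress1))
# which communities sit closest together in the embedding?
xy <- as.matrix(mds$coords[, c("x", "y")])
cent <- aggregate(xy, list(community = net$nodes$community), mean)
cat("community centroids in the MDS plane:\n")
print(cent, row.names = FALSE)
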