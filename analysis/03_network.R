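#!/usr/bin/env Rscript
# Estimate the regularized partial-correlation network (graphical lasso over
# a 100-point penalty path, EBIC selection with gamma = 0.5) and compare the
# recovered edges with the simulated ground truth.

library(bridgenet)

out <- "results/study"
scores_df <- read.csv(file.path(out, "node_scores.csv"), check.names = FALSE)
nodes <- read.csv(file.path(out, "nodes.csv"))
X <- as.matrix(scores_df[, -1])
scores <- node_score_matrix(X, nodes$community[match(colnames(X), nodes$node)])

net <- estimate_network(scores)
el <- bridgenet:::edge_list(net)
write.csv(el, file.path(out, "edge_list.csv"), row.names = FALSE)
write.csv(data.frame(node = rownames(net$weights), net$weights,
                     check.names = FALSE),
          file.path(out, "weight_matrix.csv"), row.names = FALSE)
write.csv(net$path, file.path(out, "path.csv"), row.names = FALSE)
write_graphml(net, file.path(out, "network.graphml"))

cat(sprintf("selected lambda = %.4f; %d of 190 edges nonzero (%.2f%% set to zero)\n",
            net$lambda_selected, nrow(el), 100 * net$sparsity))
cat("strongest edges:\n")
print(head(el, 5), row.names = FALSE)

truth_w <- read.csv(file.path(out, "true_weight_matrix.csv"),
                    check.names = FALSE)
truth <- list(partials = as.matrix(truth_w[, -1]),
              adjacency = as.matrix(truth_w[, -1]) != 0)
class(truth) <- "ground_truth"
rec <- recovery_metrics(net, truth)
cat(sprintf("recovery vs truth: sensitivity %.2f, specificity %.2f, weight r %.2f\n",
            rec$sensitivity, rec$specificity, rec$weight_correlation))
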