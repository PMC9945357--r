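# bridgenet

Regularized partial-correlation networks, bridge centrality and
case-dropping stability for questionnaire data.

## What this is for

In comorbidity research, anxiety symptoms, depression symptoms and
emotion-regulation difficulties are increasingly analysed as a *network*:
nodes are individual symptoms (here the 14 items of the Hospital Anxiety
and Depression Scale, scored 0–3) and component scores (the 6 subscales of
the 36-item Difficulties in Emotion Regulation Scale), and edges are
conditional associations. bridgenet implements that full analysis as a
tested R pipeline:

- **Scoring** — editable YAML instrument definitions; reverse-corrected
  item and subscale scoring into a participants × 20 node matrix;
  group descriptives.
- **Estimation** — Gaussian graphical model via graphical lasso (blockwise
  coordinate descent, compiled) over a 100-point penalty path with
  extended-BIC selection; edges are regularized partial correlations
  `w_ij = -k_ij / sqrt(k_ii k_jj)`.
- **Centrality** — strength, closeness, betweenness (fractional credit on
  tied shortest paths, edge length `1/|w|`), expected influence; and the
  four **bridge** variants restricted to cross-community connections, for
  the anxiety / depression / emotion-regulation partition.
- **Stability** — case-dropping bootstrap: re-estimate the network on
  subsamples, correlate subsample centralities with the full-sample ones,
  and summarize with the CS coefficient (largest drop proportion keeping
  correlation ≥ 0.7 in ≥ 95% of replicates).
- **Layouts** — deterministic grouped-circle placement and non-metric
  (ordinal) MDS by majorization, with Kruskal stress-1 reported.
- **Synthetic cohorts** — a generator with a known sparse
  partial-correlation ground truth (20 nodes in communities 7/7/6,
  designated bridge edges, Likert discretization), so recovery can be
  scored when no raw data can be shared.

## Worked example

The `analysis/` scripts run the whole study-scale workflow on a simulated
cohort (n = 209, seed 20240209) and narrate what they find:

```sh
Rscript analysis/01_simulate.R   # cohort + ground-truth network
Rscript analysis/02_score.R      # item scoring + descriptives
Rscript analysis/03_network.R    # EBIC-glasso estimation
Rscript analysis/04_centrality.R # centrality + bridge indices
Rscript analysis/05_layouts.R    # circle + MDS coordinates
Rscript analysis/06_stability.R  # case-dropping bootstrap (B = 250)
```

Output of the estimation step:

```
selected lambda = 0.1319; 36 of 190 edges nonzero (81.05% set to zero)
strongest edges:
 node_i node_j     weight
    Rlx    Chr  0.2385180
    Wrr    Chr  0.2271148
    Wrr    Rst  0.2207782
    IMP    CLR  0.2128887
    Enj    CLR -0.2102266
recovery vs truth: sensitivity 0.85, specificity 0.92, weight r 0.82
```

The penalty chosen by EBIC keeps 36 of the 190 possible edges; the two
strongest run between the anxiety and depression communities (Relax–Cheer,
Worry–Cheer), and comparing with the generator's ground truth shows 85% of
true edges recovered at 92% specificity. The bridge table then ranks
exactly the nodes carrying the planted cross-community edges at the top:

```
strongest bridge nodes (by bridge strength):
 node  community bridge_strength
  Chr depression       0.5795417
  Wrr    anxiety       0.4403166
  STR        DER       0.3188911
  CLR        DER       0.3162375
  Rlx    anxiety       0.3012294
```

and the stability step reports honestly modest values for a 209-person
sample:

```
CS coefficients (max drop proportion keeping r >= 0.7 in >= 95% of runs):
          strength          closeness        betweenness expected_influence
              0.10               0.05                 NA               0.10
```

(NA: at deep drop proportions every refit of this sparse network had
constant betweenness, so its CS is undefined rather than zero.)

The same machinery is available programmatically:

```r
library(bridgenet)
cfg    <- synthetic_config(seed = 1)          # 7/7/6 nodes, n = 209
truth  <- generate_true_network(cfg)
scores <- sample_responses(truth)
net    <- estimate_network(scores)            # EBIC-glasso, gamma = 0.5
node_centrality(net); bridge_centrality(net)
cs_coefficient(case_drop_bootstrap(scores, B = 100, seed = 2))
```

Or end to end with every artifact written to disk:
`run_pipeline(list(seed = 1, synthetic = list(seed = 42)), "out/")`.

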