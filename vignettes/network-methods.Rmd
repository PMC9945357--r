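---
title: "Estimating and probing symptom networks with bridgenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and probing symptom networks with bridgenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgenet)
```

## The model

bridgenet analyses questionnaire data as a *symptom network*: a Gaussian
graphical model (GGM) over p = 20 node variables — the 14 items of the
Hospital Anxiety and Depression Scale (7 anxiety, 7 depression symptoms,
each scored 0–3) and the 6 subscale sums of the 36-item Difficulties in
Emotion Regulation Scale (Nonacceptance, Goals, Impulse, Awareness,
Strategies, Clarity). In a GGM the edge between nodes i and j is their
partial correlation

$$ w_{ij} = -\frac{k_{ij}}{\sqrt{k_{ii}\,k_{jj}}}, $$

where $K = \Sigma^{-1}$ is the precision matrix: an absent edge means the
two variables are conditionally independent given all other nodes. With 20
nodes there are 190 pairwise parameters to estimate from a couple of
hundred participants, so the precision matrix is estimated by the
*graphical lasso* — penalized maximum likelihood

$$ \hat K = \arg\max_{K \succ 0} \;\log\det K - \mathrm{tr}(SK)
   - \lambda \sum_{i \neq j} |k_{ij}| $$

with S the sample correlation matrix of the node scores. The penalty is
applied to off-diagonal entries only; this is the convention of the
psychometric-network tradition and gives the clean full-shrinkage limit
$\hat K = \mathrm{diag}(1/s_{ii})$ once $\lambda \ge \max_{i\ne j}|s_{ij}|$.
The solver is blockwise coordinate descent (compiled via Rcpp), sweeping
until the working covariance changes by less than `tol` (default 1e-6, at
most 1000 sweeps); the inner lasso subproblems run 100 times tighter so the
unpenalized limit reproduces `solve(S)` to 1e-6. Off-diagonal zeros come
out of the soft-threshold exactly, so the edge set needs no post-hoc
thresholding.

The penalty is chosen by the extended Bayesian information criterion,

$$ \mathrm{EBIC}_\gamma(\hat K) = -2\,\ell(\hat K) + E \log n
   + 4 E \gamma \log p, \qquad
   \ell(K) = \tfrac{n}{2}\left(\log\det K - \mathrm{tr}(SK)\right), $$

with E the number of estimated edges, over a log-spaced descending path of
100 penalties from $\lambda_{\max} = \max_{i\ne j}|s_{ij}|$ down to
$0.01\,\lambda_{\max}$, warm-starting each fit from the previous one. Exact
EBIC ties go to the larger penalty (the sparser model). Defaults
$\gamma = 0.5$, 100 path points and ratio 0.01 are the community-standard
settings; all are exposed as arguments.

### Choices the data cannot make for us

* **Correlation input.** Node scores are ordinal (0–3) for the symptom
  nodes and quasi-continuous for the subscale sums. The default is the
  Pearson product-moment matrix, with `method = "spearman"` as a switch;
  polychoric correlations are out of scope.
* **Edge weights are partial correlations.** Throughout, edge weights are
  read as regularized partial correlations (the standard GGM estimand),
  not regression coefficients; both descriptions circulate informally for
  the same fitted object.
* **No relaxed refit.** The selected model's weights stay penalized; we do
  not refit the selected zero pattern without the penalty.

## Centrality and bridge centrality

Four node indices summarize a fitted network. With edge lengths defined as
$1/|w_{ij}|$ (strong associations are short):

* **strength** $= \sum_j |w_{ij}|$ and **expected influence**
  $= \sum_j w_{ij}$ — magnitude vs. signed connectedness;
* **closeness** $= 1/\sum_{j} d_{ij}$, the reciprocal summed shortest-path
  distance to the reachable peers (0 for an isolated node, with a warning
  when the network is disconnected);
* **betweenness**: the number of shortest paths between other node pairs
  passing through the node, with fractional credit shared among tied paths
  (Brandes accumulation; ties in path length are recognized to an absolute
  tolerance of 1e-10).

For a community partition (here anxiety / depression / emotion regulation),
the four **bridge** variants restrict each notion to a node's connections
toward *other* communities: bridge strength and bridge expected influence
sum only cross-community edges (absolute vs. signed — keeping the same
magnitude/direction split as the node-level pair), bridge closeness is the
reciprocal summed distance to all nodes of other communities (0, flagged,
if any is unreachable), and bridge betweenness counts shortest paths
between nodes of two different communities. This preserves the conservation
identity *bridge strength + within-community strength = strength*, which
the test suite asserts on every random graph it generates. Tables are
max-scaled (each index divided by its largest absolute value) and ordered
by scaled expected influence.

The shortest-path machinery (Dijkstra with path counting and
community-restricted Brandes accumulation) is implemented in the package
because the community-restricted accumulation is not available in general
graph libraries; plain distances and betweenness are cross-checked against
igraph and against exhaustive path enumeration on small random graphs.

## Case-dropping stability and the CS coefficient

How much does a centrality ranking depend on the particular sample? For
each drop proportion q on a grid (default 0.05–0.75 in steps of 0.05) and
each of B replicates (default 1000), the bootstrap draws
$\lceil (1-q)n \rceil$ participants *without replacement*, re-runs the full
correlation → glasso path → EBIC → centrality pipeline, and correlates each
subsample index vector with the full-sample one. The **CS coefficient** of
an index is the largest q such that at q *and every smaller grid
proportion* at least 95% of the defined correlations are ≥ 0.7. The
monotone-prefix reading makes CS unique even when the qualifying fraction
dips and recovers; subsampling (not resampling) matches the case-removal
design. Replicates whose refit fails or whose index vector is constant
(e.g. an empty network, where every strength is zero) are recorded as
undefined and dropped from the fraction's denominator with a warning; a
proportion where *all* replicates are undefined leaves that index's CS
undefined (an error from `cs_coefficient()`, reported as NA by the
pipeline).

At questionnaire scale this machinery re-estimates the network thousands of
times, which is why the glasso core is compiled: one full path fit on
209 × 20 data takes a few tens of milliseconds.

## Layouts

Two deterministic placements of the same network:

* **Grouped circle**: community centers equally spaced on a unit master
  circle starting at 90°, each community's nodes equally spaced on a
  sub-circle of radius 0.45, in given node order. Purely positional — node
  distances carry no meaning.
* **Non-metric MDS**: dissimilarities $\delta_{ij} = \max_{kl}|w_{kl}| -
  |w_{ij}|$ (pairs with no edge get the maximal dissimilarity; the
  max-subtraction keeps them finite, unlike a reciprocal transform), then
  2-D ordinal scaling by iterative majorization: monotone regression of
  configuration distances on the dissimilarity order (primary treatment of
  ties — tied dissimilarities may keep unequal fitted distances), disparity
  normalization, Guttman transform. The internally tracked normalized
  stress is non-increasing across iterations and the final configuration
  reports Kruskal's stress-1
  $\sqrt{\sum (d_{ij} - \hat d_{ij})^2 / \sum d_{ij}^2}$. The best of
  `n_init` starts is kept; the first start is the classical Torgerson
  solution (which also makes perfectly representable geometries converge
  immediately and deterministically), the rest are seeded random
  configurations. If every association magnitude is equal the
  dissimilarities are degenerate and the layout falls back to unit
  dissimilarities, i.e. regular-simplex geometry. Exactly coincident
  coordinates are perturbed by 1e-8 so no two nodes overlap.

## The synthetic-data generator

Participant-level questionnaire data of this kind can rarely be shared, so
every stage is exercised on simulated cohorts with a *known* network. The generator works directly in partial-correlation space:

1. draw a community-structured adjacency over the 7/7/6 node set
   (`p_within = 0.3` inside, `p_between = 0.03` across communities), and
   force four designated bridge edges (defaults STR–Wrr, STR–Slw, Rlx–Chr,
   Wrr–Chr, mirroring the regulation-to-symptom and anxiety–depression
   conduits such a study focuses on);
2. draw magnitudes uniformly in [0.15, 0.35] with a 20% chance of a
   negative sign (clinical symptom networks are predominantly positive);
3. shrink all off-diagonals by a common factor until the implied
   unit-diagonal precision matrix ($k_{ij} = -p_{ij}$) has smallest
   eigenvalue ≥ 0.05, and record the final true partials — parameterizing
   in partial space keeps the ground truth unit-compatible with the
   estimand;
4. sample n = 209 participants (the emulated cohort size) from the implied
   correlation matrix, discretizing symptom nodes to 4 Likert levels by
   equal-probability normal thresholds and leaving subscale-sum nodes
   continuous. An item-level mode expands nodes to raw questionnaire items
   (subscale factor + noise, loading 0.7, reverse-coded items stored
   uncorrected) purely to exercise the scoring stage end to end.

What the generator does *not* emulate: floor effects and skew of clinical
samples (equal-probability thresholds are the default; skewed thresholds
would be a straightforward extension), item-level local dependence, and the
demographic composition of any particular cohort. Passing recovery tests
therefore show that the estimator tracks the assumed data-generating model,
not that any specific empirical dataset would yield a particular network.

Two problem sizes recur in the tests and the acceptance script, chosen as
the smallest sizes at which the claims are statistically unambiguous:

* the **recovery benchmark** — the same design at n = 2000 with continuous
  node scores, where the EBIC-glasso should recover the truth nearly
  perfectly (sensitivity ≥ 0.7, specificity ≥ 0.9, weight correlation
  ≥ 0.8, strength-rank correlation ≥ 0.8) and centrality should be stable
  under case dropping (B = 100 over a 5-point grid);
* the **study-scale run** — n = 209 with Likert symptom nodes, which shows
  what the same machinery does at realistic power: visibly sparser
  estimates, and honest (often low or undefined) CS values. With effect
  sizes in the generator's range, EBIC at $\gamma = 0.5$ is conservative at
  n ≈ 200 and can select very sparse or even empty models on unlucky
  draws; this is a property of the selection criterion at that sample size,
  and the pipeline reports it rather than hiding it.

## Degenerate inputs and numerical policies

* Constant node-score columns abort correlation with the column named.
* An all-zero correlation off-diagonal collapses the penalty path to {0}
  with a warning.
* A single-community partition is a fatal error for bridge indices.
* An index that is identically zero max-scales to all zeros, with a
  warning.
* Group descriptives report SD as NA (not 0) for single-participant groups
  and warn when a grouping variable is entirely missing.
* All randomness is seed-explicit: ground truth, sampling, bootstrap and
  MDS starts each take (or derive, in the pipeline, from one master seed)
  their own recorded seed, and reruns are byte-identical.

## Known limitations

* Pearson (or Spearman) input correlations; no polychoric/nonparanormal
  option, no mixed graphical models, no directed structure.
* The stability module covers case-dropping centrality stability only —
  not edge-weight bootstrap CIs or pairwise difference tests.
* MDS is 2-D only, and ordinal ties use the primary approach; secondary
  (tie-preserving) monotone regression is not implemented.
* Community partitions are taken as given (instrument structure), never
  inferred.
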