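# pivcomm

Pivotal gene community detection in hard-thresholded co-expression networks.

## What it does, and for whom

Co-expression module discovery (WGCNA-style) tends to return modules far too
large to reason about biologically. `pivcomm` is for the analyst who already
has one module containing a target gene — a disease-associated receptor, a
transcription factor — and wants the small, tightly interlocked community of
genes around that target, together with evidence that the community is real
and not a thresholding artefact.

Starting from a gene × subject expression matrix restricted to the module,
the package:

1. builds the absolute-Pearson similarity network
   `s_ij = |cor(x_i, x_j)|` and binarises it at every threshold `t` of a
   grid (edge iff `s_ij ≥ t`);
2. profiles degree, betweenness, diameter and eccentricity across the grid
   and restricts the search to the threshold range where the non-monotonic
   properties peak;
3. partitions each thresholded graph with four community detection
   algorithms (fast greedy, Louvain, walktrap, infomap) and extracts the
   community containing the target;
4. scores each community with the **Pivotal Module Index**

       PMI = (k_tc · b_tc) / (D_tc · N_tc)

   — mean degree × mean betweenness over diameter × size, all on the
   community's induced subgraph — and picks the threshold maximising the
   cross-method average PMI, with subject-bootstrap 25th–75th percentile
   error bands and a weighted linear trend test flagging thresholds in
   significant excess;
5. corroborates the choice with betweenness-based Shannon entropy (bits per
   node, normalised betweenness as the probability mass), validates it with
   Dice-index concordance across methods and stability across the threshold
   neighbourhood, and quantifies the target's embeddedness against a
   random-community strength null plus a scaled-strength hub table.

A planted-block multivariate-normal generator (`planted_design()`,
`simulate_expression()`) produces synthetic modules with a known core
community so the whole pipeline is testable end to end.

## Worked example

```r
library(pivcomm)

sim <- simulate_expression(planted_design(), seed = 1)   # 85 genes x 199 subjects
fit <- pivotal_community(sim$expr, target = "TARGET",
                         grid = threshold_grid(0.30, 0.60, 0.05),
                         n_boot = 100, seed = 1)
summary(fit)
```

```
Pivotal community detection
  target gene:    TARGET
  grid:           0.3 .. 0.6 (7 thresholds)
  scan range:     0.4 .. 0.5 (topology-selected)
  best threshold: 0.45 (PMI argmax, entropy concurs)
  community:      32 genes (fast_greedy)

Method concordance at the best threshold (Dice vs fast_greedy):
       method size size_q25 size_q75  dice valid
1 fast_greedy   32     31.0       34 1.000  TRUE
2     louvain   32     28.8       31 0.906  TRUE
3    walktrap   33     30.0       34 0.892  TRUE
4     infomap   32     32.0       82 0.906  TRUE

Target strength per node:
                 set strength_per_node    sd
1      whole_network             0.413    NA
2 detected_community             0.505    NA
3        random_null             0.405 0.015

PMI linear trend: slope -9.516, intercept 4.921, reduced chi2 3.1
thresholds above the 95% band: 0.45
```

Reading the output: the topology profiles confined the search to thresholds
0.40–0.50; within that range the cross-method average PMI peaks at 0.45 and
the betweenness-entropy maximum lands on the same threshold. All four
detectors agree on essentially the same 32-gene community (Dice ≥ 0.89
against the fast-greedy reference), which recovers the 28-gene planted core
with Dice 0.87:

```r
dice(fit$community, sim$core)
#> [1] 0.8666667
```

and the target is markedly more embedded in the detected community (strength
per node 0.505) than in the whole module (0.413) or in random same-size
communities (0.405 ± 0.015). `plot(fit)` draws the four diagnostic panels;
`write_report(fit, "out/")` writes every table as TSV.

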