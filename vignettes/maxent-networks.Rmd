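---
title: "Maximum-entropy chains on gene networks: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maximum-entropy chains on gene networks: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcentropy)
library(dplyr)
```

## The model

A sample is modelled as a stationary Markov chain on a fixed gene-interaction
topology. Two inputs determine everything:

* a directed network $G$ over $n$ genes, with adjacency $A$ augmented so that
  $a_{ii} = 1$ for every gene;
* the sample's expression vector $x \ge 0$, normalised to the stationary
  distribution $\pi = x / \lVert x \rVert_{1}$.

Among all transition matrices $P$ supported on $A$ ($p_{ij} = 0$ wherever
$a_{ij} = 0$), row-stochastic ($\sum_j p_{ij} = 1$) and stationary at $\pi$
($\sum_i \pi_i p_{ij} = \pi_j$), we select the one whose *edge-flow*
distribution $f_{ij} = \pi_i p_{ij}$ has maximum entropy

$$\mathrm{MCE} = -\sum_{(i,j)} \pi_i p_{ij} \log (\pi_i p_{ij}).$$

This is the least-committal chain consistent with the observed expression and
the known topology. The optimality conditions factor the solution as
$p_{ij} = \alpha_i \beta_j a_{ij}$, and the two constraint families become an
alternating diagonal scaling,

$$\alpha_i \leftarrow \frac{1}{\sum_j a_{ij} \beta_j}, \qquad
  \beta_j \leftarrow \frac{\pi_j}{\sum_i \pi_i \alpha_i a_{ij}},$$

i.e. Sinkhorn scaling of the support matrix to flow marginals $(\pi, \pi)$.
`fit_transition_matrix()` runs this iteration and attaches *certificates*:
the maximum row-sum deviation and the maximum stationarity deviation of the
returned matrix. A fit is only called converged when both are below the
requested tolerance; nothing is taken on faith from the iteration count.

Two closed forms anchor the implementation: with self-loops only the unique
feasible chain is the identity and $\mathrm{MCE} = H(\pi)$; with complete
support the optimum is the i.i.d. chain $p_{ij} = \pi_j$ and
$\mathrm{MCE} = 2H(\pi)$. Both are verified to $10^{-8}$ in the test suite,
and an independent oracle (below) checks everything in between.

```{r closed-forms}
genes <- c("a", "b", "c")
pi <- setNames(c(0.2, 0.3, 0.5), genes)
loops <- add_self_loops(gene_network(
  tibble::tibble(from = genes, to = genes), genes = genes))
fit <- fit_transition_matrix(loops, pi)
c(mce = fit$mce, entropy_pi = -sum(pi * log(pi)))
```

## Why the fitted support should be symmetric

Feasible flows are circulations: flow can cross an edge only if a directed
cycle returns it. On an acyclic support plus self-loops the only feasible
chain is the identity — the gene at the end of the order can only recycle its
own mass, and by induction every off-diagonal flow is forced to zero. Such
boundary optima exist but are numerically unpleasant: the scaling approaches
them sublinearly, and the certificates reveal the stall honestly
(`converged = FALSE`).

Interaction databases rarely orient physical interactions meaningfully, so
the pipeline symmetrizes the topology by default (`symmetrize = TRUE` in
`mce_config()`, `symmetrize_network()` directly). Every edge then sits on a
2-cycle, the optimum is interior, and convergence is geometric — roughly 200
iterations for a 300-gene scale-free topology at tolerance $10^{-8}$. Users
with genuinely oriented regulatory networks can disable this, accepting that
edges on no cycle will carry no flow.

The default iteration cap (10 000) covers typical fits; heavy-tailed
expression occasionally produces a slow mode (a gene with tiny $\pi$) that
needs a few times more, so the packaged study configurations raise the cap
to 50 000. Raising the cap only ever sharpens the certificates.

## The independent oracle

`oracle_max_entropy()` solves the same optimisation by a different route, for
networks of at most 8 genes: edges on no directed cycle are fixed to zero; a
strictly feasible interior flow is constructed from the diagonal plus small
cycle circulations; the marginal constraints are eliminated with an SVD
null-space basis; and the entropy is maximised over the reduced coordinates
with `stats::constrOptim()` (log-barrier, analytic gradient). On random
strongly connected graphs the two routes agree to about $10^{-8}$ in both the
matrix and its entropy; the acceptance suite requires $10^{-4}$ / $10^{-5}$
over 50 graphs. "Connected" is taken as *strongly* connected here: weak
connectivity alone permits forced-zero edges, and agreement at those
tolerances presumes an interior optimum.

## Methylation: G0, G1 and the index $\rho$

Promoter hypermethylation silences transcription. The package operationalises
this as node deletion: per sample, beta values are classified with the
conventional thresholds (fully methylated $\ge 0.6$, unmethylated $\le 0.2$,
partial in between, both cut-offs inclusive), and the fully methylated genes
are removed from the network. The pruned topology is re-augmented with
self-loops, $\pi$ is renormalised over the survivors, and the chain is
*refitted from scratch* — G1 must itself solve the maximum-entropy program on
its own support; renormalising rows of the G0 matrix would not satisfy
stationarity. Genes with a missing beta value are retained (absence of
evidence of methylation) and reported per sample.

Each gene's share of the total entropy is its Markov flow entropy
$\mathrm{MFE}(i) = -\sum_j \pi_i p_{ij} \log(\pi_i p_{ij})$, computed over
the gene's outgoing flows; the shares partition the MCE exactly, which the
tests check to $10^{-10}$. The formula is implemented over out-edges as
written; because a gene's *incoming* flows are the natural reading of "how
much the rest of the network influences it", an in-flow variant
(`direction = "in"`, attributing each flow to its target) is provided and
partitions the MCE equally. The network methylation index contrasts the two
fits,

$$\rho(i) = \frac{\mathrm{MFE}_1(i) - \mathrm{MFE}_0(i)}{\mathrm{MFE}_0(i)},$$

negative when the methylation of other genes suppresses flow through gene
$i$, positive when it concentrates flow there. $\rho$ is `NA` where the gene
itself was pruned (or carried no G0 flow); `absence_census()` counts those
absences per gene across samples — recurrent absence marks recurrently
silenced genes.

## Ranking and the stable core

Genes are ranked by weighted PageRank on the fitted chain. The classical
weighted formula divides each source's contribution by its in-degree; applied
to a row-stochastic weight matrix that normalisation is redundant and breaks
mass conservation, so the default mode (`row_stochastic`) iterates
$PR(v) = (1-d)/N + d \sum_u w_{uv} PR(u)$ with the transition probabilities
as weights, and the classical rule is retained as `as_printed` for
comparison. The damping factor defaults to 0.85.

Scores are clustered per sample with one-dimensional k-means (k = 10 by
default, k-means++ seeding, 10 restarts, ids canonicalised by ascending
cluster mean so "cluster 10" always means the top scores). The cluster-count
entropy curve over k = 5–15 (`cluster_entropy_curve()`) is the diagnostic
for the choice of k; the entropy used is that of the cluster-size
distribution, the unambiguous reading of "average entropy" for assignments.

For a candidate panel (driver genes, at most 200), every 3-subset
co-clustered in a sample counts one co-occurrence. The top `top_n` triples by
count — ties at the boundary broken lexicographically, so the cut is
deterministic — are flattened into a gene list for G0 and for G1, and the
intersection is the *core*: genes ranked highly and stably whether or not
methylated genes are present. The default `top_n = 100` fits panels of
several hundred candidates; for small panels it should scale down
proportionally (the packaged 30-gene recovery study uses 20), since a cut
far larger than the number of signal triples necessarily admits noise.
Bridge genes are non-core nodes adjacent (ignoring direction) to at least
two distinct core genes in the core subnetwork.

## What the synthetic data emulate — and what they do not

`simulate_study()` generates the full input set with known ground truth:

* **Topology**: directed preferential attachment (`simulate_network()`,
  growth orientation new → target, attachment kernel degree + 1), giving a
  power-law degree tail with exponent near 3, like curated interactomes.
* **Planted module**: the module is wired as a clique attached to the
  highest-degree background gene — its shared hub regulator and designated
  connector — and expressed as a tightly co-regulated amplified program: a
  shared per-sample level of `effect = 10` times the background median with
  within-module log-sd 0.05. Both halves of this design matter. Piloting the
  generator showed that expression co-ranking alone does not co-*cluster*
  the module: one-dimensional k-means resolves the heavy upper tail of
  PageRank scores finely, and module genes in different network positions
  acquire score spreads wider than the tail clusters. Interchangeable
  network positions plus tight co-expression give the module a compact score
  clump, which is exactly what "a co-regulated functional module" means
  physically.
* **Methylation**: beta values from the mixture
  $0.45\,\mathrm{Beta}(3,19) + 0.45\,\mathrm{Beta}(19,3) +
  0.10\,\mathrm{U}(0,1)$, placing the component modes exactly at 0.1 and
  0.9 as on methylation arrays. About half of all genes are fully methylated
  in any sample, so G1 prunes aggressively and background candidates churn
  in and out of G1 — while the planted module is drawn unmethylated (it *is*
  the methylation-stable core the method is built to find).
* **Candidates**: the module plus random background genes (30 total by
  default), the hub excluded.

Study conditions for the recovery benchmark: 300 genes, 20 samples, module
of 6 among 30 candidates, ten generator seeds, recovered core compared to
truth by Jaccard overlap (pass at $\ge 0.8$ in at least 8 of 10 seeds; in
the packaged runs all ten seeds recover the module exactly).

These data are deliberately stylised. Real expression has gene-specific
baselines, library-size effects and correlated noise; real methylation is
probe-level, regionally structured and correlated with expression in *cis*;
real driver modules are neither cliques nor uniformly co-expressed. Passing
the recovery benchmark shows the machinery — fit, pruning, ranking,
co-occurrence, intersection — is sound end to end; it does not certify
performance on cohort data.

## Numerical choices

* Natural logarithms throughout; all entropies in nats. $0 \log 0 := 0$.
* Scaling-fit defaults: tolerance $10^{-8}$ on the max of the two residuals,
  cap 10 000 iterations, $\beta^{(0)} = \mathbf{1}$. The fit is a pure
  function of (support, $\pi$, tolerance, $\beta^{(0)}$): reruns are
  bitwise identical.
* Values below $10^{-12}$ are reported as fitted, never pruned from the
  support: pruning would change the feasible set, and the residual
  certificates are the authority on fit quality.
* Zero-expression genes: dropped from the sample's network by default
  (the stationary vector must be strictly positive); a pseudocount mode
  exists for sensitivity analysis.
* PageRank: uniform start, renormalised every sweep, L1 stopping rule at
  $10^{-10}$.
* K-means: seeded restarts under a fixed master seed; per-sample seeds are
  derived from it, so pipeline runs are reproducible and manifests
  byte-identical.

## Known limitations

* The fitted chain inherits the support's quality: missing or spurious
  interactions reshape flows silently.
* Node deletion is a hard model of silencing; partial methylation (0.2–0.6)
  currently has no graded effect.
* The in-flow/out-flow duality of the flow entropy is resolved by exposing
  both; results for individual genes can differ between the two readings,
  and hub genes differ most.
* The oracle covers supports up to 8 genes; beyond that, correctness rests
  on the certificates and the closed-form anchors.
* Absolute MCE values scale with network size and density; compare samples
  only on a fixed topology.
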