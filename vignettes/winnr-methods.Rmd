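---
title: "Network gene prioritization, significance and expansion with winnr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network gene prioritization, significance and expansion with winnr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winnr)
```

## The problem

A typical network-medicine analysis starts from a set of *seed genes* —
differentially expressed genes, members of a curated pathway, or
literature-mined candidates — and a large collection of gene–gene
interactions, each carrying a confidence score $c(j,i) \in [0,1]$ (set to 1
when the source provides none). Three questions follow:

1. **Prioritization** — which of the seed genes are most central to the
   seeded network?
2. **Significance** — is a gene's priority a property of its specific wiring,
   or would any network with similar gross topology produce it?
3. **Expansion** — which non-seed genes interact with the seeded network so
   strongly that they were probably left out of the input list?

`winnr` answers all three with one propagation model, one family of
randomization null models, and a pair of hypergeometric filters.

## The ranking model

Each gene starts from an initial score built from its interactions under the
active mode,

$$S_0(i) = e^{2\ln w(i) - \ln I(i)} = \frac{w(i)^2}{I(i)},$$

where $w(i)$ is the summed confidence of the gene's interactions and $I(i)$
their count. For an unweighted network $S_0$ is exactly the node degree;
with weights it rewards genes whose interactions are both many and strong.
Genes with no interaction under the active mode get $S_0 = 0$, as do genes
that appear in the global interaction collection but not in the ranked
network.

Scores are then relaxed by a damped random-walk update,

$$S_t(i) = (1-\sigma)\,S_0(i) +
  \sigma \sum_{j} \frac{c(j,i)\,S_{t-1}(j)}{d(j)},$$

with damping $\sigma = 0.85$ (the conventional value for personalized
PageRank-style propagation). Iteration stops when the largest per-gene
change drops below $10^{-3}$ (default `tol`), or after 200 iterations. Two
numerical conventions are worth stating:

* **Convergence norm.** The stopping rule uses the maximum absolute
  per-gene change. It is the strictest of the usual choices and does not
  depend on network size; an aggregate (summed) criterion would loosen
  per-gene accuracy as networks grow.
* **Distribution denominator $d(j)$.** In the undirected case $d(j) = w(j)$
  and the update is the classical confidence-weighted walk. In directed
  modes the literal within-mode $w(j)$ is zero for every pathway source or
  sink, which would leave the update undefined on something as simple as a
  chain. We therefore define $d(j)$ as the total confidence of the edges
  along which $j$ actually distributes score in the active mode (its
  in-confidence for upstream ranking, its out-confidence for downstream),
  which reduces to $w(j)$ in the undirected case and keeps the operator
  well-defined everywhere. Genes with $d(j)=0$ simply contribute nothing.

Because the update is affine with a contraction factor $\sigma < 1$, the
iteration converges to the unique solution of
$(I - \sigma M)S = (1-\sigma)S_0$; the test suite checks the iterative path
against that dense solve directly. Two limiting identities make useful
sanity checks: for all-confidence-1 undirected networks the converged score
*equals* node degree (and convergence is immediate), and as
$\sigma \to 0$ the scores collapse to $S_0$.

Ranks are assigned in descending score order with average-rank ties, and
converted to percentiles ($\text{rank } 1 \mapsto 100$, last
$\mapsto 0$) so that pathways of different sizes can be pooled.

**Directed modes.** With `mode = "upstream"` score flows from regulated
genes to their regulators, so regulators that drive high-scoring targets
rise; `mode = "downstream"` is the mirror image. On the chain
$A \to B \to C$ upstream ranking scores $A$ highest and $C$ zero, and
conversely.

## Significance: topology-preserving nulls

The observed converged score is compared to its distribution over
randomized networks. Five schemes are implemented, all of which keep the
node set and resample edge weights from the original empirical weight
distribution (rewiring algorithms produce unweighted topologies):

* **degree-preserving** (default): repeated double-edge swaps,
  $10\,|E|$ attempts, so every gene keeps its exact degree;
* **modularity-preserving**: a community partition is fixed once (greedy
  modularity maximization) and swaps are restricted to edge pairs joining
  the same pair of communities — this preserves every degree *and* every
  community-pair edge count, hence Newman's $Q$ of the fixed partition
  exactly, while still shuffling partners. The construction is ours: the
  constraint "same modularity" does not by itself prescribe an algorithm,
  and the restricted-swap scheme is the weakest constraint we found that
  makes $Q$ invariant exactly rather than approximately;
* **total rewiring**: every edge's endpoints are redrawn uniformly
  (self-loops and duplicates rejected) — only $|E|$ survives;
* **add / remove 5%**: $\max(1, \mathrm{round}(0.05\,|E|))$ edges are added
  between non-adjacent pairs, or deleted.

For each gene a normal is fitted to its null scores by the sample mean and
standard deviation ($1{,}000$ replicates by default), and the ranking
p-value integrates the tail on the side of the observation:

$$p_r(i) = \begin{cases}
  \Phi\!\left(\frac{S(i)-\mu(i)}{\sigma(i)}\right) & S(i) < \mu(i)\\[2pt]
  1-\Phi\!\left(\frac{S(i)-\mu(i)}{\sigma(i)}\right) & S(i) > \mu(i),
\end{cases}$$

with $p_r = 0.5$ at the mean, and the degenerate $\sigma(i)=0$ null giving
1 when the observation equals the mean and 0 otherwise. As printed this is
a single-tail quantity bounded by $0.5$; `double_tail = TRUE` doubles it
into the conventional two-sided p-value. The default keeps the printed
form, but note that *calibration* statements only hold for the doubled
version: under the null itself, a rule "single tail $< 0.05$" fires for
about 10% of draws (either tail can be small), while the doubled p-value
rejects at the nominal 5%. The package's own calibration check therefore
uses the doubled form.

Whether per-gene null scores are close enough to normal for this fit is
itself tested with a chi-square goodness-of-fit statistic: 10
equal-probability bins under the fitted normal, adjacent bins pooled until
every expected count reaches 5, $df = \text{bins} - 3$. On scale-free
fixtures, degree-preserving randomization yields markedly smaller per-gene
chi-square statistics than total rewiring — preserving a gene's degree
leaves its null score a sum of a fixed number of resampled weights (hence
near-normal), while total rewiring makes the degree itself a skewed random
variable.

**Noise robustness.** To ask whether significance buys stability, the
network is spiked with a fraction of spurious interactions, re-ranked, and
each gene's rank shift recorded ($\geq 10$ positions counts as a change,
configurable). The assay reports the change probability separately for
genes with $p_r < 0.05$ and $p_r \geq 0.05$. Two conditions matter for
this comparison to be informative, and both are part of the assay's study
design here: confidence weights must actually vary (we use the full
$[0,1]$ weight range for this experiment — with near-constant weights a
degree-preserving null makes significance pure noise, uncorrelated with
rank stability), and gene–replicate events are pooled across several
networks, mirroring the pooling of many pathways in comparable analyses;
on a single 100-node fixture the handful of significant genes makes the
two empirical rates too noisy to order reliably.

## Expansion: two hypergeometric filters and a score

Candidates are the genes of the global collection adjacent to at least one
ranked gene. Interactions are counted without regard to direction
throughout. Each candidate $j$ with $n$ distinct neighbours, $k$ of them
ranked, faces two over-representation tests:

* **Test 1 (against the universe).** Could $k$ ranked neighbours out of
  $n$ arise by drawing the candidate's partners uniformly from the
  $N = |V| - 1$ other genes, $K$ of which are ranked?
  $p_{1e} = P[X \geq k]$ for hypergeometric $X$.
* **Test 2 (against a degree-matched ranked gene).** The reference $g^*$
  is the ranked gene with the closest degree (ties: larger degree, then
  lexicographic). When $\deg(j) \leq \deg(g^*)$,
  $p_{2e} = P[X \geq k]$ with $N = \deg(g^*)$, $K$ the reference's own
  ranked-neighbour count, $n = \deg(j)$. When the candidate is the larger,
  the parameterization is swapped (the candidate becomes the universe,
  its seed links the marked set, the reference degree the draw count) and
  the complementary form $1 - P[X \leq k-1]$ is used, clipped to $[0,1]$.
  A count beyond $\min(n, K)$ is impossible under the reference and is
  treated as tail mass 0. The exact parameter meanings of this pair of
  tests admit alternatives; both are isolated in `expansion_test1()` /
  `expansion_test2()` so a different convention can be swapped in without
  touching the loop.

A candidate must pass **both** tests at $\alpha = 0.05$
($p_e = \max(p_{1e}, p_{2e})$ is recorded). Among the passers, the one
with the highest expansion score

$$e(i) = \sum_{j \in \text{ranked neighbours}}
  \frac{c(i,j)\,S(j)}{W(j)}$$

is added — $W(j)$ being the gene's *global* interaction confidence total,
deliberately different from the within-network $w(j)$ of the propagation
step, so that a seed whose interactions mostly lie outside the ranked
network passes on proportionally less of its score. Ties break by smaller
$p_e$, then lexicographically. The ranked set is re-ranked on its induced
subnetwork (including edges among previously added genes) and the loop
repeats; it is fully deterministic.

## Evaluation procedures

* `precision_recall_f1()`: retrieval metrics of a predicted expansion set
  against a reference update set; recall divides by $|U|$ (the natural
  reading — the printed source formula would duplicate precision).
* `bfs_layers()`: strongly connected components are collapsed, condensed
  sources form layer 1, and breadth-first distance from the nearest source
  sets the layer — upstream regulators land in low layers, effectors deep.
* `percentile_by_layer()` pools percentiles across pathways per layer.
* `baseline_rankers()`: PageRank (damping 0.85), degree, normalized
  betweenness (unweighted paths — confidences are similarities, not
  costs), eigenvector centrality and the local clustering coefficient.
* `pathway_levels()`: the five-step spine-and-offset procedure for a
  directed pathway-to-pathway network — the longest shortest path anchors
  levels $1..n$, remaining pathways get distance-offset levels (upstream
  offsets subtract), multiple assignments average, and the offset pass
  repeats; the spine tie-break is lexicographic (the procedure needs *a*
  deterministic rule; any fixed one gives equivalent level geometry), and
  disconnected remainders are levelled recursively on their own.
* `bin_level_correlation()`: nested top-$2^x$ gene bins, each bin's
  *add-on* enriched pathways (those not hit by any smaller bin), and the
  Pearson correlation of add-on pathway level against bin exponent.

## Synthetic fixtures and what they do (not) show

`make_scale_free_weighted()` grows preferential-attachment networks
(exactly $(n-m)m$ edges) with confidences drawn from a symmetric beta on
$[\text{min\_weight}, 1]$; the default floor 0.75 mimics a
high-confidence-filtered interactome, while the significance/noise
experiments use the full range (floor 0), emulating an unfiltered
collection. `plant_expansion_module()` wires a dense module (density 0.7
by default — the internal connectivity of a well-curated pathway) into a
background and withholds some members as retrieval ground truth.
`make_layered_dag()` builds layered regulatory DAGs whose construction
layers `bfs_layers()` recovers exactly; `make_regular_graph()` provides
the degenerate symmetric test bed. All generators are pure functions of
their seed.

These fixtures reproduce the *mechanisms* — scale-free degree structure,
planted enrichment, layered direction — but not the curated texture of
real interactomes: no protein families (locally dense cliques), no
annotation bias, no correlated confidence errors. Passing the package's
checks on fixtures demonstrates internal correctness and qualitative
behaviour, not field performance on any particular database release.

## Problem sizes and numerical choices

The shipped checks use 20–100-node networks, nulls of 200–1,000
replicates, 100 noise replicates per fraction, 20 retrieval draws and
20-seed DAG ensembles — sizes chosen so the whole suite exercises every
code path at desk scale. Degenerate inputs follow fixed conventions
stated on each function: isolated genes score 0, $\sigma = 0$ nulls give
0/1 p-values, empty candidate pools end expansion, zero-variance inputs
raise errors rather than returning NaN. Duplicate edges merge keeping
maximum confidence; self-loops are dropped; identifiers are opaque and
case-sensitive (symbol mapping is a user concern).

## Known limitations

* Randomization schemes cover undirected networks; directed
  degree-preserving nulls (joint in/out-degree) are not implemented.
* Swap-based degree-preserving randomization is MCMC-style mixing, not
  exact uniform sampling over the degree-sequence ensemble; $10|E|$
  attempted swaps is a standard mixing heuristic, verified only
  empirically.
* The expansion filters' exact parameter conventions follow one concrete,
  self-consistent reading (documented above) among several plausible
  ones.
* The one-tailed default $p_r$ is bounded by 0.5 and intentionally not a
  calibrated two-sided p-value; use `double_tail = TRUE` when nominal
  error rates matter.
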