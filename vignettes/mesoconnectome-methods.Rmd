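---
title: "From regional transcriptomes to a multilayer mesoconnectome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From regional transcriptomes to a multilayer mesoconnectome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoconn)
```

This vignette explains the models behind each stage of the package, the
assumptions they make, the tunable parameters and their defaults, the
numerical choices taken where the method leaves room, and what the synthetic
validation does and does not establish about real data.

## The modeling idea

Bulk expression profiles measured per brain region are treated as the
micro-level substrate of macro-level connectivity: genes whose expression
profiles are distributed alike across regions are taken to be co-expressed,
co-expression communities are taken to be functional transcriptional units,
and regions whose community-restricted profiles are alike are taken to be
wired by that community. Stacking one region–region similarity graph per
community yields a node-aligned multiplex — the mesoconnectome — whose
mesoscale structure (centrality, coreness, modules) summarizes which regions
the transcriptome binds together. Everything downstream of the expression
matrix is assumption-light but scale-sensitive; each choice is spelled out
below.

## Variant-gene selection

For gene $i$ with expression $g_{i,n}$ over $N \ge 2$ regions we use the
log10 of the unbiased sample variance,
$s^2_i = \log_{10} \frac{\sum_n (g_{i,n}-\bar g_i)^2}{N-1}$.
Genes with zero variance are flagged non-finite, excluded from the sweep and
never classified variant. The threshold sweep runs on a grid from
$\lfloor \min s^2 \rfloor$ to $\lceil \max s^2 \rceil$ in steps of 0.1 (the
`step` parameter, in log10-variance units), counting genes strictly above
each threshold. First and second derivatives of this count curve are central
finite differences on the grid; the selected threshold maximizes the second
derivative among grid points within $10^{-9}$ of the global first-derivative
minimum, ties to the smallest threshold. On an idealized step curve this is
the foot of the drop; on smooth curves the tolerance set typically contains
one point and the rule is the first-derivative argmin. Anchoring the grid at
the data range (not zero) keeps the grid small without changing the
selection; "variant" uses strict `>`.

Two consequences worth knowing. The derivative rule reacts to the *steepest*
decline, so a broad low-variance population whose variance spread exceeds a
few grid steps yields a threshold inside that population rather than past
it; the annotation blacklist stage exists precisely to remove such
housekeeping-like transcripts before the sweep. And because the central
difference spans two grid cells, a drop concentrated between grid points $t$
and $t+0.1$ produces a first-derivative tie at both, which the
second-derivative rule resolves to $t+0.1$ — the foot, as intended.

## The divergence network

Profiles are normalized to distributions over regions, so only the *shape*
of a gene's regional usage matters, not its absolute level — appropriate
when between-gene scale differences reflect capture efficiency rather than
biology, and deliberate: divergence is scale-invariant. The Jensen–Shannon
divergence with base-2 logarithms is symmetric, bounded in $[0,1]$ and zero
iff the profiles coincide; $0\log 0 = 0$.

The gene–gene divergence matrix is binarized by percentile of the
upper-triangle values (linear interpolation, integer grid 1–99), keeping
pairs *at or below* the cutoff. The percentile is chosen by the
maximum-entropy criterion on betweenness: for each candidate graph we
compute unweighted node betweenness and estimate the Shannon entropy
(natural log) of its distribution with 100 equal-width bins spanning the
betweenness range; a degenerate range (all values equal, e.g. a complete
graph where all betweenness is zero) has entropy 0. Over-sparse graphs
concentrate betweenness on a few bridges (low entropy), over-dense graphs
collapse it toward a single value (low entropy); the entropy peaks where the
mesoscale structure is richest. We estimate the entropy from the value
distribution (histogram) rather than from the sum-normalized betweenness
vector because the vector entropy is maximized by *any* near-uniform
betweenness profile — in particular by nearly complete graphs — and
therefore increases monotonically toward the top percentile instead of
peaking at intermediate density. 100 bins gives percent-level resolution of
the betweenness range; the count only matters up to the usual
coarse-graining trade-off.

A stability caveat: on graphs of a few hundred nodes the entropy-percentile
curve is jagged, and its argmax can occasionally land in the dense regime,
where modularity's resolution limit then merges communities. The curve
smooths out as the network grows (the regime the method is intended for,
thousands of genes); on small inputs we recommend inspecting
`autoplot(betweenness_entropy_sweep(d))` and, if needed, overriding the
percentile explicitly (`edge_percentile` in the pipeline config). After
thresholding, the graph is strictly unweighted and zero-degree nodes are
removed.

The single-layer metric panel (degree, betweenness, closeness, eigenvector
centrality, degree assortativity and the mean-neighbor-degree curve) uses
the standard estimators; on disconnected graphs eigenvector centrality is
reported for the largest component with a warning, and assortativity of a
regular graph is NaN.

## Gene communities

Newman's leading-eigenvector method maximizes
$Q = \frac{1}{2m}\sum_{ij} \left(A_{ij} - \frac{k_ik_j}{2m}\right)\delta(g_i,g_j)$
by recursive spectral bisection: each group is split by the sign pattern of
the leading eigenvector of its generalized modularity matrix
$B^{(g)}_{ij} = B_{ij} - \delta_{ij}\sum_{k \in g} B_{ik}$, followed by a
greedy single-node fine-tuning pass (flips that increase $s^\top B^{(g)} s$,
never emptying a side), and a branch stops when the leading eigenvalue is
$\le 10^{-8}$ or the split does not increase $Q$. The leading eigenpair
comes from shifted power iteration started at a seeded random vector — the
explicit seed is the only source of run-to-run variability, which is why
repeated runs on rigid fixtures are bit-stable while near-degenerate spectra
can genuinely vary across seeds. Disconnected graphs are processed per
component. Reported $Q$ is always re-evaluated directly from the final
labels.

Size rules follow the workflow's defaults: communities under
`min_size = 10` genes are dissolved to an `"unassigned"` label (excluded
from all downstream layers), and communities over `max_size = 150` are
re-submitted to the detector on their induced subgraph, keeping a split only
if it produces at least two sub-communities of size $\ge$ `min_size` with
positive subgraph modularity, recursively until stable. Note that a large
Erdős–Rényi-like community *will* be split by this rule — random graphs have
genuinely positive spurious modularity — so "left intact" is guaranteed only
for truly indivisible structures such as cliques.

Stability is summarized over `runs = 30` seeded repetitions (seeds
`base_seed … base_seed + runs − 1`): the modularity sample, plus per-gene
agreement with the majority assignment after greedy best-Jaccard label
matching against the highest-$Q$ run. Significance uses `n_null = 30`
$G(n,m)$ null graphs — exact edge-count matching, so the null shares the
density the detector saw — each processed by the same community stage, and a
one-way ANOVA (equal-variance F test) between observed and null modularity
samples. A single comparison is made, so no multiplicity correction applies.

## The multiplex mesoconnectome

For each retained community, a region's profile is the community-restricted
expression vector at that region, normalized; layers are the region–region
JSD matrices. One cutoff binarizes all layers: the mode of the pooled
off-diagonal divergences, located as the midpoint of the most populated bin
of a Freedman–Diaconis histogram (ties to the lowest bin; fewer than 10
pooled values is an error; an all-equal pool returns that value at
percentile 100). The mode value is authoritative; its percentile rank is
reported alongside for comparability. Regions are coupled to their replicas
in every other layer with categorical weight `omega` (default 1.0).

Metrics on the multiplex:

* **degree** — total intra-layer degree across layers, couplings excluded;
* **PageRank** — power iteration on the supra-transition matrix
  (column-normalized intra-layer edges plus couplings; dangling node-layers
  teleport uniformly), damping `r = 0.85`, L1 tolerance $10^{-10}$; the
  stationary distribution over the $N\!\cdot\!L$ node-layers sums to one and
  is aggregated per region. The sequential per-layer warm start described
  for some implementations only affects the iteration path; the stationary
  solve converges to the same fixed point regardless of initialization,
  which is what we compute;
* **eigenvector centrality** — leading eigentensor of the supra-adjacency by
  power iteration with a +1 diagonal shift (a bipartite supra-structure has
  a matching negative eigenvalue that would otherwise make the iteration
  oscillate); per-region sums rescaled to unit maximum; disconnected
  supra-graphs are flagged, the scores reflecting the dominant component;
* **k-core** — iterative pruning on total intra-layer degree with whole-node
  removal across all layers; the coreness distribution reports
  $P_k(q) = n_k(q)/n_{k\text{-core}}$ among regions of coreness $\ge 1$.

## Brain modules

Multilayer Louvain greedily maximizes the Mucha-type quality
$Q = \frac{1}{2\mu}\sum_{ijsr}\left[\left(A_{ijs} - \gamma
\frac{k_{is}k_{js}}{2m_s}\right)\delta_{sr} + \delta_{ij}\,\omega\right]
\delta(g_{is}, g_{jr})$
with uniform interlayer coupling: seed-shuffled local moving of node-layers
followed by aggregation of modules into super-nodes (per-layer strength
bookkeeping survives aggregation), repeated until no gain above $10^{-12}$.
Edgeless layers contribute no null-model term. `gamma` and `omega` default
to 1; the reported supra-modularity is re-evaluated directly on the final
assignment, and per-layer projected modularities evaluate each layer's graph
under the labels its replicas carry (edgeless layers score 0 with a
warning). A region's consensus module is its majority label over layers,
ties to the lowest label. Module counts depend on `gamma`/`omega`; the
defaults are documented, not tuned to reproduce any particular count.

## The synthetic generator, and what passing tests mean

`simulate_expression()` emulates the structure the analysis assumes at desk
scale: default 600 genes × 60 regions, 4 communities, 3 region modules, 50%
background, gene-level log-normal noise `noise_sd = 0.1`. Community profiles
draw one level per region module from a Gamma(2, `profile_scale`)
distribution (positivity keeps JSD defined) with 10% multiplicative
within-module jitter (log-normal, sdlog 0.1); community genes multiply a
per-gene log-uniform base level (one decade) by their community profile and
noise; background genes share one flat level with small noise
(`background_sd = 0.02`), so their log-variances cluster tightly and the
derivative sweep sees a sharp, realistic drop. All draws derive from one
seed; identical seeds give bit-identical output.

Parameter-recovery results on this generator show that the chain of
implementations is faithful — thresholds land between planted populations,
the divergence network separates planted communities, detection recovers
them (NMI 1.0 at the default noise) and degrades monotonically as noise
grows. They do *not* show that real regional transcriptomes satisfy the
model: real background genes are not exactly flat, community profiles are
not piecewise-constant, and donor-to-donor variability is not simulated at
all.

One structural property deserves emphasis: because a community's
region-module level multiplies *every* gene of that community equally, and
JSD normalizes each region's profile, the planted region-module structure
cancels out of the community layers of the synthetic expression data — the
layers carry community membership but no module signal. Region-module
recovery is therefore validated on `simulate_multiplex()`, which plants the
modules directly in the layer topology (within/between edge probabilities
0.6/0.05 by default). On real data the analogous signal must come from
genes *not* sharing one common regional scaling, which the generator
deliberately does not model.

## Numerical and reproducibility choices

Problem sizes used by the test-suite and the acceptance script — 600 × 60
expression fixtures, 5 chain seeds, 60-region multiplexes over 10 seeds, 30
stability runs and 30 nulls in the pipeline defaults — were chosen once as
representative desk-scale conditions. Every stochastic step takes an
explicit integer seed; the RNG state is saved and restored around seeded
sections, so stages compose without interfering. Power iterations use
tolerance $10^{-10}$ with generous iteration caps and fail loudly rather
than return unconverged values. Percentiles use R's type-7 quantiles;
modularity evaluations include the $i=j$ null term (the standard
$\sum_c [m_c/m - (K_c/2m)^2]$ convention). All outputs are plain text (TSV,
GraphML, JSON), and the pipeline manifest records every numeric decision a
stage makes, so a run can be audited and reproduced exactly.

## Known limitations

* The entropy-argmax edge threshold is noisy on small graphs (see above);
  inspect the sweep on inputs below a few thousand genes.
* Modularity optimization inherits the resolution limit; small true
  communities inside dense graphs may be merged, which is why the oversized
  communities rule re-splits rather than trusting one global pass.
* The ANOVA on modularity samples treats runs as independent; seeded
  repetitions on rigid graphs can have zero variance, where the F statistic
  degenerates (handled, but the p-value is then nominal).
* No normalization, batch correction or donor integration is attempted; the
  expression matrix is taken as given.
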