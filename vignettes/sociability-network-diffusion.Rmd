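---
title: "Network diffusion for sociability gene prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network diffusion for sociability gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socionet)
```

## The problem

Gene lists assembled from comparative studies of social behavior — seed genes
implicated in sociability across species — are too sparse and too noisy to
interpret one gene at a time. The strategy implemented here embeds such a
list in the human protein interaction network and asks which genes, seeds or
not, sit in regions of the network that the seed signal concentrates on. The
output is a ranked candidate network of genes: the seeds' well-supported
neighborhood, from which novel disease-risk candidates (for example for
autism spectrum disorders) can be nominated.

## Building the interactome

Input is an edge table in the STRING `protein.links.full` dialect, one row
per ordered protein pair with per-channel evidence subscores on a 0–1000
scale. `recombine_links()` recomputes the combined score after dropping
channels (text mining by default, which is circular for literature-derived
seed lists): each included channel score $s$ is de-priored
$s' = \max(0, (s/1000 - p)/(1 - p))$ with prior $p = 0.041$, combined as
$c = 1 - \prod(1 - s')$, re-priored $t = c(1-p) + p$, and rescaled to 0–1000.
A single informative channel therefore round-trips to its own value, which
the synthetic benchmark exploits to make filtering exactly checkable.

`build_interactome()` maps protein to gene identifiers (dropping unmapped
records with a count), removes self-loops, collapses duplicate gene pairs to
their maximum score, and retains an edge when either

* its combined score is at least 700 (high confidence), or
* it lies in the top 3 medium-confidence edges
  ($400 \le s < 700$) of *either* endpoint, ranked by descending score with
  ties broken by lexicographic partner id.

The either-endpoint reading keeps weakly-connected genes attached through
their best few partners rather than orphaning them; the explicit tie-break
makes the graph a pure function of the input. The medium band is ranked
separately from the high-confidence set — folding high edges into the top-3
lists would make the union clause nearly redundant.

## Diffusion and the smoothing index

With $A$ the adjacency matrix (binary by default — the retention thresholds
already encode confidence; `weighting = "score"` uses $s/1000$) and $D$ the
degree matrix, diffusion runs on the symmetrically normalized
$W = D^{-1/2} A D^{-1/2}$ (isolated genes get zero rows by the $0/0 = 0$
convention; the spectral radius of $W$ is at most 1). The seed vector $x_0$
is 1 on seeds, 0 elsewhere, and the damped steady state is

$$x_s = (1-\alpha)\,(I - \alpha W)^{-1} x_0,$$

the closed form of a random walk with restart probability $1-\alpha$;
$\alpha = 0.7$ by default. Note the *damped* inverse: the undamped
$(I - W)^{-1}$ is singular on any connected component containing seeds
(there $W$ has a unit eigenvalue), so the damped form is the only solvable
reading and is the one implemented, via a sparse Cholesky factorization of
$I - \alpha W$. A truncated power series
$(1-\alpha)\sum_k \alpha^k W^k x_0$ is provided as an independent route; the
two agree to $10^{-8}$ on random graphs and both are exercised in the tests.

One conservation property is worth recording because the intuitive one is
false: plain mass $\sum_i x_s(i)$ can exceed $\sum_i x_0(i)$ (a seed attached
to a hub amplifies it), but degree-weighted mass is conserved exactly,
$\sum_i \sqrt{d_i}\, x_s(i) = \sum_i \sqrt{d_i}\, x_0(i)$, because
$D^{1/2}(I-\alpha W)^{-1}D^{-1/2} = (I - \alpha A D^{-1})^{-1}$ and
$AD^{-1}$ is column-stochastic. The tests assert the exact weighted law and
the plain-sum equality only on regular graphs, where the two coincide.

The smoothing index $S_i(\varepsilon) = x_s(i)/(x_0(i) + \varepsilon)$
de-emphasizes seeds with little network support: as $\varepsilon$ grows the
seed's own unit weight matters less relative to what the network returns to
it. `select_epsilon()` scans a grid and scores each $\varepsilon$ by how
many seeds among the top-ranked genes remain connected in the induced
top subgraph (smallest $\varepsilon$ on ties); $\varepsilon = 50$ is the
default operating point.

## Permutation statistics

`permutation_adjusted_index()` permutes the seed labels uniformly over all
network genes (seed count preserved; a degree-matched variant permuting
within degree deciles is available but off by default, matching the plain
scheme the index was designed with) and recomputes $S_i$ each time. The
p-value uses a pseudocount, $p_i = (1 + \#\{S_i^{perm} \ge S_i\})/(n_{perm}+1)$,
so it is never zero — necessary because the adjusted index
$\tilde S_i = -S_i \log_{10} p_i$ takes its logarithm. Ranking by
$\tilde S$ breaks ties by higher $x_s$, then gene id, so the ordering is
total and reproducible. All permutation draws flow from one stored RNG seed;
identical seeds give bit-identical results, and the per-permutation top
rankings are retained for the resampling statistic below.

## Extracting the top network

For every $r$ in an inclusive grid (default 50–500 by 10), the top-$r$ genes
by $\tilde S$ induce a candidate subnetwork scored on four criteria:

1. modularity of its multilevel community partition (0 when edgeless),
2. the number of member genes with $p_i < 0.01$,
3. a network-resampling p-value — the fraction of permutations whose own
   top-$r$ genes induce at least as many links as observed (with the same
   pseudocount), capturing whether the observed ranking concentrates edges,
4. upper-tail hypergeometric enrichment in a disease gene list against the
   interactome universe.

How to combine the four is genuinely open; the package uses equal-weight
rank aggregation (higher Q and $n_{sig}$, lower p-values are better; average
ranks on ties; composite = sum of ranks; smallest $r$ on a tied composite)
for transparency and scale-invariance, with configurable weights. The
resampling procedure is deliberately isolated in
`network_resampling_pvalue()` since it is the one extraction ingredient with
room for interpretation: the permuted-ranking link-count form used here is
the natural operationalization given the stored permutations.

## Cartography

Communities come from igraph's multilevel (Louvain) or fastgreedy
algorithms; the stochastic one is wrapped with a seed so partitions are
reproducible. For each gene, the within-community degree z-score
$z_i = (\kappa_i - \bar\kappa_{s})/\sigma_{\kappa_s}$ (statistics over the
gene's community including itself; $\sigma = 0$ gives $z = 0$; sample
standard deviation) and the participation coefficient
$P_i = 1 - \sum_s (k_{is}/k_i)^2$ classify genes into the seven classical
cartography roles: nonhubs ($z < 2.5$) split at $P \le 0.05, 0.62, 0.80$
into ultraperipheral/peripheral/connector/kinless (R1–R4), hubs at
$P \le 0.30, 0.75$ into provincial/connector/kinless hubs (R5–R7).
Boundary comparisons use $\le$ so every finite $(z, P)$ maps to exactly one
role; isolated genes are R1 with $z = P = 0$. All thresholds are arguments.

## Enrichment and meta-pathways

Over-representation uses the exact upper-tail hypergeometric (log-space via
`phyper`) with BH correction; pathways are size-filtered (3–200 genes,
computed after intersecting with the universe). The background universe
defaults to the interactome gene set, not the whole genome — genes that
cannot appear in a network should not inflate its enrichment. Pathways that
pass (at least 3 overlap genes, FDR < 0.05) form a pathway network with an
edge where the overlap coefficient $|A \cap B| / \min(|A|, |B|)$ exceeds a
threshold; the threshold is chosen from a 0.05–0.95 grid (step 0.05) as the
value maximizing fastgreedy modularity of the binarized graph, smallest on
ties, and meta-pathways are the communities at that threshold.

## Genomic context

Cytoband enrichment reuses the hypergeometric/BH machinery per band
(significance flagged at FDR < 0.25, a deliberately permissive screen for a
positional signal). Linkage neighbors pair a network gene with any target
gene on the same chromosome whose span lies within the window, measured
between closest span ends (0 when overlapping, boundary inclusive), with
genetic distance under the uniform 1 cM ≈ 1 Mb rule. Two window conventions
circulate for this kind of screen — a fixed 50 kb physical window, or 0.5 cM
(≈ 500 kb under the same conversion); they differ by an order of magnitude,
so the window is a required-visible parameter defaulting to 500 kb, and the
50 kb variant is one flag away. Loci are 1-based inclusive, with BED
(0-based half-open) converters. HAR annotation is pure set algebra over the
supplied lists.

## The synthetic benchmark

`generate_benchmark()` emits every input the pipeline reads — STRING-dialect
links (both orientations, a text-mining channel that must be excluded, and a
`combined_score` column that still includes it), an identifier mapping, seed
and annotation lists, a pathway GMT, a locus table, and the ground truth.
Its defaults are the validation conditions used throughout: 500 genes on a
Barabási–Albert background (m = 3; scale-free-like, closer to interactome
topology than an ER graph, which is retained for calibration), a planted
40-gene module wired at intra-module probability 0.25 against a much
sparser background, half the module genes plus ~3% of background genes as
seeds, a 30-gene disease list overlapping the module by 15, and half the
module genes clustered on one cytoband. Module edges draw scores from
[700, 1000]; background edges mix high and medium tranches ([400, 699]) so
the retention rules are actually exercised. `null_benchmark()` keeps the
marginals but plants nothing: seeds uniform, annotations independent — the
configuration under which permutation p-values must be uniform.

What the generator does *not* emulate: realistic degree distributions beyond
the BA shape, pathway hierarchies, correlated annotation biases, or linkage
disequilibrium structure. Passing the benchmark shows the machinery is
correct and calibrated, not that real interactome analyses are free of the
biases those features introduce.

## Numerical choices and problem sizes

Tolerances: solve-vs-series agreement $10^{-8}$; exact small-N agreement of
the hypergeometric with a brute-force enumeration oracle to $10^{-12}$;
symmetric-matrix checks at $10^{-12}$. Degenerate inputs have fixed
conventions rather than errors where a convention is defensible: edgeless
candidates score $Q = 0$ and resampling p = 1; an empty edge table yields an
empty interactome; isolated genes diffuse to 0.

The validation suite runs at deliberately modest sizes chosen to resolve the
properties being tested: the planted benchmark at 500 genes with 200
permutations (recall of the planted module ≥ 80%), density-monotonicity of
recall at three intra-module densities × five generator seeds with 100
permutations, and null calibration at 500 genes with 500 permutations
against a DKW band at level 0.05. These sizes are the package's own choice
of experiment; all scale up by changing the config.

## Limitations

The resampling criterion is one reasonable operationalization among several;
it is isolated so alternatives can be swapped in. Equal-weight rank
aggregation treats the four extraction criteria as exchangeable evidence,
which is a choice, not a theorem. Cartography on networks with many small
components yields small-community z-scores that are noisy by construction;
profiles can be restricted to the major component by subsetting the graph
first. The uniform cM↔bp conversion ignores real recombination-rate
variation by design.
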