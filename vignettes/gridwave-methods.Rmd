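---
title: "GridWave: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GridWave: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GridWave)
```

## The problem

Classical gene-set enrichment asks whether a pathway contains many
individually differentially expressed genes. That question misses a kind
of signal that metabolic networks produce naturally: *coordinated*
regulation of neighboring reactions (a whole branch shifting up or down
together) and *contrasting* regulation of adjacent reactions — a
switch-like pattern in which flux is redirected at a branch point, one
neighboring reaction up-regulated while the other is shut down. Each
individual gene may move too little to survive genome-wide multiple
testing, while the joint, spatially structured pattern is strong.

GridWave tests pathways for exactly these patterns in a two-group design
(in the motivating application: breast tumors with favorable vs
unfavorable prognosis). The analysis has four stages, each a module of
this package:

1. **Pathway model** — reactions are nodes; two reactions are adjacent
   when some metabolite is the product of one and the substrate of the
   other (in either direction). Pathways without any connected reaction
   carry no neighborhood information and are discarded. Reactions encoded
   by exactly the same non-empty gene set are merged into one node (their
   expression evidence is identical), with edges unioned.
2. **Grid embedding** — the reaction graph is placed on the smallest
   square lattice that holds it, minimizing the total Manhattan length of
   its edges, so that network neighbors become spatial neighbors.
3. **Wavelet features** — each sample's reaction-level expression is
   painted onto the grid and a multi-level 2x2 Haar cascade computes, for
   every 2x2 block, one smoothing coefficient (mean of means — a low-pass
   detector of coordinated regulation) and three contrast coefficients
   (difference combinations — high-pass detectors of switch-like
   regulation).
4. **Statistics** — every non-trivial feature is tested favorable vs
   unfavorable with a two-sided Wilcoxon rank-sum test; pathways are
   ranked by their best feature after Bonferroni correction, and reported
   together with per-reaction regulation counts.

## The embedding model

For a pathway graph $G = (V, E)$ with adjacency matrix $M$ and a square
grid $g$ of side $s$, the embedding minimizes

$$\min \sum_{a<b} M(a,b)\, d_{ab}$$

over injective assignments of nodes to grid cells, where $d_{ab}$ is the
Manhattan distance $|i_a - i_b| + |j_a - j_b|$ between the chosen cells.
In the integer-programming formulation the assignment is carried by
binary variables $x_{vij}$ (node $v$ on cell $(i,j)$), each node placed
exactly once, each cell used at most once, and $d_{ab}$ linearized by
four inequalities $d_{ab} \ge \pm A \pm B$ with $A = i_a - i_b$,
$B = j_a - j_b$. Distance variables are only needed for adjacent pairs:
non-edges contribute nothing to the objective, so dropping their
variables is a pure model reduction that cannot change the optimum.
Minimizing *total* edge length (not the longest edge, as VLSI placement
does) is deliberate: it penalizes every pair of separated neighbors.

No integer-programming library is part of this package's dependency
footprint; `embedExact()` is an authored exact branch-and-bound solver of
the same model. Nodes are placed one at a time in a connectivity-driven
order; a partial placement is pruned with an admissible bound (every
fully-unplaced edge costs at least 1; a node with placed neighbors costs
at least its best achievable distance sum over the free cells). Two
devices from the polyhedral treatment of the problem are kept, as they
change bounds but never the optimal value:

* **Motif cuts.** For an edge-induced subgraph $G' \subseteq G$ with
  least lattice contribution $lb(G')$, the inequality
  $\sum_{(u,v) \in E(G')} d_{uv} \ge lb(G')$ is valid. The right-hand
  sides depend only on the motif, so `motifLowerBound()` computes each
  once by exhaustive lattice optimization and caches it: stars
  ($lb(K_{1,k}) = k$ for $k \le 4$, then growing as only four unit
  neighbors exist), cliques up to 10 nodes, odd cycles $C_3$ ($lb = 4$)
  and $C_5$ ($lb = 6$; odd cycles cannot close at odd length on a
  bipartite lattice), and trees with maximum degree $\le 4$
  ($lb = |E|$, attained by paths). An edge-disjoint collection of
  detected motifs, plus 1 per uncovered edge, gives the root lower bound
  used for optimality proofs and the reported gap.
* **Symmetry breaking.** The grid's rotations and reflections map optima
  to optima, so the first placed node is restricted to a fundamental
  domain (the upper-left octant); every equivalence class of embeddings
  keeps at least one representative.

`embedBruteforce()` is the independent oracle: full enumeration of all
injective placements, feasible to 7 nodes. The test suite proves the
branch-and-bound exact on *every* connected graph with up to 6 nodes
(142 isomorphism classes), with and without cuts and symmetry breaking.
`embedHeuristic()` (simulated annealing over swap/relocate moves,
deterministic per seed) covers pathways too large for exact solving; the
pipeline switches to it above 9 nodes by default. Its `gap` slot reports
lower bound / incumbent, mirroring the convention of reporting average
optimality rather than demanding proofs everywhere. Ties among multiple
optimal embeddings are broken arbitrarily by the solver; downstream
results are therefore always reported together with the serialized
embedding that produced them.

**Grid side.** The default is $\lceil \sqrt{|V|} \rceil$, the smallest
grid that holds the graph — fewest variables, fewest empty cells. A
`gridSlack` flag adds one extra row/column for configurations where a
looser canvas is wanted; both options are exposed because the tradeoff
(compactness vs freedom to spread) is genuinely open.

## The wavelet cascade

A sample's reaction values are painted onto the embedded grid, zeros
elsewhere; an `occupied` mask remembers which cells carry a reaction at
all. Matrices with odd dimensions are extended with rows/columns of
zeros at the bottom/right so they tile into disjoint 2x2 blocks. Per
block $(a, b; c, d)$, with row means $m_u, m_l$ and row differences
$d_u, d_l$:

* $f_1 = (m_u + m_l)/2$ — mean of means (smoothing),
* $f_2 = m_u - m_l$ — difference of means,
* $f_3 = (d_u + d_l)/2$ — mean of differences,
* $f_4 = d_u - d_l$ — difference of differences.

All $f_1$ values form the next level's matrix (padded again if odd),
recursing until a single block remains. Only the smoothing coefficient
recurses; the contrast coefficients are features at their own level.
Means divide by 2 and differences are plain — not the orthonormal
$\sqrt2$ scaling — because the downstream Wilcoxon test is rank-based
and invariant to any fixed positive rescaling of a feature (asserted as
a test). The transform is exactly invertible (`reconstructBlock()`), and
exact linearity of the whole cascade is what lets `featureTable()`
assemble the feature map once as a linear operator from reaction
indicator images and apply it to all samples by one matrix product.

**Tiling offsets.** Disjoint 2x2 tilings see a pair of adjacent cells
together only if the block boundary does not fall between them. The
default (`offsetsMode = "all4"`) therefore repeats the cascade for the
four shift origins (0,0), (0,1), (1,0), (1,1) — all four possible 2x2
arrangements — so every pair of lattice neighbors shares a block in at
least one arrangement. `"single"` restricts to the aligned tiling for a
strictly disjoint feature set.

**Non-trivial features.** A feature enters testing only if its spatial
footprint contains at least one reaction-bearing cell (a structural
criterion via the occupied mask — unmeasured reactions sit at the
neutral log-ratio 0 but still count as structure) and its value varies
across samples (constant features are untestable by a rank test). This
operationalizes "non-trivial"; both criteria are deliberately
conservative.

One caveat worth stating: zero padding breaks translation invariance.
Shifting even a constant image changes individual coefficient values,
because shifted tilings pair constant cells with padding zeros. The
conservation properties (top smoothing coefficient = grand mean of the
padded image; all contrasts vanish on constants) hold per tiling, and
are tested on the aligned one.

## Statistics and ranking

Features are tested with two-sided Wilcoxon rank-sum tests: the exact
distribution for pooled sizes up to 20 without ties, otherwise the
normal approximation with mid-ranks and tie-corrected variance (no
continuity correction). The exact path is verified against full
enumeration of all rank assignments for every group-size split up to
$n_a + n_b = 8$.

The Bonferroni family defaults to *all* non-trivial features across all
pathways in the run — the most conservative, globally valid choice — a
per-pathway family is available by configuration. A pathway is reported
significant when its best feature survives correction at
$\alpha = 0.05$ **and** it has more than 3 (i.e. at least 4)
significantly differentially regulated reactions. That second filter
needs a per-reaction call the ranked table also reports: two-sided
Wilcoxon per reaction at uncorrected 0.05, direction by the sign of the
median difference (unfavorable minus favorable); unmeasured reactions
are always "unchanged". Reactions merged for identical gene sets count
once. Because the ambiguity cannot be resolved from first principles,
the output reports both the raw and the adjusted best-feature p-value.

Sample labels follow strict inequalities: favorable requires recurrence
time $t > 5$ years, unfavorable requires $t < 3$ years *with*
metastasis, and everything else — including the boundaries $t = 3$ and
$t = 5$ exactly — is discarded ("above" and "less than" are strict).
Gene-to-reaction aggregation defaults to the mean (median and max are
available); the mean is the symmetric, standard choice for log-ratio
data when the true isoenzyme weighting is unknown.

Two enrichment baselines are included for comparison, not as the method:
Fisher's exact test on the 2x2 table of pathway membership against
differential expression (DE defined by per-gene Wilcoxon at 0.05), and a
simplified permutation rank-enrichment score (weighted running-sum
statistic with a sample-label permutation null). A note on the latter:
with sample-label permutation the null preserves each gene's marginal
distribution, so pathologically extreme planted shifts (many SDs) keep
the planted genes extreme under permutation too and the null score
distribution widens; the minimal p-value is attained for strong but
moderate shifts. This is a property of label-permutation GSEA-type
statistics in general, not an implementation artifact.

## The synthetic-data generator

Real inputs (a 295-sample breast-cancer expression study; curated
pathway maps) cannot be bundled, so `simulationDesign()` defines the
study conditions the test suite and the acceptance analyses run under:

* 5 pathways of 6 reactions (random recursive spanning tree + 2 extra
  edges — connected, with cycles, the size regime where exact embedding
  is instant), 2 genes per reaction;
* 30 favorable vs 30 unfavorable samples, i.i.d. Normal log-ratio noise
  with SD 1 — a modest two-group microarray study;
* planted patterns added to unfavorable samples: `block_up`/`block_down`
  shift a connected reaction block by $\pm\delta$; `switch` plants
  $+\delta$ and $-\delta$ on the two endpoints of a randomly chosen
  network edge — the contrasting-neighbor pattern the method is designed
  to detect, planted on graph-adjacent reactions specifically;
* the default effect size is $\delta = 2$ noise SDs; the clinical table
  encodes labels via $t = 6$ (favorable) and $t = 2$ with metastasis
  (unfavorable).

Everything is reproducible from the design seed (byte-identical
outputs). The generator emulates the *structure* of the real inputs —
connected reaction networks, two-channel-style log-ratios, a clinical
table the labeling rules act on — and deliberately not microarray
artifacts: no probe-level noise, no dye bias, no correlated gene-gene
background, no missing values, and gene sets are disjoint across
pathways. Passing tests therefore demonstrate that the algorithms
detect what they are designed to detect under clean conditions; they do
not certify performance on real arrays.

`benchmarkSensitivity()` mirrors a simulated sensitivity comparison:
replicated designs are scored per pathway by each method (wavelet
pipeline: best raw feature p; Fisher baseline; optionally the
rank-enrichment baseline), pooled into a threshold sweep
(sensitivity/specificity per significance cutoff) and a threshold-free
ROC AUC. On switch patterns at moderate effect sizes
($\delta \in \{0.5, 0.75, 1\}$ SD, where the baselines are off their
ceiling) the wavelet method's AUC clearly exceeds Fisher's — the
method's designed advantage: a switch pair contributes $2\delta$ to a
contrast feature whose noise shrinks with gene averaging, while
per-gene tests see only $\delta$ each and the enrichment table then
discards effect magnitude entirely. At $\delta \ge 1$ SD with 30 + 30
samples both methods saturate (AUC $\to$ 1), so the qualitative
comparison is made on the pooled sweep.

## Numerical and degenerate-input choices

* Exact Wilcoxon refuses ties and falls back to the approximation; zero
  rank variance yields p = 1.
* Edgeless graphs embed trivially with objective 0 and gap 1; the gap is
  lower bound / incumbent, in (0, 1], and equals 1 iff optimality is
  proven.
* The exact solver's time limit (default 300 s per pathway) returns the
  best incumbent with its gap on expiry.
* Boundary recurrence times (exactly 3 or 5 years) are discarded, never
  silently assigned.
* Reactions without any measured gene stay in the grid (occupied, value
  0) so that feature triviality is structural, not value-dependent.
* Problem sizes in the tests and acceptance analyses: exhaustive
  embedding verification on all 142 connected graphs with at most 6
  nodes; 500 null replicates for family-wise error; 100 seeds for
  planted-pattern recovery; 25 replicates per effect size for the ROC
  benchmark — sizes chosen so the whole battery re-runs in a few
  minutes while keeping Monte-Carlo error well inside the asserted
  margins.

## Known limitations

* Embeddings are unique only up to the solver's tie-breaking; all
  statistics are tied to the serialized embedding used.
* The heuristic solver carries no optimality proof; its gap is only as
  tight as the motif bounds.
* Currency metabolites (ATP, H2O, ...) are *not* excluded by default —
  an exclusion list is accepted but empty; on real pathway data
  currency filtering materially changes neighborhoods and deserves
  explicit curation.
* The KGML reader covers the reaction/substrate/product/gene-entry
  core of the format, not its layout or relation elements.
* The rank-enrichment baseline is a simplified stand-in, not a full
  GSEA implementation.

## A worked example

```{r example, eval = FALSE}
library(GridWave)

design <- simulationDesign(pattern = "switch", effect_size = 2, seed = 42)
pathways <- generatePathways(design)
sim <- generateExpression(design, pathways)

embedded <- runEmbedding(pathways)
run <- runRanking(embedded, sim$expr, sim$clinical)
head(run$results)
```
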