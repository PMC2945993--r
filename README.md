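# GridWave

Pattern analysis of metabolic pathway expression on optimally arranged
lattice grids.

## What it does, and for whom

Standard enrichment tests (Fisher's exact, GSEA-style scores) ask whether a
pathway contains many individually differentially expressed genes. They are
blind to a signature that metabolic networks produce at branch points:
**switch-like regulation**, where one reaction is up-regulated while its
direct network neighbor is down-regulated — flux redirected rather than a
whole gene list shifted. GridWave is for analysts of two-group expression
studies (the motivating case: breast tumors with favorable vs unfavorable
prognosis) who want to rank pathways by coordinated *and* contrasting
regulation of neighboring enzymatic reactions.

The method:

1. **Reaction graphs.** Reactions are nodes; reactions `a`, `b` are
   adjacent iff some metabolite is the product of one and the substrate of
   the other. Pathways with no connected reaction are discarded; reactions
   with identical gene sets are merged (counted as one reaction).
2. **Lattice embedding.** Each graph `G = (V, E)` is placed injectively on
   the smallest square grid, minimizing the total Manhattan edge length

   `min Σ_{a<b} M(a,b) · d_ab`,  `d_ab = |i_a − i_b| + |j_a − j_b|`,

   so network neighbors become spatial neighbors. The placement integer
   program is solved exactly by an authored branch-and-bound with
   motif-derived lower-bound cuts (stars, cliques ≤ 10, odd cycles C3/C5,
   bounded-degree trees) and symmetry breaking; a brute-force oracle and a
   seeded simulated-annealing heuristic (for large pathways) back it up.
3. **Haar wavelet features.** Per sample, reaction expression is painted
   onto the grid (zeros elsewhere) and a multi-level 2×2 Haar cascade
   computes per block the mean-of-means `f1 = (m_u + m_l)/2` (coordinated
   regulation, recursed across levels) and three contrast coefficients
   `f2 = m_u − m_l`, `f3 = (d_u + d_l)/2`, `f4 = d_u − d_l` (switch
   patterns), over all four 2×2 tiling arrangements.
4. **Ranking.** Every non-trivial feature is tested favorable vs
   unfavorable with two-sided Wilcoxon rank-sum tests; pathways are ranked
   by their best feature, Bonferroni-corrected, and flagged significant
   when additionally more than 3 reactions are individually differentially
   regulated. Fisher's-exact and permutation rank-enrichment baselines are
   included for comparison, plus a synthetic-data generator with planted
   block/switch patterns and an ROC sensitivity benchmark.

## Worked example

Simulate a study with one planted switch pathway (effect 2 SD on one
adjacent reaction pair, 30 vs 30 samples), embed, and rank:

```r
library(GridWave)

design   <- simulationDesign(pattern = "switch", effect_size = 2, seed = 42)
pathways <- generatePathways(design)
sim      <- generateExpression(design, pathways)

embedded <- runEmbedding(pathways)
run      <- runRanking(embedded, sim$expr, sim$clinical)
run$results[, 1:9]
#>   rank pathway n_diff_regulated n_reactions n_down n_up        p_raw   p_adjusted significant
#> 1    1     pw1                2           6      1    1 5.316743e-10 1.743892e-07       FALSE
#> 2    2     pw3                0           6      0    0 6.248512e-02 1.000000e+00       FALSE
#> 3    3     pw2                0           6      0    0 8.634645e-02 1.000000e+00       FALSE
#> 4    4     pw5                0           6      0    0 9.775106e-02 1.000000e+00       FALSE
#> 5    5     pw4                0           6      0    0 4.508458e-01 1.000000e+00       FALSE
```

The planted pathway `pw1` (truth: `R1` up, `R5` down in unfavorable
samples) is ranked first: its best wavelet contrast feature separates the
groups at raw p = 5.3e-10, which survives Bonferroni correction over all
328 non-trivial features (adjusted p = 1.7e-7). It is still not flagged
`significant` because a two-reaction switch cannot meet the "> 3
differentially regulated reactions" filter — the counts column shows
exactly the planted 1 up + 1 down. A planted five-reaction block
(`pattern = "block_up", block_size = 5`) does pass both conditions. The
embedding behind the features:

```r
embedded$embeddings$pw1
#> GridEmbedding 'pw1': 6 reactions on a 3x3 grid
#>   objective = 8, gap = 1 (proven optimal)  [exact]
```

A thin command-line front end over the same functions lives at
`inst/scripts/gridwave.R` (subcommands `embed`, `rank`, `simulate`,
`benchmark`).

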