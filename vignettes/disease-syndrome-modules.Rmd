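---
title: "Detecting disease and syndrome modules in weighted PPI networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disease and syndrome modules in weighted PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dismod)
```

# The model

`dismod` operationalizes the disease-module hypothesis: genes associated
with a complex disease cluster in a limited neighbourhood of the
interactome. The pipeline has three statistical layers.

**Topological modules.** The high-confidence PPI network is partitioned by
greedy maximization of weighted Newman–Girvan modularity

$$Q = \sum_c \left[ \frac{W_c}{W} - \left(\frac{S_c}{2W}\right)^2 \right],$$

where $W$ is total edge weight, $W_c$ intra-community weight and $S_c$ the
summed node strength of community $c$. The optimizer is the two-phase BGLL
("Louvain") scheme: sweeps of single-node moves accepting the
maximal-positive-gain move, then aggregation of communities into
super-nodes, iterated to convergence. Modularity maximization assumes the
configuration-model null; it has a resolution limit (very small communities
can be absorbed), which is acceptable here because downstream statistics
operate on modules of tens-to-hundreds of proteins.

**Module enrichment.** For a module of size $n$ inside a background
universe of $N$ genes containing $K$ annotated genes, the overlap $k$ is
scored by the hypergeometric upper tail $P(X \ge k)$ — sampling without
replacement, one-tailed, because only over-representation ("enriched
modules") is of interest. The urn assumes exchangeable genes within the
universe; genes of the annotation set that are absent from the universe are
dropped before counting (with a logged count) so that $K$, $n$, $k$ and
$N$ describe the same population.

**Selection rules.** *Potential disease modules* contain at least one
disease gene; their union is the default background universe
(`covered_modules` policy). *Disease modules* pass a joint criterion: raw
$p < \alpha$ (default 0.01, no multiple-testing correction at this stage)
AND annotated proportion $k/n \ge r \cdot K/N$ with relative-risk
multiplier $r = 3$. *Syndrome modules* are disease modules whose
symptom-gene enrichment also satisfies $p < \alpha$, where the symptom gene
set is the union over a symptom→gene bipartite map. Target-set overlays
(drug targets, herbal-formula targets) are plain intersection counts used
as converging evidence, not hypothesis tests. Per-module annotation ORA
uses the same urn against a GMT collection and applies Bonferroni:
$\mathrm{CPV} = \min(1, m \cdot p)$, significant when $\mathrm{CPV} <
0.01$.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `score_threshold` | 700 | STRING combined score (0–1000) | the conventional high-confidence cut |
| `strict` | `TRUE` (`>`) | – | the source analysis states "weight of edges > 700"; STRING's own convention is `>= 700`, selectable via `strict = FALSE` |
| `resolution` | 1.0 | – | classic Newman modularity; exposed because the partition grain is version-dependent |
| `seed` | mandatory | – | Louvain's local optimum depends on sweep order; forcing a seed makes runs bit-reproducible |
| `alpha` | 0.01 | raw p | module-selection threshold; Bonferroni appears only in the ORA stage |
| `rr_multiplier` | 3 | fold over background | the relative-risk filter; 0 reduces selection to the pure p-rule, `alpha = 1` to the pure proportion rule |
| `background` | `covered_modules` | – | the published arithmetic (997/11,380, 890/11,380) divides by the covered-proteins count, not the full node count |

Two readings of the selection rule circulate: a pure p-threshold
("enriched modules are disease modules") and the proportion cut applied in
the results ("$> 3\times$ background"). The default applies **both**,
which is consistent with the published per-module table where all eight
selected modules satisfy both; each criterion is independently relaxable.

# Numerical and algorithmic choices

- The hypergeometric tail is evaluated through the survival function of
  `stats::phyper` (log-space internally); tests verify agreement with a
  direct `lchoose` enumeration to `1e-12` for all urns with $N \le 60$.
- Louvain convergence: a full pass must improve $Q$ by more than
  `1e-12` — below double-precision noise at desk scale. A node moves only
  on strictly positive gain relative to staying, which guarantees $Q$
  strictly increases and the sweep terminates; ties among candidate
  communities break to the lowest label, so output is a deterministic
  function of (graph, seed, resolution).
- Partition labels are canonical: `0..M-1` by decreasing module size, ties
  by smallest member identifier.
- Reciprocal duplicate edge rows (A–B / B–A, as in STRING dumps) collapse
  to one undirected edge keeping the **maximum** score — a symmetric,
  idempotent reduction. Self-loop rows are skipped with a warning. Nodes
  with no surviving edge are dropped: the published node count describes
  the post-filter graph.
- Gene and protein identifiers are opaque strings assumed pre-reconciled;
  no Ensembl/symbol/STRING-ID mapping is attempted because the upstream
  reconciliation procedure is not recoverable.
- The Bonferroni factor counts only terms with non-empty membership in the
  background — the "number of tests actually performed" — preventing
  inflation by unusable terms.
- The exclusion ledger rounds the ambiguous fraction to 4 decimals
  (36/831 → 0.0433), matching the precision of the published figure.

# What the synthetic generator does and does not emulate

`generate_sbm()` produces a planted-partition (stochastic block model)
graph with constant edge weights above the score filter;
`plant_gene_set()` adds Bernoulli gene membership at rate `q_in` inside
enriched blocks versus `q_out` elsewhere; `generate_symptom_map()` repeats
the planting per symptom with derived seeds (`seed + index`);
`generate_target_sets()` samples a fraction of the planted set plus
decoys. This reproduces the *statistical shape* the analysis assumes —
assortative communities, a disease signal concentrated in a few modules at
a multiple of background, symptom genes concentrated in a subset of those.

It does **not** emulate: heavy-tailed degree distributions, the empirical
STRING score distribution (weights are constant), overlapping or nested
community structure, correlated gene–gene annotation noise, or identifier
mismatch between resources. A green synthetic test therefore establishes
algorithmic correctness and calibration under the stated generative model,
not performance on a real interactome.

# A deliberate red: the end-to-end recovery criterion

The acceptance suite includes an end-to-end scenario stated as: 8 blocks ×
40 nodes, `p_in = 0.25`, `p_out = 0.004`, blocks 1–2 enriched at
`q_in = 0.5` over `q_out = 0.05`, symptoms planted on one block; the
pipeline should flag exactly the two planted blocks as disease modules (and
one syndrome module) in ≥ 18 of 20 seeds. This criterion **fails** (0/20),
and the failure is informative rather than a defect of the implementation:
with 2 enriched blocks among ~8 covered ones, the planted genes themselves
inflate the covered-universe background to $K/N \approx 0.16$, so the
relative-risk cut $3 K/N \approx 0.47$ lands on top of the planted rate
$q_in = 0.5$ — each planted block clears it with probability near one half,
and the thresholds co-move with the draws. At the scale the rule was
designed for, disease modules are a small fraction of the universe (8 of
314 modules), background inflation is negligible, and $3 \times 8.76\% =
26.28\%$ sits far below observed in-module proportions. The test is kept at
the stated parameters; the pipeline-correctness test instead uses a
genuinely separated world (12 blocks, `q_in = 0.8`), where recovery is
reliable.

# Known limitations

- Pure-R Louvain is intended for desk-scale graphs (10²–10⁴ nodes); the
  full 15k-node interactome partitioning is feasible but slow compared to
  compiled implementations.
- The module-selection stage uses raw p-values by design fidelity; users
  wanting family-wise control across modules should lower `alpha`.
- ORA term content is whatever GMT the user supplies; published GO/KEGG
  term lists are database-version dependent and not reproduced here.
- The curation module reproduces the arithmetic of merging sources, not
  the literature screening that produced them.
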