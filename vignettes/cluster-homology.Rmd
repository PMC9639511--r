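---
title: "Cross-species cluster homology: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species cluster homology: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scHomology)
```

## What the package computes

`scHomology` asks, for each cluster of a *target*-species single-cell
dataset, which *source*-species cluster it most resembles
transcriptionally. Clustering itself is an input: the pipeline consumes two
clustered count matrices (genes × cells, MatrixMarket), per-cell label TSVs
and a two-column ortholog table, and produces a source × target grid of
enrichment statistics plus a formal best-match call per target cluster.

The chain is: library-size log-normalization → one-vs-rest Wilcoxon markers
→ ortholog-mapped marker gene sets (source side) and signed-p ranked lists
(target side) → weighted Kolmogorov–Smirnov preranked enrichment with a
gene-permutation null → NES / permutation p / BH adjustment → homology
matrix and match calls.

## The model, stage by stage

### Normalization

Counts are transformed per cell as
$x'_{gc} = \ln\!\left(1 + x_{gc}\, s / \sum_g x_{gc}\right)$ with scale
factor $s = 10^4$ by default (`scale_factor`). This is the standard
log-normalization of the major single-cell toolkits; the upstream analysis
this package reconstructs names its toolkit but not the formula, so the
toolkit's documented default is adopted. Cells with zero total counts are
an *error*, not silently dropped — dropping them would desynchronize the
companion label files.

### Marker detection

For cluster $k$ versus all remaining cells, each gene is scored with the
Mann–Whitney statistic $U$, the normal deviate
$z = (U - n_1 n_2/2)/\sigma$ with tie-corrected variance

$$\sigma^2 = \frac{n_1 n_2}{12}\left[(n+1) - \frac{\sum_t (t^3 - t)}{n(n-1)}\right],$$

and the two-sided tail $p = 2\Phi(-|z|)$ with **no continuity correction**,
matching the fast rank-sum implementations inside the cited class of
toolkits. The fold change is the classic natural-log
`avg_logFC` $= \ln(\overline{e^{x'}-1}_{in} + 1) - \ln(\overline{e^{x'}-1}_{out} + 1)$
(pseudocount $\varepsilon = 1$). Whether the original analysis used the
natural-log (older) or log2 (newer) convention cannot be determined from
its description; natural log is the default here and the base only rescales
the ranking, never reorders it.

Two modes: `filtered` (detection fraction ≥ `min_pct` = 0.1 **and**
|`avg_logFC`| ≥ `logfc_threshold` = 0.25 before testing — the documented
defaults of the reconstructed marker finder) feeds the gene-set side;
`full` (every gene with ≥ 1 nonzero count, no thresholds) feeds the ranked
lists, which must cover the whole expressed universe. BH adjustment is per
cluster across its tested genes. Output order is the deterministic
tri-level sort (p ↑, |logFC| ↓, gene id ↑) so "top N" is reproducible under
ties.

The normal approximation's accuracy at small group sizes is measured
exhaustively in the acceptance suite: over all tie-free group sizes
$2 \le n_1, n_2 \le 7$ and all achievable $U$, the approximate two-sided p
deviates from the exact permutation p by at most **0.24** (at $n_1=2,
n_2=3$), and by at most **0.19** when both groups have ≥ 3 observations.
Those two bounds (rounded to 0.25/0.19) are the documented envelope the
tests assert. At the hundreds-of-cells scale the pipeline actually operates
on, the approximation error is negligible.

### Gene sets and ranked lists

Per source cluster, the builder walks the sorted marker table keeping only
up-regulated records (`avg_logFC > 0` — "marker genes" conventionally means
up-regulated, and mixed-sign sets would make NES uninterpretable as
similarity), skips genes with no ortholog, and stops after `top_n` = 100
*mapped* source genes. The mapping filter is applied **during** selection
("top 100 that could be mapped"), not after; one-to-many orthologs expand
to all their targets, many-to-one collapse by deduplication — this mirrors
how ortholog exports behave, and dropping paralogs would silently shrink
sets. A cluster with no mappable positive marker is omitted with a warning
and recorded in run metadata; its matrix cells carry an `empty_set`
rejection marker.

Per target cluster the ranking score is
$\mathrm{signedP} = \mathrm{sign}(\mathrm{avg\_logFC}) \cdot
(-\log_{10} \max(p, p_{\mathrm{floor}}))$, $p_{\mathrm{floor}} = 10^{-300}$
(so $p = 0$ scores ±300). `avg_logFC` is available as an alternative metric
(`metric`): the source description names both, and which one produced the
published figure cannot be resolved; signedP is the default because it is
the metric the enrichment call itself names. Ties in any ranked list break
by gene id ascending.

### Enrichment

The statistic is the standard weighted running sum: with ranked scores
$s_i$ and gene set $S$ ($k = |S \cap \mathrm{universe}|$, $N$ genes),

$$P_{hit}(i) = \frac{\sum_{j \le i,\, g_j \in S} |s_j|^w}{\sum_{g \in S} |s_g|^w},
\qquad P_{miss}(i) = \frac{\#\{j \le i : g_j \notin S\}}{N - k},$$

and ES is the deviation $P_{hit} - P_{miss}$ of maximal absolute value,
weight $w = 1$ (the preranked default). Sets are tested only if their
intersection with the universe has between `min_size` = 15 and
`max_size` = 500 members (the analysis' stated bounds); rejection is a
recorded outcome, not an error.

Numerical conventions worth knowing:

* **Tie-break in the extremum:** the smallest rank index wins. Because the
  positive and negative extrema can tie *exactly* (e.g. ±1/3) while the two
  cumulative sums differ by one ulp, candidates within `1e-12` of the
  maximal magnitude are treated as tied before the index rule applies.
* **All-zero member scores:** if every member scores 0 the hit weights fall
  back to uniform ($|s|^0$) instead of dividing by zero.
* **Degenerate sets:** an empty intersection and a set equal to the whole
  universe are errors (the miss denominator vanishes).

### Null distribution, NES, p

The reference implementation of fast preranked GSEA estimates tiny
p-values with an adaptive multilevel sampler (its `eps = 0` setting). This
package **substitutes plain gene permutation**: `n_perm` (default 10,000;
2,000 in the acceptance regime) uniformly random $k$-subsets of the
universe, with the add-one estimator

$$p = \frac{1 + \#\{e \in Q : |e| \ge |ES|\}}{1 + |Q|}, \qquad
Q = \{e_{null} : \mathrm{sign}(e) = \mathrm{sign}(ES)\},$$

and $NES = ES / \mathrm{mean}(|Q|)$. Rationale: a cluster-homology matrix
needs p-values resolved to roughly $1/n_{perm}$, not $10^{-50}$; the
multilevel machinery is out of proportion to that need, and the add-one
estimator keeps p strictly positive with the floor $1/(n_{perm}+1)$. The
substitution is recorded in `run_metadata.json`. No attempt is made to
reproduce the exact p-values of any published figure — the permutation
count behind it is unstated anyway.

Each (target cluster, source set) pair draws its permutations from an
independent stream seeded by `derive_seed(master_seed, target, source)`, so
results do not depend on evaluation order. BH runs within each target
cluster across its source sets, mirroring one enrichment call per ranked
list; a global-matrix BH is deliberately *not* the default.

### Matrix, calls, rendering

The homology matrix is complete by construction: every (source, target)
pair holds either a result or an explicit rejection reason
(`size_filtered`, `empty_set`); a missing pair is a bug and raises. The
best-match rule — the package's own formalization, since the source
analysis states no numeric rule for reading its heatmap — is: candidates
are cells with `padj ≤ α` (default 0.05) **and** `NES > 0`; the best match
is the maximal NES (ties to the smaller source index); a target with no
candidate is *unassigned*. Cells display NES (size-comparable across sets,
unlike signed log-p). The heatmap uses a diverging palette centered at 0
(positive red, negative blue), renders rejected cells as grey `NA` — not as
0 — and always writes a TSV twin of exactly the plotted values.

## The synthetic world

The simulator stands in for the deposited datasets the original analysis
used. Its stated world:

| parameter | default | meaning |
|---|---|---|
| `n_source_clusters` / `n_target_clusters` | 10 / 18 | the analyzed datasets' cluster counts |
| `n_shared_orthologs` | 2,000 | ortholog-linked gene space |
| `n_private_genes` | 500 | species-specific genes per species |
| `markers_per_program` | 100 | planted markers per cluster program |
| `theta` | $e^{1.5}$ | multiplicative marker effect |
| `baseline_meanlog`, `baseline_sdlog` | −1.5, 1.0 | log-normal baseline gene means |
| `dispersion` | 0.5 | NB dispersion φ (variance μ + φμ²) |
| `cells_per_cluster` | 300 | cells per cluster |
| `lib_sdlog` | 0.3 | per-cell library-factor spread |
| `decoy_frac` | 0.05 | decoy one-to-many ortholog pairs |

Baseline means are shared between ortholog partners; a cell of cluster $c$
draws $x_{gc} \sim \mathrm{NB}(\ell_c \lambda_g\, \theta^{[g \in
\mathrm{program}(c)]},\ \phi)$ with log-normal library factor $\ell$. Each
source cluster owns one marker program (a block of shared genes); target
clusters named in the correspondence express their partner's program
through the ortholog pairing, the remaining target clusters express fresh
blocks from the shared pool. The log-normal/NB choices are the standard
minimal model for UMI counts: at these means the NB itself produces
realistic dropout-level sparsity (~70 % zeros at the defaults), so no
explicit zero-inflation is added. Baseline parameters (−1.5, 1.0) were
chosen once to put typical gene means near 0.2 counts/cell — the regime of
real 10x data — and are not tuned further.

Two presets: `acceptance_sim_params()` (6 × 8 clusters, 5 planted pairs,
150 markers, 300 cells — the regime the acceptance suite runs in minutes)
and `paper_shape_params()` (10 × 18 clusters, 6,146 / 12,073 total cells,
matching the shape of the analyzed datasets, for manual runs). The
acceptance regime is deliberately smaller than the 10 × 18 shape purely for
runtime; nothing else distinguishes them.

**What a green test does and does not establish.** The simulator plants
clean block-structured programs with a single effect size, no batch
effects, doublets, ambient RNA, cell-type hierarchies or partially
overlapping programs. Recovery of planted correspondences therefore
demonstrates the pipeline's statistical machinery is correct and
well-calibrated — not that any particular biological mapping in real data
is right. Conversely, the null world (`theta = 1`, empty correspondence)
checks that the machinery does not invent homology where none exists.

One behavior of the *real* data structure the simulation does reproduce:
ranked lists carry a heavy negative tail of anti-markers (genes marking
*other* clusters), so a gene set that is merely "expressed everywhere"
concentrates mid-list and can acquire a mildly positive ES under gene
permutation. At realistic scale (2,000+ gene universe) this bias stays far
from significance — the acceptance suite's unmatched-source set scores
ES ≈ 0.2 with p ≈ 1 — but users comparing tiny universes (hundreds of
genes) should expect it.

## Known limitations

* Gene permutation treats genes as exchangeable; correlated gene programs
  make it anti-conservative in principle. The calibration tests bound this
  at the simulated scale only.
* The ortholog table is taken as given: no confidence weighting, no
  reciprocal-best filtering, no live database queries.
* One direction only (source sets → target lists); the reciprocal analysis
  is a re-run with the inputs swapped.
* No optimal bipartite assignment: best-match calls are per target cluster
  and two targets may claim the same source.
* p-values below $1/(n_{perm}+1)$ are floored there by design.

## Reproducibility

Every random draw keys off an explicit seed (`sim_params(seed=)`,
`score_homology(seed=)`); per-pair permutation streams are derived
deterministically from the master seed and the pair labels, and
`run_metadata.json` records package version, full configuration and seed —
deliberately no wall-clock timestamp — so an identical configuration
reproduces every text output byte-identically.
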