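---
title: "Detecting disease modules by connectivity significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting disease modules by connectivity significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diamondR)
```

## The model

`diamondR` treats the interactome as an undirected simple graph over
opaque protein identifiers and a disease as a set of `s0` seed proteins
mapped onto it. The working hypothesis is that the proteins of one
disease occupy a coherent network neighborhood — a *disease module* —
that is visible not through link density but through the *statistical
significance* of links to known disease proteins.

Under the null model that seeds are placed uniformly at random, the
number of seed links `ks` of a protein with degree `k` is hypergeometric,

$$p(k, k_s) = \frac{\binom{s_0}{k_s}\binom{N-s_0}{k-k_s}}{\binom{N}{k}},$$

and its connectivity p-value is the upper tail
$\sum_{k_i=k_s}^{\min(k,s_0)} p(k,k_i)$. The module-growth loop
(`runDiamond`) scores every protein adjacent to the current module, adds
the protein with the smallest p-value, counts it as a seed from then on
(`s` grows by one per iteration), and repeats for a fixed budget. The
agglomeration order is the ranking; no randomness enters the loop.

Key assumptions worth keeping in mind:

* the null is *uniform* placement — degrees are conditioned on, but no
  degree-matched null is used for the seed draw;
* the network is treated as unweighted and undirected; evidence quality
  of individual interactions is ignored;
* p-values at different iterations are **not** comparable (the seed count
  grows), so the raw significance cannot serve as a stopping rule — the
  recovery-based and annotation-based procedures below exist for that
  purpose.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `nIterations` | 200 | growth budget; across disease corpora both annotation support and integrated-seed counts plateau around 200 added genes, which is why 200 is the conventional module cutoff |
| `alpha` | 1 | seed weight; `alpha > 1` counts links to *original* seeds `alpha`-fold (agglomerated members always weigh 1), implemented by the virtual seed-duplication transform `N' = N + (α−1)s0`, `s' = αs0 + s_agg`, `k' = k + (α−1)k_w`, `ks' = ks + (α−1)k_w` |
| `nRandom` | 1e5 | replicates for the LCC null; published corpus tables use 1e6, the default trades a ~3× larger Monte-Carlo error for desk-scale runtime and is configurable |
| `restart` | 0.4 | restart probability of the random-walk baseline |
| `tolerance` / `maxSteps` | 1e-10 / 1e4 | L1 convergence for the walk's fixed point; the converged scores are insensitive to tightening it further |
| `targetSize` | 200 | planted connectivity-module size, the putative size of a complete disease module given that curated disease gene sets (50–150 genes) are thought to cover 30–50% of the truth |
| `removeFraction` | — | hidden fraction in recovery runs; the study grid is 25/50/75% |
| `alphaLevel` | 0.05 | Bonferroni-corrected threshold for seed-term enrichment (a printed threshold of 0.5 in the source literature is treated as a typo; the parameter is exposed) |
| `window` | `s0` | sliding-window width in annotation validation, matched to the seed count so window counts are comparable across iterations |

`alpha` is accepted as any real ≥ 1: the duplication transform is printed
with integer copies in mind, but the log-gamma binomial generalization
reduces exactly to duplication semantics at integral `alpha` (this is
property-tested against explicitly duplicated graphs) and interpolates
smoothly between them otherwise.

## Numerical choices

* **Log-space everywhere.** Real seed sets produce connectivity
  significances down to 1e-23 and far below; all pmf/tail work uses
  log-gamma binomial coefficients and log-sum-exp, and `log.p = TRUE` is
  available throughout.
* **Saturated tails are exactly 1.** A degree-`k` protein must hit at
  least `k − (N − s0)` seeds by pigeonhole; in that regime the tail is
  returned as exactly 1 rather than `1 ± 1e-14` of accumulated rounding,
  which keeps the monotonicity underlying candidate pruning clean.
* **Dominance pruning.** At fixed `ks` the candidate with the smallest
  `k` dominates, and vice versa; each iteration computes exact p-values
  only for the per-`ks` minima. The pruned selection is tested to be
  identical to exhaustively scoring every candidate.
* **Deterministic ties.** Equal p-values are broken by higher `ks`, then
  lower `k`, then lexicographic identifier. The tie rule is a package
  convention (the source literature does not specify one); rankings are
  therefore bit-reproducible, but a particular published module size
  obtained with a different tie order could differ by a few members.
* **Degenerate inputs.** A seed set equal to the whole network (or any
  null with zero variance) flags the LCC z-score as undefined instead of
  dividing by zero; an exhausted candidate pool ends the growth loop with
  a warning; empty boundary sets give local modularity `R = 1` by
  convention; empirical p-values use the `(r+1)/(n+1)` estimator so a
  never-exceeded observation reports `p < 1/(n+1)`, never 0.
* **Local modularity indexing.** `R` is computed as "edges incident to
  boundary nodes that stay inside the community, over all edges incident
  to boundary nodes", with boundary–boundary edges counted once — the
  textual definition of the measure; a brute-force edge-classification
  oracle confirms it on random graphs.
* **Rewiring.** Partial rewiring detaches `⌊fE⌋` edges and re-pairs their
  stubs uniformly; invalid pairs (self-loops, duplicates) are re-shuffled
  up to 100 rounds and any remainder resolved by double-edge swaps, so
  the degree sequence is preserved *exactly* and the graph stays simple —
  which plain configuration-model pairing alone would not guarantee.
* **Random walk.** The baseline is implemented as the deterministic fixed
  point $p = r\,u + (1-r)Wp$ (column-normalized `W`, uniform restart over
  seeds, dangling nodes teleporting to the seeds) rather than by
  simulating a walker; the two are equivalent in the limit and the fixed
  point is reproducible and fast. Power iteration is cross-checked
  against a dense linear solve in the tests.

## What the synthetic data emulate — and what they do not

The generator builds scale-free backgrounds by preferential attachment
(`syntheticInteractome`, 5,000 nodes and 10 edges per node by default,
i.e. mean degree ≈ 20 — chosen to match the density of consolidated human
interactome maps, whose mean degree is about 20.7). Planted structures
come in three flavors: cliques wired into a sparse background (fully
controlled ground truth), radius-2 *shell* modules, and
*connectivity-significance* modules grown by the algorithm's own rule to
200 nodes, which mimic the topology of real disease neighborhoods.

These fixtures reproduce the heavy-tailed degree distribution and the
seed-expansion geometry of the real problem, but **not** the local
clustering contributed by protein complexes, nor annotation biases, nor
the ascertainment noise of curated disease associations. Consequently:

* recovery experiments on synthetic modules support *directional* claims
  (early precision of module growth, late catch-up of the diffusion
  baseline) rather than published curve values;
* one published qualitative claim — that the recall *fraction* is
  insensitive to the removed fraction across 25/50/75% — reproduces here
  only partially: at a fixed 300-iteration budget the 25% and 50%
  distributions overlap, while 75% removal sits visibly lower. The
  recalled *counts* behave comparably across fractions, but with
  denominators differing three-fold the fraction distributions need not
  overlap on backgrounds without complex-driven clustering. The
  corresponding acceptance assertion is kept in its strict form and
  fails, documented rather than relaxed.

Recovery budgets in the shipped experiments are 300 iterations (twice the
largest removal count, so every fraction can reach full recall), with the
50%-removal arm extended to 400 for the baseline comparison; studies use
50 planted modules in the test suite and 20 in the acceptance script.
These sizes are the package's documented study conditions.

## Design decisions on open points

* Disease proteins absent from the network are recorded (`unmapped`) but
  excluded from `s0` — statistics describe what lies on the network.
* Candidates are neighbors of the *current module*, not only of original
  seeds, so initially disconnected seed clusters grow simultaneously and
  proteins two steps from every seed can enter once an intermediate is
  absorbed.
* In leave-one-seed-out analysis, "deviation persists" is operationalized
  as deviation > 0 at that iteration; persistence is the fraction of
  iterations with nonzero deviation.
* Validation windows exclude the seed genes themselves; the background
  universe of enrichment tests is the annotation collection's own
  background (the union of annotated genes unless supplied explicitly).
* GO evidence-code filtering and ontology propagation are upstream
  preprocessing: the package consumes flat GMT. To produce a compliant
  file from GO or MSigDB exports, keep one line per term — identifier,
  description, then member genes — tab-separated, restricted to the
  evidence codes you trust, with annotations propagated to ancestor terms
  before flattening.

## Limitations

* The hypergeometric null ignores degree correlations; on strongly
  assortative networks the significance of high-degree candidates is
  overstated relative to a degree-preserving null.
* The growth loop is greedy: a single early tie broken differently can
  propagate (which is why the tie rule is fixed and documented).
* p-values across iterations are incomparable by construction; any
  module-size choice must come from recovery saturation or annotation
  support, not from a p-value threshold.
* Identifiers are opaque strings; no mapping between gene identifier
  namespaces is attempted.
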