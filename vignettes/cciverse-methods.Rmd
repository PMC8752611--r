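---
title: "Methods: downstream analysis of predicted cell-cell communication"
author: "cciverse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream analysis of predicted cell-cell communication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cciverse)
```

## The problem

Cell-cell communication inference tools (CellPhoneDB, CellChat, ICELLNET,
SingleCellSignalR, or custom analyses) score ligand-receptor interactions
between pairs of cell clusters from single-cell or bulk expression data.
Their output — a table of *interaction pairs* (an ordered pair of molecular
components, each a single gene or a multi-subunit complex) observed in
*cluster pairs*, with a score and often a p-value — is where most analyses
stop. `cciverse` takes exactly this table as its input and provides the
downstream layer: standardization into one data model, per-cluster and
per-gene summaries, functional annotation against gene-set collections,
data-driven grouping of interaction pairs into functional *modules* with a
permutation test for term specificity, and comparison of communication
across experimental conditions.

The package is headless: every computation is a plain R function returning
a data frame or a small classed object, and a thin command-line wrapper
(`inst/cli/cciverse.R`) exposes the same pipeline as subcommands.

## Data model and standardization

A `cci_table` stores one record per couplet — the occurrence of an
interaction pair in a specific ordered cluster pair. Canonical ids join the
two components with `"_"` and complex subunits with `"+"`
(`BMP7_ACVR1+ACVR2A`); display strings use the `BMP7 & (ACVR1+ACVR2A)`
notation. The underscore is therefore reserved and may not occur inside a
component name; the CellPhoneDB reader maps underscores inside complex
names to `"-"`.

`standardize_cci()` applies three steps before any analysis:

1. components are mapped to gene symbols (an explicit `gene_map` may
   override the membership of named components, e.g. database complexes);
2. missing molecular types (ligand `L` / receptor `R`) are filled from a
   curated typing table; a type already present in the input wins over a
   contradictory curated entry, with a warning. Components typed by neither
   source are kept with type `"unknown"` and excluded from flow-directed
   analyses — dropping them silently would bias counts, while guessing a
   type would fabricate directionality;
3. records ordered receptor-ligand are swapped wholesale (components,
   clusters and types together) to ligand-receptor, so that `clust_a`
   always expresses the ligand of a directed interaction and communication
   flow is preserved. Ligand-ligand and receptor-receptor records are left
   as they are. The operation is idempotent.

Filtering (`filter_cci()`) is explicit and recorded in the table's
provenance: cluster subsetting, a minimum score, a maximum p-value. A
p-value filter applied to a table that never had p-values is a no-op, but a
record with a *missing* p-value in a table that has them fails the filter —
the conservative reading, since such a pair was not actually tested.

## Summaries

Counts per ordered cluster pair are directed: `(A,B)` and `(B,A)` are
different cells of the matrix, and autocrine communication sits on the
diagonal. The "weighted" count is the **sum** of interaction scores over
the records of a cluster pair; a mean would hide how many interactions
support an edge, and the sum is consistent with how ring sections are sized
in sunburst exports. Per-cluster totals attribute each paracrine record to
both participating clusters, once each, because a cluster's communication
load includes interactions it receives as well as sends; autocrine records
count once, flagged autocrine.

## Functional annotation

Collections are read from GMT files, one per source database. A term
annotates an interaction pair only when **every** gene of **every**
component — including each subunit of a complex — is contained in the
term's gene set. Gene matching is exact after upper-casing both sides
(GMT files vary in case). Identically named terms from different sources
(case-insensitive) are merged into a single column with concatenated
source labels; the merged column is 1 when any single source's gene set
annotates the pair. Terms annotating no pair are dropped. The result is a
binary interaction-pairs-by-terms matrix; `rank_terms()` orders terms by
the number of annotated pairs, ties broken alphabetically.

No over-representation statistics are computed at this stage: annotation
is membership, not enrichment against a background.

Sunburst data for a term considers every couplet whose pair is annotated
to it: the inner ring groups couplets by the cluster expressing the first
component, the outer ring nests the second component's cluster under its
inner section. Section values are couplet counts or summed scores; widths
are normalized within each ring (they sum to 1 to within floating-point
round-off) and sections are sorted descending, ties alphabetical.

## Interaction-pair modules

Module definition follows a fixed pipeline on the annotated pairs of a
chosen *viewpoint* cluster and *communication flow* (directed-outgoing:
the viewpoint sends ligands, any receiver including itself;
directed-incoming: the viewpoint expresses the receptor; undirected:
ligand-ligand or receptor-receptor records touching the viewpoint):

1. **Embedding.** UMAP of the binary annotation profiles with the cosine
   metric, so similarity means shared functional terms regardless of how
   many terms a pair carries. Defaults: `n_neighbors = 15`,
   `min_dist = 0.1`, seed 42; all configurable, and `n_neighbors` is
   clamped to n-1 with a warning. Initialization is *random* (but
   seed-deterministic): binary profiles contain many exact duplicates,
   which collapse a PCA initialization to rank 1 and can disconnect the
   graph that spectral initialization needs; the random layout is immune
   to both and the optimizer separates the profile groups reliably.
   Reproducibility is exact for a fixed seed (single-threaded
   optimization).
2. **Clustering.** Agglomerative hierarchical clustering of the 2-D
   coordinates with euclidean distance and Ward's `ward.D2` criterion, cut
   at k modules. Module ids are relabeled 1..k by decreasing size (ties:
   lower original label) so output ordering is stable.
3. **Choosing k.** Two diagnostics are computed over cuts k = 1..k_max
   (default `min(10, n-1)`): the total within-cluster sum of squares
   (WSS), and the average silhouette width (k >= 2). The default k is the
   WSS *elbow*, found as the point of maximum curvature: the k with the
   largest perpendicular distance between the WSS curve and the chord
   joining its endpoints, computed on **log(WSS)**. The log scale matters:
   with well-separated groups the embedding places clouds so far apart
   that the k=1 to k=2 drop dwarfs the rest of the raw curve and the chord
   construction can miss the true elbow; WSS shrinks multiplicatively as
   real groups split apart, and the log curve bends sharpest where that
   shrinking stops. On planted 2-, 3- and 4-group fixtures the log-scale
   elbow recovers the planted k across all tested seeds. Ties take the
   smallest k; identical coordinates (WSS ~ 0 everywhere) give k = 1 with
   a warning.
4. **Small scopes.** With 10 or fewer unique annotated pairs in scope only
   one module is defined — too few points for the embedding and the cut to
   be meaningful — though 2-D coordinates are still produced for plotting.

## Term-specificity permutation test

For each (term, module) the statistic is the **module ratio**: the
proportion of the module's pairs annotated to the term. The module
assignment vector is shuffled without replacement (module sizes preserved)
`n_perm` times (default 1000), and the one-sided empirical p-value is the
plain proportion of permuted ratios greater than or equal to the observed
one. One shuffle per iteration is shared across all terms — cheaper than
per-term shuffles and with the identical marginal null distribution. The
plain proportion can be exactly 0; an optional `(b+1)/(m+1)` estimator is
available (`smoothed = TRUE`) but off by default to keep the estimator
exactly as defined. Terms are ranked by p-value; the default significance
threshold is 0.05. With a single module the statistic is invariant under
permutation, so every p-value is 1 and a warning says so.

Against exact enumeration of all assignment permutations (feasible to
n = 8), the Monte-Carlo p-values agree to within four standard errors at
`n_perm = 1e5`; the hand-checkable case — a term matching exactly one
2-pair module among 4 pairs — has exact p = 1/6.

## Multiple conditions

A `condition_set` bundles per-condition tables over the union cluster
universe; labels are compared verbatim, so harmonizing cluster names across
conditions is the caller's responsibility, and tables are compared as
given (no re-filtering is imposed). Couplets and interaction pairs are
*unique* to a condition when present there and absent from every other
condition — strict uniqueness, so an element in two of three conditions
belongs to none. Pie fractions are each condition's share of all unique
couplets. Count comparisons report raw per-cell-type differences
(`count_x - count_y`) restricted to selected flow classes; undirected
records count once per participating cluster side, autocrine once. No
significance test is attached to count differences; only the raw deltas
are reported.

Condition-specific terms reuse the module-ratio test verbatim with the
module assignment replaced by the condition assignment over the union of
condition-unique pairs. On label-exchangeable synthetic data the test
rejects at the 0.05 level in well under 7% of simulated null datasets
(the discrete permutation null makes it conservative).

## The synthetic fixture generator

`fixture_spec()` / `make_cci()` / `make_gmt()` /
`make_condition_fixture()` generate the study conditions every test runs
under: 6 cell clusters, 30 interaction pairs split into 3 planted
functional modules of 10 (balanced), a 0.2 probability that a component is
a 2-subunit complex, 10% autocrine records and 10% undirected
(receptor-receptor) pairs, lognormal(0, 0.5) scores (positive and
right-skewed, like expression-derived means) and Beta(0.5, 3) p-values
(skewed toward small values, as inference tools report). Gene symbols are
synthesized (`GENE0001`, ...) so fixtures can never accidentally match a
real gene-set collection. Every pair occurs at least once in the outgoing
scope of the viewpoint cluster `C1`; planted module terms contain exactly
the genes of one module's pairs, background terms cover random pair
subsets. Condition fixtures share `n_shared` pairs across all conditions
and plant `n_unique` pairs plus one covering term per condition. All
randomness derives from the spec's single seed; identical specs produce
byte-identical files.

What the generator does **not** emulate: expression-level noise (scores
are drawn, not computed from counts), correlation between score and
p-value, overlapping or hierarchical gene sets such as an ontology,
imperfect module structure (planted profiles differ only through
background terms), or label noise across conditions. Passing tests
therefore demonstrate algorithmic correctness under clean planted
structure, not robustness to the messiness of real CCI predictions.

## Numerical choices and degenerate inputs

- Circle-plot link scores are z-scored with the population (1/n) standard
  deviation and clipped to [-2, 2]; zero variance maps every link to 0.
- Ties: term ranking and sunburst sections break ties alphabetically;
  elbow ties take the smallest k; module relabeling ties keep the lower
  original label.
- Empty results from filters or selections warn (classed warnings) but
  return typed empty objects; structural problems (missing columns,
  duplicate couplets, unknown clusters) are classed errors.
- Sunburst ring widths sum to 1 within 1e-9 (in practice to machine
  precision); permutation ratio comparisons use a 1e-12 slack to absorb
  division round-off.
- Test and acceptance problem sizes are the package's chosen study scale:
  30-pair/3-module fixtures, 20 seeds for recovery, `n_perm = 1e5` against
  enumeration oracles and 500-1000 simulated null datasets at
  `n_perm = 1000` for calibration.

## Known limitations

Only the public CellPhoneDB v2 output dialect is parsed natively; other
tools' exports are ingested through the custom schema, and the writing
side of that schema makes the conversion a one-liner. Gene symbols are
assumed human and are not ortholog-mapped. Annotation requires user-supplied
GMT files rather than live database queries, trading freshness for
reproducibility. UMAP coordinates are deterministic for a fixed seed and
library version but not comparable across `uwot` versions; module
*assignments* on well-separated structure are far more stable than the
coordinates themselves.
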