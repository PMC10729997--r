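---
title: "Methods: network analysis of zooarchaeological assemblages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network analysis of zooarchaeological assemblages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zooarchnet)
```

`zooarchnet` models a zooarchaeological dataset as a taxon-by-context matrix
of Minimum Number of Individuals (MNI) and derives network graphs from it.
This vignette documents the modelling decisions: what each stage computes,
which parameters matter and why their defaults are what they are, what the
synthetic generator does and does not emulate, and where the genuinely open
design choices were made.

## The data model

The unit of observation is a *context* — a discrete excavation provenience
(a stratigraphic layer or a sampled stratum) treated as one assemblage — and
the unit of abundance is MNI, the smallest number of individual animals that
accounts for the identified specimens of a taxon in a context. MNI is
preferred over raw specimen counts (NISP) because fragmentation inflates
NISP differentially across taxa. All relative abundances are *percent MNI*:
a taxon's share of a context's total MNI within a stated taxon scope. The
scope matters: the stratigraphic stages are invertebrate-only analyses, so
their denominators are invertebrate totals, while the site-wide stages use
every identified taxon.

Counts must be non-negative integers; absences may be written as dashes or
empty cells in the CSV interchange format and parse as zeros. Taxon
identifiers are kept verbatim — combined names with a forward slash
(`Nassarius/Phrontis vibex`) and `cf.`/`sp.`/`spp.` qualifiers stay distinct
nodes — because silently lumping rows would change every downstream graph.
Whether same-genus `sp.` and `spp.` rows should be a single node is a
genuine uncertainty in the source compilation; keeping them distinct is the
conservative choice and is what the bundled fixture does.

The bundled Pineland dataset has 336 taxa and 15 contexts. One transcription
caveat is worth stating: in the source table's last column the printed cells
sum to 9950 while the printed Totals row reads 9949, an internal
one-individual inconsistency; the package keeps the cells verbatim, so
`context_totals()` reports 9950 there.

Habitat designations for invertebrates — the five salinity-regime classes
*tidal stream*, *estuarine mangrove*, *oyster bed*, *seagrass meadow* and
*littoral* — are not part of the printed compilation. The bundled
`pineland_taxa.csv` is therefore a curated, editable stand-in assigned at
genus/family level from standard ecology of these estuarine taxa. Analyses
that depend on habitat membership (the exclusive-habitat filter, the habitat
collapse, habitat-coloured graphs) are exact *given* a designation table,
but their fixture results should be read as illustrative of the workflow,
not as reproductions of the original study's habitat readings.

## Metrics

* **Shannon diversity** `H = −Σ p ln p` (nats) on percent MNI. The source
  analyses size context nodes by an unnamed "diversity value"; Shannon H on
  all-taxa percent MNI is the default here, with richness available through
  the `diversity` configuration key, since only relative node sizes matter.
  Natural logarithms are conventional.
* **Richness** — taxa with MNI ≥ 1. **Presence** always means MNI ≥ 1; no
  abundance floor is applied for presence, ubiquity or Jaccard.
* **Ubiquity** — occupied contexts / all contexts.
* **Exclusive-habitat filter** — habitat-level stages use only invertebrates
  whose habitat set has exactly one element: a species at home in two
  habitats cannot witness either. The habitat collapse consequently uses
  exclusive-habitat taxa by default; a `fractional` scope that splits
  multi-habitat taxa equally across their habitats is available because the
  original figure caption is ambiguous about the collapse scope.

## Similarity and thresholds

Context-to-context and species-to-species co-occurrence use the **Jaccard
coefficient** on presence sets. Two all-empty presence sets get `J = 1`
(identical emptiness) with a warning; such items are normally filtered out
before comparison.

"Similarity in presence and abundance" between species profiles is the
**Renkonen percentage similarity**: each species' percent-MNI profile across
contexts is normalized to sum one and two species score the sum of
column-wise minima. The original analyses never name the abundance-overlap
metric their point-and-click tool computed; Renkonen is the field's standard
percent-similarity measure with the required `[0, 1]` semantics and is the
default, with `1 −` normalized Manhattan distance available as an explicit
alternative (the two coincide on normalized profiles, which makes the option
a useful cross-check rather than a different model).

Thresholds follow the wording of the published captions literally: cutoffs
described as "greater than" (0.60 for the stratigraphic species graph, 0.33
for the context graph, 0.40 for the site-wide species graph) are strict
`>`; the subgroup projection rule, "at least 5 %", is inclusive `≥`. Whether
the original point-and-click software applied `>` or `≥` internally is
unknowable from the text; strict is the literal reading.

`max_connected_threshold()` formalizes "the graph just before it is broken
apart": it sweeps the distinct observed similarity values in decreasing
order (no continuous search — only observed values can change the graph) and
returns the largest value at which the scoped items, with inclusive ties at
the candidate, form one connected component. Items with no positive
similarity to anything can never connect and are excluded from the scope
with a warning. If the remaining items never connect, the caller chooses:
error (default), re-scope to the largest component, or fall back to the
minimum positive value — the last is what the package's own recovery
pipeline uses, because perfectly separated species packages are exactly the
situation in which the graph *should* stay disconnected.

## Community detection

Girvan–Newman is implemented from scratch, as it is the analytical core:

1. **Edge betweenness** by Brandes' algorithm on unweighted shortest paths
   (once thresholded, ties are binary; similarity weights do not shorten
   paths). Each unordered vertex pair contributes once, with equal-length
   multiplicities split fractionally. The inner loop is compiled (C++) since
   the removal sequence recomputes betweenness after every deletion.
2. **Removal** of the maximum-betweenness edge, ties broken by the bytewise
   smallest endpoint pair — full determinism without randomness.
3. **Recording**: after every removal, the connected-component partition and
   its **modularity on the original edge set** (standard practice; the
   degree distribution of the data, not of the partially dismantled graph,
   defines the null expectation).
4. **Selection**: the maximum-Q partition, ties resolved toward fewer groups
   and then the earlier step; or a fixed group count via `partition_at()`,
   which exists because the published analyses report fixed readings (five
   stratigraphic subgroups; seven site-wide subgroups in the text against a
   six-group "optimal solution" in the figure caption — the two cannot both
   be the modularity optimum, so the package reports its own best-Q count
   and leaves the fixed-count mode to mimic either reading).

Isolated nodes pass through as singleton groups; in the pipelines, community
detection runs on the tied (degree ≥ 1) nodes and isolates are appended
afterwards, since an isolate carries no co-occurrence signal and would
otherwise inflate the group count arbitrarily. Pipeline group labels are
integers ordered by descending member MNI — the original Group 1–7 numbering
is a display artifact, so any matching to published group numbers is up to
permutation.

The correctness of the from-scratch implementation is established in the
test suite against independent oracles: exhaustive shortest-path enumeration
for betweenness, closed-form modularity values, and an independent
reference implementation (igraph's edge-betweenness clustering) on planted-
partition graphs. The reference implementation is used only as an oracle,
never as the computation.

## Pipelines

`run_stratigraphic()` scopes to the four Operation P levels (a waterlogged
midden column; the deepest level is the earliest) and to invertebrates, and
emits six stages: the habitat ego-network, the layer-by-exclusive-species
graph, the layer-by-habitat collapse, the thresholded Renkonen species
graph, its partition, and the layer-by-subgroup projection.
`run_sitewide()` uses all 15 contexts and all taxa for its five stages
(diversity-sized two-mode graph, context Jaccard graph, species Jaccard
graph sized by ubiquity and partitioned, subgroup projection, and the
group-composition table).

In the composition table the most abundant group — empirically a ubiquitous
"base" package present almost everywhere — can be excluded. Exclusion drops
the row but keeps the denominators, because the published pie charts
*removed* the base group from display, not from the assemblages; a
`renormalize_excluded` switch rescales instead. Subgroup-projection tie
weights are stored as fractions (0.07), rendered as percents in reports.

Every stage writes GraphML plus edge-list and node CSVs and a JSON manifest
of resolved parameters and node/edge/group counts. Manifest paths are
relative to the output directory and no output embeds a timestamp, so
re-running a stage with the same configuration and inputs is byte-identical.

## The synthetic generator

`generate_assemblage()` draws matrices with the statistical structure the
analysis presumes: `n_groups` species *packages*, each abundant only in its
supported block of contexts; an optional ubiquitous *base* package (so
base-exclusion logic is exercised); member weights drawn once per package
from a symmetric Dirichlet whose concentration controls how similar member
profiles are ("found together in similar proportions"); a Poisson context
total allocated multinomially among the packages active in that context; and
Poisson stray counts in every cell. Habitat labels are assigned blockwise,
one habitat per package, so the habitat stages have non-trivial synthetic
behaviour. `context_total` is an expectation, not an exact size — realized
totals are Poisson around it plus strays.

The generator emulates block co-occurrence structure, overdispersion-free
integer noise and a base package. It does **not** emulate taphonomic loss,
sample-size differences between contexts, rank-abundance tails, or spatial
autocorrelation between adjacent strata — so a passing recovery test shows
the pipeline finds planted co-abundance structure at realistic noise, not
that the Pineland groups are "correct".

Recovery is scored by the Adjusted Rand Index between the recovered and
planted partitions over the non-base species (the base package is a
confound by design). The reference conditions used in the tests and the
acceptance script — 8 contexts, 4 packages × 10 species, concentration 50,
stray rate 0.2, expected context total 500, with a base package of 5 species
(a size chosen once here, as the reference conditions leave it open) —
recover the planted four-package structure with ARI ≥ 0.9 in at least 18 of
20 seeded replicates; mean ARI degrades monotonically as the stray rate
grows.

## Numerical and degenerate-input choices

* Proportion columns must sum to 1 within `1e-9`; contexts with zero scoped
  MNI are *flagged* (NA proportions, a warning, names in an attribute), not
  silently zeroed.
* Similarity matrices are symmetric by construction with unit diagonal;
  thresholding keeps all items so isolates remain visible.
* An edgeless graph yields the trivial single-step dendrogram; modularity on
  an edgeless graph is an error (undefined), and the trivial partition's Q
  is reported as missing in that case.
* Betweenness ties are resolved with a `1e-9` absolute tolerance — the
  values are small rationals, so genuinely different values at the scales
  used differ by far more.
* All randomness is seeded through a single integer per generator call;
  identical seeds give identical matrices, and the pipelines themselves are
  deterministic.

## Problem sizes

The test suite runs the stratigraphic pipeline on the full fixture (114
exclusive-habitat species over 4 levels), the site-wide pipeline on a
synthetic 18-species assemblage, oracle comparisons on 200 random graphs of
up to 12 nodes, and 20-seed recovery batches; the acceptance script
additionally runs the full site-wide fixture analysis (336 species, 4,643
ties). These sizes were chosen so every check completes in seconds to a
couple of minutes on one CPU while still exercising the full code paths.

## Known limitations

* Habitat designations are a curated stand-in (above); habitat-dependent
  fixture outputs are illustrative.
* No rarefaction or sample-size standardization is applied; contexts with
  very different MNI totals are compared on proportions and presences, as in
  the source workflow.
* Only Girvan–Newman is provided for community detection; the fixed-count
  mode mimics published readings but cannot adjudicate between them.
* Graph layout is left to downstream viewers; `plot_network()` is a seeded
  convenience, and published node positions are a display artifact of the
  original software.
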