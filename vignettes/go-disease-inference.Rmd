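---
title: "Inferring GO-disease networks and ranking comparable diseases"
author: "goDiseaseNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring GO-disease networks and ranking comparable diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goDiseaseNet)
```

## The model

Curation databases hold two kinds of direct statements about genes:
ontology annotations (a GO biocurator states that gene *g* participates
in biological process *t*) and disease curations (a disease biocurator
states that gene *g* is a marker, mechanism or therapeutic target of
disease *d*). Neither statement mentions the other, but the two can be
joined transitively: whenever at least one gene carries both, the pair
(*t*, *d*) becomes an **inferred GO-disease relationship**, and the set
of genes realising the join is its **inference gene network**

$$ G(t, d) \;=\; \{g : g \in \mathrm{ann}(t) \,\wedge\, g \in
\mathrm{cur}(d)\}, \qquad (t,d) \text{ inferred} \iff G(t,d) \neq
\emptyset. $$

`inferGODisease()` computes exactly this join. Because GO is a DAG in
which annotation to a term implies annotation to every ancestor (the
true-path rule), inferences are *subsumed* upward on demand:
`rollupGO()` attaches to each term the union of the diseases (and gene
networks) of all its descendants. The package stores inferences at the
directly annotated term and treats subsumption as a query-time view;
the flat download files describe direct joins, and storing both direct
and subsumed rows would duplicate state that a cheap closure
recomputes.

Disease vocabularies are hierarchical too (a parent disease has
curated sub-types), so the dual operation `rollupDisease()` merges a
disease with its hierarchy descendants before comparison, and
`slimBin()` collapses disease lists into a small set of generic
categories for summary pie-chart-style breakdowns.

### Disease similarity from shared processes

Two diseases can be mechanistically similar without sharing a single
curated gene, because disjoint gene sets can participate in the same
biological processes. The pair matrix built by `buildPairMatrix()`
compares every disease with at least one inferred GO-BP term against
every other — $\binom{n}{2}$ unordered pairs — and records, per pair:
curated gene counts and their intersection, inferred GO-BP term counts
and their intersection, the Jaccard index

$$ J(A, B) = \frac{|T_A \cap T_B|}{|T_A \cup T_B|} $$

on the term sets, per-disease overlap percentages, and a one-sided
hypergeometric overlap p-value with Bonferroni adjustment across the
matrix. Two deliberately strict filters isolate the interesting
region:

* `filterDisjointGenes()` keeps pairs with **zero** shared curated
  genes but at least one shared inferred term, removing overlap that
  is trivially explained by common genes;
* `filterGeneParity()` keeps pairs where both diseases have at least
  `minGenes` (default 10) curated genes and the two counts are within
  `tolerance` (default 10%) of each other, so a heavily studied
  disease is never compared against a barely curated one. The rule is
  applied symmetrically — min(nA, nB) ≥ (1 − tol)·max(nA, nB) — which
  reproduces the canonical bracket (a 50-gene disease admits partners
  with 45–55 genes) while staying independent of which disease is
  called A; an asymmetric reading would make the filter
  order-dependent for no benefit.

`diseaseComps()` then ranks a query disease's partners by descending
Jaccard, breaking ties by shared-term count and finally disease id so
the ranking is a deterministic function of the inputs.

### Overlap significance

`hypergeomOverlapP(k, K, n, N)` returns the upper tail
$P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$ — the one-sided
test appropriate for "is this overlap larger than chance", evaluated
through `stats::phyper`, which works in log space and is stable for
the extreme tails this analysis produces. The universe $N$ defaults to
the number of distinct GO-BP terms carrying at least one inference in
the loaded dataset; no universally correct universe exists for
annotation data, so the default is the smallest defensible one and a
`universe` argument allows an explicit choice. For three or more sets
a Pearson chi-square on a membership contingency table is used
(`overlapContingency()` builds one row per set, counting universe
terms inside and outside the set); the exact layout of a multi-set
overlap table is a genuine design choice, and this per-set
member/non-member construction was chosen because its margins are
always positive whenever every set is nonempty and a universe exists.
Only Bonferroni is offered for multiplicity (`bonferroniAdjust()`);
the pair matrix makes millions of non-independent comparisons and the
conservative bound is the defensible one.

### Drug repositioning by gene-set coverage

When two diseases share many inferred processes but no genes, drugs
therapeutic for one are candidates for the other. The workflow in
`runRank()`:

1. `vennChemicals()` partitions the chemicals with *therapeutic*
   evidence for either disease into onlyA / both / onlyB;
2. `referenceGeneSet()` intersects the interacting-gene sets of the
   shared chemicals — the molecular milepost;
3. `rankCandidates()` scores every disease-B-specific chemical by
   coverage = (reference genes it interacts with) / (reference size),
   flagging candidates whose coverage **strictly** exceeds the
   threshold (default 0.5; "more than half", so exactly half does not
   flag);
4. `annotateReferenceWithGO()` reports how much of the pair's shared
   GO-BP signal the reference gene set itself carries, as a sanity
   check that the milepost is on the mechanism.

`crossSetInteractions()` supports the related nexus analysis: edges of
a gene-gene interaction network with one endpoint in each of two
disjoint gene sets, with per-gene cross-degrees identifying hub genes
that bridge the two diseases. Edges are treated as undirected —
direction labels are carried but not interpreted — and within-set
edges are excluded by default (`includeWithinSet = TRUE` restores
them), since the question is what connects the sets, not what happens
inside either.

## Ontology conventions

* **Granularity level** (`termLevel`) is the *shortest* is_a path from
  the branch root: roots are level 0, their direct children level 1.
  A DAG admits several root-to-term path lengths and a single
  published "level" per term implies one canonical value; the minimum
  matches the usual GO convention and is what `levelHistogram()` bins.
* **Relations.** Default traversal uses is_a only. part_of is honored
  where a query explicitly asks for it; the one place it is on by
  default is `diseasesForCCTerm()`, because a cellular-component
  query for, say, an organelle should also collect complexes that are
  part of it. Both modes are exposed.
* **Placeholder roots.** The three branch roots
  (GO:0008150/GO:0003674/GO:0005575) are annotation placeholders, not
  biology; readers drop rows naming them, containers refuse them, and
  `rollupGO()` stops below them.
* **Obsolete terms** are dropped from traversal with a warning rather
  than an error: files in the wild routinely carry them and a hard
  failure would make every real ontology unreadable.
* **Evidence codes** are accepted by default with an allow-list
  option (`evidenceAllow`), since no code set is universally excluded;
  taxon filtering is likewise a caller-supplied allow-list rather than
  a taxonomy resolver, keeping the package free of a taxonomy-database
  dependency.

## The synthetic-data generator

`simulateBundle()` emits every dialect the readers consume — OBO
ontology, gene2go annotations, CTD-style gene-disease, chemical-gene,
chemical-disease and gene-gene tables, and a disease hierarchy with
slim categories — together with a `ledger.json` stating the planted
ground truth, so every downstream result can be checked against what
was actually planted.

What it emulates, and the defaults it uses:

* a three-branch DAG with a deep, broad biological_process branch
  (250 BP / 40 MF / 40 CC non-root terms, depth 6) and occasional
  double parents, so closures meet real diamonds; part_of edges occur
  only in CC;
* gene-first annotation sampling with preferential attachment to
  mid-depth terms (Gaussian weight over levels). Uniform sampling
  would concentrate mass at whatever level has most terms and make
  every granularity-level analysis degenerate; mid-depth weighting
  reproduces the familiar pattern that most annotation sits at
  intermediate specificity. Background genes draw a Poisson number of
  annotations (mean 6, floored at 1), split 60/20/20 across BP/MF/CC;
* background diseases with 4–28 curated genes (mean near 16) drawn
  from a shared background pool, so background pairs often share genes
  and are removed by the disjoint-gene filter — exactly the nuisance
  structure the filters exist for;
* **planted pairs**: each of the 5 planted disease pairs gets two
  equal-sized (11–16 gene) *disjoint* gene sets reserved from the pool
  before any background sampling, and a pair-specific pool of 20
  mid-depth BP terms to which each planted gene is annotated with
  probability 0.8. Gene disjointness is guaranteed by construction
  (partitioning, not rejection), so planted pairs always survive the
  disjoint-gene filter, match on gene parity, and share most of their
  term pool;
* dialect chaff the readers must filter: NOT-qualified rows,
  non-target-taxon rows (on dedicated genes so taxon filtering never
  changes the inference result), branch-root placeholder rows, exact
  duplicates, and no-evidence "inferred" gene-disease rows;
* `plantRepositioningScenario()` plants the repositioning benchmark
  directly: 2 anchor chemicals therapeutic for both diseases, 28/39
  disease-specific chemicals, a 277-gene anchor-intersection
  reference, exactly 4 candidates with coverage strictly above 50%
  (the rest strictly below, with a margin on both sides of the
  threshold so rounding can never flip a flag), and a 320-term shared
  GO-BP set of which 307 are annotated to reference genes.

Randomness is organised as one stream per output file, each seeded
deterministically from (master seed, file tag), so adding an output
file to the generator never perturbs the files that already existed,
and identical config + seed gives byte-identical trees (the RNG kind
is pinned explicitly).

What the generator does **not** emulate: real term names or MeSH
labels, literature provenance, evidence-code biases, the long-tailed
curation depth of real databases (where one disease can have thousands
of genes), or annotation correlation between related genes. Passing
the planted-recovery tests therefore shows the machinery is correct
and well-calibrated for detectable effect sizes; it does not show that
real curation data contains such clean structure.

## Numerical and degenerate-input choices

* Jaccard on two empty sets, percentages of an empty term set, an
  empty reference gene set, and an empty disease set for binning are
  *errors*, not NaN — each is an undefined quantity a caller should
  see, not propagate.
* Percentages are displayed at integer precision (via `round`) but
  stored at full precision in the matrix.
* The pair matrix stores each unordered pair once with
  diseaseA < diseaseB lexicographically; for *n* eligible diseases it
  has exactly n(n−1)/2 rows. (Counted this way a published figure of
  9,063,154 pairs for 4,258 diseases is one more than
  $\binom{4258}{2}$ = 9,063,153; the package documents and uses the
  combinatorial count.)
* All sorting that reaches output files uses radix order (C locale),
  so bytes do not depend on the session locale.
* Tie-breaks are always stated and total: comparator ranking uses
  (jaccard desc, shared terms desc, id asc); candidate ranking uses
  (coverage desc, chemical id asc); conflicting display names for one
  identifier resolve to the lexicographically smallest, with a
  message.
* A disjoint gene-identifier space between annotations and curations
  yields an empty inference set with a *warning*, because it almost
  always means an id-mapping failure rather than empty biology.

## Problem sizes in the shipped tests

The suite exercises: the inference join against a triple-nested-loop
oracle on 200 random bipartite instances (≤ 80/60 edges); the
hypergeometric tail against exhaustive subset enumeration for every
valid table with N ≤ 12; planted-pair recovery over 20 generator
seeds (5 planted pairs against 50 background diseases each, all
planted pairs required in the Jaccard top-10 in at least 19 of 20
seeds); the repositioning benchmark at its full planted size (277-gene
reference, 69 chemicals); and 1,000 random set pairs for Jaccard's
symmetry and bounds. These sizes give each property enough random
instances to be meaningful while keeping the whole suite near a
minute on one CPU.

## Known limitations

* The OBO reader covers the tags this pipeline needs (id, alt_id,
  name, namespace, is_a, relationship: part_of, is_obsolete); it is
  not a general OBO 1.4 implementation (no intersection_of, no
  typedefs, no regulates reasoning).
* Gene identity is keyed on the numeric gene id when present, else
  the symbol; no cross-species orthology or id-history resolution is
  attempted.
* The pair matrix is built in memory with per-pair set operations;
  it is comfortable to a few thousand eligible diseases (millions of
  pairs) but is not engineered for database-scale joins.
* The multi-set chi-square construction is one defensible layout
  among several; it is exposed as data (`overlapContingency()`) so a
  different construction can be tested without touching the test
  itself.

## A worked miniature

```{r example}
res <- runSimulate("planted-pairs", seed = 7, outDir = tempdir())
ann <- readGene2GO(res$files[["gene2go"]], taxa = 9606)
gd  <- readGeneDisease(res$files[["gene_disease"]])
inf <- inferGODisease(ann, gd)
inf

rec <- filterGeneParity(filterDisjointGenes(buildPairMatrix(gd, inf)))
head(rec[order(-rec$jaccard),
         c("diseaseA", "diseaseB", "nSharedGenes", "nSharedGo",
           "jaccard")])
```

The top-ranked pairs are the planted ones recorded in
`res$ledger$plantedPairs`: diseases that share no curated gene yet
overlap heavily in inferred biological processes.
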