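---
title: "Methods: the bHLH domain survey pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bHLH domain survey pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhscan)
```

## The motif model

Basic helix-loop-helix (bHLH) transcription factors share a roughly
60-residue domain: a DNA-binding basic region followed by two amphipathic
helices separated by a loop of variable length. `bhlhscan` identifies the
domain with a degenerate consensus written as an ordered token list

```
+ + X(3-6) E + X R X(3) a N X(2) f X(2) L + X(5-22) + X(2) K X(2) d L X(2) A d X Y a X(2) L
```

where `+` is K or R, `a` is I/L/V, `f` is F/I/L, `d` is I/V/T, named
residues are invariant, `X` is any residue, and the two `X(i-j)` runs are
variable-length spacers. The 19 non-wildcard tokens are the diagnostic
sites. A placement of the motif on a sequence fixes a start position and
both spacer lengths; its score is the number of diagnostic sites whose
residue falls outside the allowed set. A sequence whose best placement has
at most nine mismatches is called a putative bHLH domain. With minimal
spacers the motif spans 44 residues, with maximal spacers 64.

```{r}
bhlh_consensus()
```

The nine-mismatch budget is the classical acceptance rule for this
consensus. The survey literature also describes accepted domains as having
"more than 10 conserved amino acids", which taken literally would imply a
budget of eight; we treat at most nine mismatches as the operative rule and
expose it as the `max_mismatch` argument so a stricter cutoff is one
keystroke away.

### Best placement, ties and overlap

The scanner enumerates every (start, spacer, loop) placement that fits.
Per start it keeps one placement, choosing by: fewest mismatches, then
shortest total match, then smaller first spacer, then leftmost start. The
sources never state how competing spacer expansions are resolved; this
ordering prefers the most parsimonious explanation of the data and is
deterministic. Surviving placements that overlap a better-scoring one by
more than half their span are suppressed, so a protein reports one hit per
domain while genuinely multi-domain proteins remain representable.

Residues outside the twenty canonical amino acids (B, Z, X, U, `*`) are
accepted as input but always count as mismatches: translated EST and
ab-initio gene-model proteins routinely contain ambiguity codes, and a
site whose residue is unknown cannot be claimed as conserved.

### Segmentation and binding diagnosis

An accepted placement is segmented into the four structural regions. The
basic region runs from the leading K/R pair through the three wildcards
after the invariant arginine (12 residues at minimal first spacer); helix 1
runs from the I/L/V anchor through the basic residue that precedes the
loop (9 residues); the loop is exactly the second spacer; helix 2 is the
remaining 18 residues. The regions tile the matched span contiguously, and
the loop interval always equals the loop spacer length — these two
invariants fix the split uniquely.

DNA binding is diagnosed structurally rather than by absolute position:
when the first spacer is at its maximum the invariant glutamate and
arginine sit at domain positions 9 and 12, the Glu-9/Arg-12 pair that
reads the CANNTG E-box. A hit is an `E-box-binder` when both invariants
match and at least one of the three basic-region K/R sites is present;
otherwise it is a `non-binder`, the configuration of the group D
antagonists that lack a functional basic region.

## Family classification

Accepted domains are assigned to the 45 recognised bHLH families
(supergroups A-F) by distance to one representative domain per family.
Alignment is anchor-based, not optimised: the 19 diagnostic sites of every
domain are pinned to 19 shared columns and spacers are right-aligned
against the following anchor, so the frame is at most 64 columns wide.
Distance is one minus column identity over gap-free column pairs. A query
takes the family of its nearest representative unless that distance
exceeds `orphan_threshold` (default 0.55): beyond roughly 55% domain
divergence, family identity under this scheme is no longer credible, which
matches how the published survey left two proteins as orphans.

Full Bayesian or maximum-likelihood tree inference over hundreds of
millions of MCMC steps is deliberately out of scope. The package instead
offers neighbor joining (`neighbor_joining()`, consistent on additive
distances) for desk-scale placement, and column-resampling bootstrap
support for assignments: columns are drawn with replacement, distances
recomputed, and support is the percentage of replicates in which the query
stays nearest to its assigned family. These supports quantify the
stability of the distance assignment; they are not expected to reproduce
published likelihood bootstrap or posterior values, which are recorded in
the packaged catalog as data.

The packaged registry's representative domains are synthetic stand-ins:
the historical reference set is not distributed with the survey, so
representatives were generated once (seeded) to satisfy the package's
self-consistency contract — each passes the scanner with zero mismatches,
and families are mutually well separated (minimum inter-family distance
about 0.56 on the anchored frame). Every analysis that depends on specific
residues should supply its own registry file; the packaged one exists so
that classification, bootstrap and recovery experiments are fully
reproducible offline.

## Enrichment statistics

Term and pathway enrichment uses the upper-tail hypergeometric
probability: for a sample of `n` genes from a background of `N` of which
`K` carry a term, the P value of observing `k` or more carriers is
`P(X >= k)`, evaluated exactly in log space (`stats::phyper`). Multiple
testing is corrected with the Benjamini-Hochberg step-up rule pooled
across *all* tested sources together (KEGG, PANTHER, Reactome, GO in one
pool): with the published 16-row pathway table, only that pooling
reproduces the printed corrected column — for example, the Melanogenesis
row inherits the Jak-STAT row's adjusted value through the step-up
minimum. Results with at least one hit are retrieved at raw `P <= 0.5`
(the published retrieval default) and reported with the FDR-ready
corrected values; coherence is the percentage of the group's annotated
genes covered by the term, rounded to one decimal.

The background size `N` is a required modelling input (default 20000,
a conventional vertebrate gene count): the published analyses ran against
web-service backgrounds that were never stated, so their raw P values are
shipped as fixtures and are not recomputation targets. When an explicit
gene universe is supplied, sample genes outside it are excluded with a
warning; with only a size, the sample is taken at face value.

Recomputing the published corrected column from the *printed* raw P values
reproduces it to about 3e-7 absolute, not better: the printed inputs carry
seven-decimal rounding, and a raw-value perturbation of 5e-8 scales by up
to `m/j` under the step-up rule. The package's regression test asserts the
precision the printed inputs support.

## Interaction networks

Edge lists are confidence-filtered at 0.15 (the published STRING
exploration default). The confidence scale is never auto-detected — scores
are 0-1 unless `string_scale = TRUE` maps 0-1000 down — because a silent
misread would discard or keep entire networks. Duplicate and reciprocal
edges collapse to the maximum confidence; self-loops are dropped with a
warning. A hub is a node with at least five *distinct* interaction
partners (degree counts neighbours, never parallel edges), and family
modules are connected components of at least two nodes within each
family's induced subgraph. The published count of 68 hub proteins depends
on the live interaction database and is shipped as a labeling fixture, not
recomputed.

## Synthetic data and what passing tests mean

The generators produce every input with known ground truth under a single
integer seed (identical spec and seed give byte-identical files):

* **Proteomes** — planted proteins carry exactly one motif instance built
  token by token with a scheduled number of diagnostic violations inside
  uniform random flanks (10-30 residues by default); decoys are uniform
  random sequences. Certification uses the independent brute-force scanner,
  never the production scanner, so generator and scanner defects cannot
  cancel: schedules within the budget must be the globally best placement
  at the planted coordinates with exactly the scheduled count, schedules of
  10+ must leave no placement inside the budget anywhere, and decoys are
  re-sampled until their best placement carries at least 12 mismatches.
  Background residue frequencies are uniform over the twenty canonical
  amino acids.
* **Annotations** — planted terms are wired to overlap the study sample at
  `round(fold * K * n / N)` genes; null terms are uniform draws, so their
  overlap is hypergeometric by construction. Because the test is discrete,
  null P values are *super*-uniform rather than uniform, and the suite
  checks exactly that property (the 0.05 exceedance rate over seeds).
* **Networks** — hubs are wired to 5-8 distinct partners at confidence
  >= 0.15 while every non-hub stays at post-filter degree <= 4; labeled
  three-node cliques plant family modules; a noise block below 0.15
  exercises the filter.

Synthetic data emulates the *decision structure* of the survey — mismatch
budgets, enrichment folds, hub degrees — not the texture of real
proteomes: there is no homology between decoys, no compositional bias, no
fragmented gene models, and family divergence is uniform per site rather
than phylogenetic. Perfect recovery on these inputs therefore validates
the algorithms and their thresholds, not the biological error rate on a
real genome, which also depends on the upstream sequence databases the
original survey drew from.

## Problem sizes and numerical choices

The shipped tests run the scanner-oracle comparison on sequences of 44-80
residues, family recovery on 50 planted domains across the 45 families at
15% divergence, bootstrap support with 50-100 replicates, enumeration
oracles on urns of up to 12 genes and trees of up to 5 taxa, and pipeline
runs on bundles of about ten proteins and forty network nodes — sizes
chosen so the full suite exercises every contract in well under a minute
of compute. Distances live in [0, 1] with exact-0 self-matches;
distance ties resolve to the first family in registry order; P-value ties
sort stably by (p, source, term); and NJ tie-breaking is delegated to the
standard `ape::nj` agglomeration, which is deterministic for a given
input order (topology is input-order invariant on additive matrices,
which the suite checks).

## Known limitations

* The anchored alignment assumes every input is a full-span matched
  domain; arbitrary protein fragments must pass through the scanner first.
* Bootstrap support saturates at 100% for registry self-matches and is
  only informative near the orphan threshold.
* The enrichment module applies annotations as given: there is no GO-DAG
  ancestor propagation, matching the survey's use of deepest-layer terms.
* Published support markers ("n/m", "n/m*") and the per-group
  "enriched genes" column are preserved verbatim in the fixtures but are
  documentation, not inputs to any computation; known internal
  inconsistencies of the printed tables (per-group totals, rows above the
  stated significance cutoff, one duplicated accession) are preserved and
  flagged rather than resolved.
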