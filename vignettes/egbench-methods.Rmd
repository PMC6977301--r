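---
title: "Curating and evaluating enhancer-gene interaction benchmarks"
author: "egbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and evaluating enhancer-gene interaction benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(egbench))
```

## The curation model

`egbench` builds labelled sets of candidate element-gene pairs from
experimental interaction evidence. The underlying model is enhancer-centric:
each *distal* regulatory element (more than 2 kb from every annotated TSS)
is a query, and genes are candidate targets.

**Positives.** For 3D-chromatin assays (ChIA-PET clusters, Hi-C loop calls,
capture Hi-C interactions), a link supports a pair when, in either
orientation, one anchor overlaps an element and the opposite anchor lies
within the promoter window (±2 kb, inclusive) of at least one TSS. If the
TSS-side anchor covers the windows of two or more distinct genes, the true
target cannot be resolved from the link alone; all its pairs are emitted
flagged *ambiguous*, and a pair only keeps the flag if every link
supporting it was ambiguous. For eQTL and CRISPR-perturbation evidence the
target gene is reported explicitly, so a positive simply requires the
element to contain the variant (or overlap the perturbed region); no
ambiguity arises. The assumptions are the assays' own: a looping contact or
a genetic association between an element's locus and a promoter is treated
as evidence of regulation, which is why each assay is kept as a separate
benchmark dataset rather than pooled.

**Negatives.** For each element appearing in a positive pair, every other
annotation gene whose nearest TSS lies within a dataset-specific distance
cutoff becomes a negative. The cutoff is the 95th percentile of the
dataset's positive-pair distances, so the negative space matches the reach
of the assay and the class imbalance is a property of the data, not of the
curator. Genes an element is ambiguously linked to are excluded from its
negatives in the ambiguity-stripped variant. A gene may be positive for one
element and negative for another; that is intended under the
enhancer-centric model.

**Distance convention.** Distance between an element and a gene is the gap
in bases between the element interval and the gene's nearest TSS, zero when
a TSS falls inside or immediately at the interval. The promoter-window test
is the inclusive form |TSS − nearest anchor base| ≤ 2000. Internally all
intervals live in `GRanges` (1-based, closed); BED-style inputs and outputs
are converted at the boundary.

## Tunable parameters

All curation constants live in one `CurationPolicy` object:

| parameter            | default | units | role |
|----------------------|--------:|-------|------|
| `promoterWindow`     | 2000    | bp    | half-width of the TSS window an anchor must reach |
| `negativePercentile` | 95      | %     | positive-distance percentile bounding negatives |
| `fixedRatio`         | 4       | —     | negatives per positive in fixed-ratio variants |
| `minNegatives`       | 4       | pairs | floor below which an element leaves fixed-ratio sets |
| `matchedRatio`       | 2       | —     | negatives per positive in matched subsets |
| `nDistanceBins`      | 5       | bins  | equal-occupancy distance quantile bins |
| `seed`               | 1       | —     | source of every random draw in curation |

Assay filters default to the conventions of the public releases they parse:
ChIA-PET clusters need at least 4 supporting reads (column 7), capture Hi-C
interactions need log(observed/expected) strictly above 10 (column 11),
loop lists are taken whole. Gene identifiers are version-stripped; mixed
chromosome naming ("1" vs "chr1") is normalised at parse time;
trans-chromosomal links are dropped with a count because distance, and
hence the negative rule, is undefined for them.

## Chromosome-balanced cross-validation

Randomised CV leaks information when nearby pairs share features: windows
overlap, signals are locally smooth, and near-duplicate examples end up on
both sides of a fold split. `egbench` therefore groups *all* pairs of a
chromosome into one fold and balances fold sizes greedily: the
largest-count chromosome forms its own group, then the remaining
chromosomes, sorted by count, are repeatedly combined
current-largest-with-current-smallest. With `C` chromosomes carrying pairs
this yields `1 + ceiling((C-1)/2)` groups — 12 for the human autosomes plus
X. Ties in counts break by chromosome name and group labels are ordered by
descending size, making the assignment fully deterministic. For
cross-cell-type evaluation the test dataset inherits the training
assignment, so a model never scores pairs from a chromosome it trained on.
`randomCV()` deliberately re-implements the leaky randomised scheme for
side-by-side comparisons.

## Predictors

*Closest gene* assigns each element to the gene owning its nearest TSS
(lexicographic tie-break); *distance* ranks candidate pairs by 1/distance.
The two correlation methods score a pair by the Pearson correlation of
signal across a biosample panel: element accessibility against the
accessibility of the gene's TSS-proximal elements (maximised over the
gene's TSSs, optionally after averaging biosamples into cell-type groups),
or element accessibility against gene expression, choosing among
overlapping accessibility sites the one strongest in the focal biosample.
Pairs with no usable signal, or with zero-variance rows where the
correlation is undefined, receive a sentinel score of −100 so that they
still rank — below every finite correlation. *Average rank* combines two
score lists by the negative mean of their ranks (rank 1 = best, ties get
mean ranks). The supervised harness extracts mean track signal over the
enhancer, the promoter (nearest TSS ± window) and the intervening window
(zero when they touch), appends distance, and trains a gradient-boosted
classifier (xgboost) per held-out fold. The published defaults of this
model family — 4000 boosting rounds, learning rate 0.1, depth 5 — are kept
as defaults and are fully configurable; the examples and tests in this
package use far fewer rounds because their fixtures are small.

## Evaluation choices

Precision-recall curves place one threshold per distinct score, so all tied
pairs enter the confusion counts together and the curve does not depend on
an arbitrary ordering of ties. The area is the step-wise sum
Σᵢ (Rᵢ − Rᵢ₋₁)·Pᵢ without interpolation, since linear interpolation in PR
space is biased. Two analytic anchors follow from these choices and are
asserted in the tests: all-equal scores give AUPR equal to the positive
fraction (the random baseline), and a 1:4 fixed-ratio dataset pins that
value at 0.2 exactly. Percentiles use the nearest-rank convention (the
⌈p/100·n⌉-th order statistic) everywhere — it is reproducible across
platforms and has no interpolation ambiguity.

## The synthetic generator

`simulateAnnotation()` places genes on a jittered grid (default: 4
chromosomes × 4 Mb, 80 genes each, so one gene per 50 kb — the density of a
gene-rich locus) and relocates a configurable fraction (default 0.2) to
form divergent promoter pairs with TSSs under 4 kb apart, the mechanism
that makes real interaction anchors ambiguous. Elements (25 per
chromosome, 150-350 bp) are rejection-sampled strictly further than 2 kb
from every TSS, so all emitted elements are distal by construction.
`simulateLinks()` draws planted pair distances from a truncated log-normal
(default median 50 kb, log-sd 0.8, truncated at 1 Mb, echoing the
heavy-tailed distance distributions of real interaction data) by matching
each draw to the nearest available element-gene distance, then emits every
assay dialect around the planted pairs — including sub-threshold decoy rows
and links anchored in gene deserts that must never produce a pair. The
planted truth, ambiguity included, is computed by direct arithmetic on the
generator's own tables. `simulateSignalPanels()` gives genes broad and
elements sparse baseline activity across the biosample panel (mirroring the
observation that promoters and expression are far less cell-type-specific
than distal elements) and adds a shared latent activity component per true
pair, scaled by `coActivity`; log-scale Gaussian noise is applied last.
At `coActivity = 0` element and gene rows are independent, so correlation
scores must fall to the random baseline; at high strength true pairs are
recoverable. Everything is deterministic under the master seed, to the
byte, for the emitted files.

What the generator does *not* emulate: real sequence content, read-level
noise, assay-specific artefacts (self-ligation, bait bias), uneven gene
density, or correlated activity between neighbouring genes. Passing tests
on fixtures therefore demonstrate that the machinery implements its rules
exactly and that the statistical behaviour (baseline equalities, planted
signal recovery, CV-leakage inflation) is as designed — not that any
predictor will reach a particular accuracy on real data.

## Numerical and design notes

- Zero distances are capped at score 1 in the distance method; curated
  pairs cannot reach distance 0 (elements are distal), so the cap only
  guards degenerate inputs.
- A pair requires the element anchor and the TSS anchor to be *different*
  anchors of a link; the same-anchor case is excluded to avoid
  self-ligation-like artefacts.
- Positives further than the negative cutoff are retained as positives but
  spawn no negatives; discarding evidence-backed positives seemed wrong,
  and the negative rule keys on the cutoff only.
- Fixed-ratio sampling is per element: an element is dropped when its
  eligible negatives cannot reach `fixedRatio` per positive (at least
  `minNegatives`), which makes the retained ratio exact.
- The ambiguity-stripped variant recomputes the distance cutoff from the
  remaining positives — it is a dataset in its own right, and its negatives
  exclude, per element, the genes that element was ambiguously linked to.
- The candidate-gene universe for negatives is whatever the TSS index
  holds; build it with `proteinCodingOnly = TRUE` to restrict to coding
  genes. An explicit `exclude` list stands in for "problematic annotations"
  a user may wish to drop, rather than a hard-coded guess.
- eQTL column layouts differ by release, so dialects are data
  (`eqtlDialect()`), with GEUVADIS- and GTEx-style presets.
- The cell-type grouping used by the group-averaged correlation method is
  an input (`signalMatrix(values, groups)`), not a bundled table.
- Window features use per-base means (not sums) over regions clipped at
  chromosome bounds.

## Problem sizes

The test suite and the worked examples run on the generator's default
scale — toy genomes of 4-6 chromosomes, tens of elements and links,
signal panels of 32 biosamples, 10 seeds for the stochastic checks and
supervised models at 40-60 boosting rounds. These sizes were chosen so the
full suite exercises every code path, including the statistical
properties, in well under a minute per file; all of them scale up through
`simulationConfig()` and the learner arguments.

## Limitations

The package curates and evaluates; it does not call loops, map eQTLs, or
derive element activity from raw signal. AUPR values published for
benchmark datasets built from the real public releases depend on those
releases' exact versions and on the AUPR integration convention; the
step-wise convention here may differ in the last digits from
interpolation-based tools.
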