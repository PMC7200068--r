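---
title: "Detecting coincident gene families in pangenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting coincident gene families in pangenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copresence)
```

## The model

`copresence` treats a pangenome as a binary incidence matrix: `N` genomes
by `F` gene families, cell 1 when the family has at least one member in
the genome. Two questions are asked of every pair of accessory families.
In **association** mode: are the two found in the same genome more often
than their marginal frequencies predict? In **dissociation** mode: are
they found in different genomes more often than predicted? With
`P_i = N_i / N`, the expected association rate is `E_A = P_i P_j N`
against the observed co-occurrence count `N_ij`, and the expected
dissociation rate is `E_D = [P_i(1 - P_j) + P_j(1 - P_i)] N` against the
observed exclusive-presence count `N_i + N_j - 2 N_ij`. Both comparisons
use a one-sided upper-tail binomial exact test with `N` trials and the
expected per-genome rate as success probability: the alternative is always
"more often than expected", which is the directional question the method
poses. Two-sided or mid-p constructions would answer a different question
and are deliberately not offered.

The binomial model treats genomes as independent trials. Genomes are not
independent — they are related by the phylogeny — and the package does not
try to fold that dependence into the test. Instead, phylogenetic structure
is quantified separately, per gene, by the D statistic (below), and
reported alongside every coincident gene so that the user can discount
pairs whose coupling is plausibly explained by shared ancestry. The two
calculations are deliberately independent of one another.

### Multiple testing

All `C(F', 2)` pairs of retained families are tested; a pair is significant
when its raw p-value is at most `alpha / T`, where `T` is the number of
pairs actually tested after filtering — that is the family of hypotheses
actually evaluated, and `T` is echoed in every output header so the
correction can be audited. `alpha` defaults to 0.05. Bonferroni is
intentionally blunt: with hundreds of thousands of pairs it keeps the
family-wise false-positive rate at or below `alpha`, at the cost of power
against weak couplings. No FDR alternative is offered in this version.

### Pre-processing

Core families (`N_i = N`) cannot associate or dissociate with anything and
are removed. Families below the prevalence cutoff (default 5% of genomes,
strict inequality: a family in exactly 5% is retained) cannot reach
significance and are removed; families absent everywhere are always
dropped. The matrix and tree are first restricted to their shared genome
set — reconciliation runs before filtering, so `N` and every `N_i` refer to
the genome set on which both the pairwise tests and D are computed. Doing
the cull first would let genomes absent from the tree decide which
families survive, while their presence values never enter any statistic.

## The D statistic

For a binary trait on the tips of a rooted tree, each internal node gets a
nodal value equal to the unweighted mean of its children's values
(polytomies average over all children), computed tips-to-root; branch
lengths are ignored in this estimate. `d_obs` is the sum over all edges of
the absolute child-minus-parent difference. This sum is small for
clade-confined traits and large for dispersed ones; on the four-tip
balanced tree the clade-confined arrangement gives exactly 1.0 and the
checkerboard 2.0.

`d_obs` is scaled between two null expectations, each estimated from
`n_perm` replicates (default 1000):

- **tip shuffle**: trait values permuted uniformly across tips, prevalence
  preserved — no phylogenetic signal, anchors D = 1;
- **Brownian threshold**: a continuous character simulated along the tree
  (independent normal increments per edge, variance equal to branch
  length; unit lengths substituted when the tree has none), with the
  `sum(trait)` largest tip values set to 1 — Brownian-strength clumping,
  anchors D = 0. Assigning exactly the observed number of presences, ties
  broken by the seeded RNG, guarantees both nulls condition on the
  observed prevalence.

D may fall below 0 (clumping stronger than Brownian) or above 1
(overdispersion). When the two null means are closer than 1e-9 — possible
on pathological trees — D is undefined and reported as `NA` with a
warning rather than as an arbitrary number. D is never thresholded by the
package: it annotates nodes in the tables, sizes them in the GEXF, and
orders heatmap columns.

Scoring runs only for genes that appear in significant pairs (the
`d_all` flag scores every retained gene instead), since D is the expensive
step: each gene costs `2 * n_perm` tree traversals. Traversals are
vectorised across replicates, so a 200-tip tree at `n_perm = 1000` costs
roughly 0.15 s per gene on one core. Per-gene sub-seeds are drawn from the
master seed over the sorted gene list, making results byte-identical for
any worker count.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | family-wise error target of the Bonferroni correction |
| `cutoff_fraction` | 0.05 | minimum prevalence fraction; strict "less than" removal |
| `n_perm` | 1000 | replicates per D null; Monte-Carlo SE of each null mean scales as `1/sqrt(n_perm)` |
| `seed` | 1 | master seed; all sub-seeds derive from it |
| `workers` | 1 | forked parallelism over pairs and genes; never changes results |
| `panel_size` | 100 | gene columns per heatmap file; files = `ceil(genes / panel_size)` |

## The synthetic-data generator

`simulate_matrix()` exists so that every stage is testable without any
external dataset. It emulates the statistical structure the test assumes:
background families drawn independently per genome (`clumping = "iid"`,
presence probability 0.5 by default — a maximally informative prevalence
for pairwise tests) or by thresholding a Brownian character on the tree
(`clumping = "brownian"`, emulating lineage-dependent genes). Planted
associating pairs copy the anchor's presence vector, dissociating pairs
complement it, and a symmetric per-genome flip probability `epsilon`
decouples partner from anchor; coupling by copy-plus-noise rather than a
joint distribution keeps the ground truth unambiguous and the marginal
prevalences controllable. Trees come from `random_tree()`, a seeded
coalescent (`g0001…` tip labels). All randomness flows from one master
seed through named substreams, so the background block is identical
whether or not pairs are planted.

What the generator does **not** emulate: gene gain/loss along the tree
with realistic rate variation, horizontal-transfer networks, pangenome
openness (a realistic U-shaped gene-frequency spectrum), annotation
error, or correlated blocks larger than pairs. Passing the planted-signal
tests therefore demonstrates that the statistics recover the couplings
they model, under independence of everything else — not that real
accessory genomes satisfy those assumptions.

## Validation studies and problem sizes

The test suite fixes these study conditions (chosen once, as the scales at
which the method's properties are cleanly measurable on a desktop):

- **exactness**: every feasible `(N <= 25, N_i, N_j, N_ij)` configuration
  — 23,750 of them — in both modes against an exact integer-arithmetic
  tail oracle, at 1e-12 relative tolerance;
- **error control**: 20 independence-null matrices of 100 genomes x 500
  genes; the fraction with any significant pair stays within one-sided
  binomial tolerance of `alpha`;
- **power**: 10 planted pairs at `epsilon = 0.05` among 500 background
  genes and 200 genomes are recovered at >= 9/10 in both modes; with 40
  pairs at `epsilon = 0.2` the significant-pair count rises strictly
  through 50 → 200 → 400 genomes, with (near) zero at 50 — an effect size
  chosen by analytic power calculation to straddle the detection boundary
  at 200 genomes;
- **D calibration**: on a 200-tip tree with `n_perm = 1000`, the mean D of
  50 tip-shuffled traits lands within 0.15 of 1 and of 50
  Brownian-threshold traits within 0.15 of 0.

`scripts/acceptance.R` re-runs exactly these studies from a user-supplied
seed and writes the measured quantities as JSON.

## Numerical and formatting choices

- Binomial tails are summed in log space shifted by the largest term, so
  p-values are accurate to ~1e-14 relative error across their full range;
  values below ~1e-300 underflow to 0, and the GEXF edge-thickness map
  floors p at 1e-300 before taking logs.
- Pair enumeration is lexicographic by family identifier; output is sorted
  by ascending p, then identifiers. Ties and orderings are deterministic
  everywhere (undefined D sorts last in heatmaps, ties lexicographic).
- Edge thickness is monotone in `-log10(p)`: thickness literally
  proportional to p would make the strongest edges invisible;
  `edge_width_raw_p` restores literal proportionality for users who want
  it. Node size is an affine map of D over its observed range
  (constant when all D are equal; never clipped, since D can be negative).
- Heatmap rows follow the tip order of the tree ladderized with ape's
  `right = TRUE` convention (largest clades drawn last); the same order is
  exposed in `heatmap_spec()` so it can be verified without rendering.
- Components are numbered from 0 in decreasing size order, ties by
  smallest member identifier.
- The gene-list input dialect is `family<TAB>genome`, family first, no
  header; this is enforced, not inferred.
- Degenerate inputs degrade explicitly: zero retained families yield a
  zero-test run (exit 0 at the command line), an invariant trait is an
  error for D, and identifiers containing tabs are rejected at read time
  so every TSV output stays parseable.

## Known limitations

Only pairwise coincidence is tested — no triplet or higher-order motifs,
and no effect-size model beyond observed/expected. Bonferroni is the only
correction. The binomial null ignores phylogeny by construction; D is a
diagnostic, not a correction, and carries Monte-Carlo noise of order
`1/sqrt(n_perm)`. The D construction follows the published
nodal-averaging recipe but is validated here by its calibration anchors
rather than by numerical equivalence to any particular legacy
implementation. Heatmaps are static PDFs intended for inspection, not
publication-quality figures.
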