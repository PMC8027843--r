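---
title: "Joint junction balancing of post-crisis clone compendia: models and methods"
author: "crisisgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint junction balancing of post-crisis clone compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisisgraph)
library(dplyr)
```

## The problem

Cells that pass through telomere crisis and re-emerge as stable clones carry
the scars of the escape: breakage-fusion-bridge (BFB) amplification with its
stepwise, power-of-two-like copy-number staircase and fold-back inversion
junctions; chromothripsis with oscillating interspersed losses; whole-arm
losses; and stabilizing translocations that capture a telomere from a partner
chromosome. When many clones are derived from the same crisis, they share
parts of one rearrangement lineage, and analyzing each clone in isolation
wastes that structure.

`crisisgraph` implements a joint analysis of such clone compendia built
around **junction-balanced genome graphs**. A genome graph has one vertex per
genomic segment (each with a reverse-complement partner) and three classes of
edges: *reference* edges between genome-adjacent segments, *variant* edges
from rearrangement junction calls, and *loose* edges — slack ends that absorb
copy-number changes no junction explains. The stoichiometric constraint is
that every copy of every interstitial segment has a left and a right
neighbor: its copy number equals the copy-weighted sum of incident edges on
each side (fold-back junctions, which pair a segment end with itself, count
twice).

## The joint balance program

All clone graphs are replicas of a shared *prototype* graph built from the
disjoint refinement of every clone's breakpoints and the pooled (exactly
deduplicated, optionally window-merged) junction calls; the projection *p*
maps each clone element to its prototype element (on replicas, the identity
on ids). Given binned read depth $x^i$ (already in copy-number units) and
per-clone edge bounds $u^i$ (a variant edge is open in a clone iff it has
read support there), the package solves

$$\min_{\kappa^i}\;\; \lambda\, R + \sum_i V(G^i, \kappa^i, x^i)$$

subject to, in every clone: reverse-complement symmetry, integer junction
balance at every interstitial side, and $\kappa^i(e) \le u^i(e)$. The
complexity penalty $R$ counts the number of **unique prototype loose ends**
with nonzero total copy across the compendium — an $\ell_0$ penalty that
makes clones share unexplained ends rather than buy one each. The residual
$V$ is the bin-count-weighted squared error between per-segment mean depth
and integer copy:
$V = \sum_v w_v (\bar x_v - \kappa(v))^2$ with $w_v$ the number of bins
mapped to segment $v$. This quadratic, bin-weighted form is this package's
fixed choice for the residual (an L1 flavor would also linearize; the
weighted-L2 form matches the Gaussian noise model of corrected read depth).
The single-sample fit is the $n = 1$ special case with a per-copy slack
penalty on loose edges (default 500; 100 is the documented alternative for
noisier, less clonal material) instead of the shared $\ell_0$ term;
$\lambda$ defaults to 100.

### How it is solved, exactly

No general mixed-integer solver is assumed. The package carries its own
exact optimizer, structured around the problem:

* the quadratic residual is linearized **exactly at integer points** with
  convex unit-step columns (the marginal cost of the $t$-th copy of a
  segment is $w_v[(t-\bar x_v)^2 - (t-1-\bar x_v)^2]$, increasing in $t$),
  so LP relaxations are the convex envelope and never cut off an integer
  optimum;
* a bounded-variable two-phase simplex (C++/Armadillo) solves the LP
  relaxations; branch-and-bound on the integer copy variables closes the
  (rare, fold-back parity-induced) fractional gaps;
* the joint $\ell_0$ term is handled by an outer branch-and-bound over
  prototype loose ends. At each node a set $X$ of loose ends is closed and
  the clones decouple into independent integer programs; the node bound is
  $\lambda|F| + \sum_i \min V_i(X)$ where $F$ is the set of loose ends
  branched into the solution. Each per-clone subproblem is solved twice:
  first for the minimum residual, then for the minimum loose usage at that
  residual, which keeps bounds exact without tie-breaking penalties.
  Solutions are cached and reused across nodes when a closed loose end was
  never used.

The solver is deterministic; within a node, ties between equal-objective
integer optima are resolved by the (deterministic) pivoting order rather
than by an explicit lexicographic refinement of the copy vector. The
outer search carries a node budget (`outer_node_limit`, default 200):
on clean instances optimality is proven well within it, and every
exhaustive-oracle comparison in the test suite runs to proven optimality.
Under depth noise, however, a loose end can often be moved to a
neighboring side for a near-zero residual cost, which makes the
fixed-charge lower bound weak and lets the proof phase wander through
near-tied alternatives; the search then stops at the budget and returns
the incumbent flagged `"feasible"` (the anytime contract the
configuration's status field exposes). The incumbent at that point is the
minimum-residual, minimum-loose-usage solution refined by the explored
branches, and its accuracy is what the recovery tests measure. A node
budget rather than a wall-clock limit keeps results machine-independent.

## Walks and allele reconstruction

Given a balanced clone $(G^i, \kappa^i)$, the subgraph with nonzero copy is
exhaustively traversed for **minimal walks**: vertex-simple paths between
end sides (nonzero loose ends or chromosome termini) and vertex-simple
cycles, canonicalized so a walk and its reverse complement are one object.
"Minimal" is read as *no oriented vertex revisited*; this is a deliberate
interpretation — unrestricted walk enumeration is infinite, and alleles
that revisit segments (deep BFB stages) are reachable by combining minimal
elements. A second integer program assigns copy numbers $\phi^i(h)$ to
walks so that copy-weighted membership reproduces $\kappa^i$ exactly in
every clone, minimizing the number of **unique walks** across the
compendium (walks are identified across clones by their projected element
sequence). Finally, `combine_walks()` splices cycles into paths at shared
anchor vertices. The combination step is configuration-driven on purpose:
the analysis it reproduces treated walk combination as a curated, manual
step, and an explicit merge table keeps that step logged and replayable
rather than silently automated. On simulated BFB clones, splicing the
fold-back cycle into the derivative path reproduces the planted allele's
element sequence exactly (this is asserted in the test suite).

## Depth screening and clustering

Low-pass screening aggregates 1-kbp depth to 10-kbp bins by the median
(`collapse_bins()`), masks windows whose per-window sd/mean exceeds 0.3 in
more than 10% of the cohort (population sd, divisor $n$, for determinism;
a reference cohort may supply the mask), and clusters clones on genome-wide
Euclidean distance with Ward linkage in its `ward.D2` form — Ward applied
to unsquared Euclidean distances with squaring inside the update; the
`ward.D`/`ward.D2` distinction matters and the latter is the documented
choice. The number of clusters is a parameter (`k = 6` by default): the
analysis this follows chose six after dendrogram inspection, a manual step
this package does not automate.

## SNV phylogeny

Somatic SNVs pass hard filters (caller PASS, mapping-quality flag, caller
score > 12, total ALT count > 4) and are then called present per clone by a
two-component binomial mixture: ALT count $\sim \mathrm{Bin}(d, 0.5)$ under
presence (clonal heterozygous VAF in 100% pure, near-diploid clones) or
$\mathrm{Bin}(d, 0.001)$ under absence (sequencing error), with the site's
aggregated allele frequency across clones as prior and a 0.5 posterior
cutoff. The absence component is this package's declared reading — the
procedure it follows states the presence likelihood and prior only. The
binary clones-by-SNVs matrix yields Hamming (symmetric-difference) distances
— additive under a no-recurrence accretion model; which distance the
original procedure used is not stated, and Hamming is the natural additive
choice — and a classical neighbor-joining tree (via `ape`). Each SNV is
assigned to the branch whose clone-incidence vector is nearest in Jaccard
distance (both orientations of each unrooted edge considered), only when
that distance is < 0.1. Runs of ≥ 2 SNVs closer than 2 kbp are nominated as
kataegis-like clusters.

## Haplotype phasing

Parental heterozygous sites are loci with parental VAF strictly in
(0.3, 0.7) at depth ≥ 10 (the depth floor is this package's stabilizer; the
source procedure used curated polymorphism panels without a stated cut).
A clone with single-allele arm loss anchors phasing: per site, the allele
with zero reads in that clone is the lost (L) haplotype, the other is
retained (R); sites without exactly one zero allele stay unphased and are
flagged. Allelic counts across clones divided by a per-clone normalizer
(mean single-allele het count) give absolute allelic copy number. At desk
scale the simulated genome is small enough that engineered events are a
substantial fraction of it, so the examples compute the normalizer from
copy-neutral territory away from the events — the small-genome analog of a
genome-wide mean over an almost entirely diploid genome.

## Loose-end telomere screen

Mates of high-mapping-quality reads anchored at a loose end are scanned for
a telomere repeat motif set: all distinct cyclic rotations of
`TTAGGGTTAGGG` plus reverse complements. The 12-bp doubled motif has period
6, so there are 6 distinct rotations (12 with complements); the motif set
is configuration-driven because descriptions of this screen differ on the
count. A loose end is a neo-telomere candidate only if enough mates carry
enough motif hits; the system this models showed none, and the simulator's
loose-end mates are correspondingly non-telomeric.

## The simulator and what it does (not) capture

`crisis_scenario()` defines the study conditions: a 120-Mbp chromosome
("chrA", p-arm `[0, 35 Mbp)`) and a 45-Mbp acrocentric partner ("chrB"),
13 clones on a binary lineage tree with four clades — two unrearranged
clones, an independent arm-loss clone, a chromothripsis clone (region
12–19.9 Mbp, 12 fragments, retention 0.5), an arm-loss clone inside the
rearranged clade, and an eight-clone BFB lineage accreting fold-backs at
9.0/9.5/9.7/9.8 Mbp, each leaf ending in a bridge truncation and (for six
of eight) a stabilizing fusion to the chrB q-arm, which appears as a
partner-arm gain. A 15-Mbp interstitial deletion on the stable side of the
rearranged haplotype marks the rearranged clade. All events hit the L
parental haplotype. Rearrangement breakpoints sit on the 10-kbp depth-bin
lattice so that zero-noise bins are exactly integer; event loci are spaced
so that distinct true loose ends are farther apart than the residual cost
of merging them at `lambda = 100` — the regime in which the planted
configuration is also the program's optimum, which is what the recovery
tests assert.

Emission: depth per 10-kbp bin is Gaussian around total copy (sd 0.15 by
default, truncated at zero) — noise is Gaussian in copy-number units
because the pipeline consumes *corrected* depth, not raw counts; junction
support is Poisson (mean 10, floored at 1) with per-clone dropout;
per-branch SNVs (250 per branch by default) get Poisson depth (mean 40)
and binomial ALT counts at VAF 0.5 off the rearranged arm and
copy-adjusted on it; phased het SNPs every 2 kbp (heterozygous-panel density) get per-allele Poisson
counts (or deterministic counts in the zero-error setting). Everything
derives from one seed and is byte-reproducible. Tree-branch SNVs are
placed off the rearranged arm so that lineage presence is not erased by
copy loss of the carrier allele; the three kataegis-cluster SNVs inside
the amplified focus are the deliberate exception. An optional
`presence_error` dial can flip biological presence states; it defaults to
0 — the emitted counts' sequencing error is the error source, and the
realized per-entry presence-calling error (measured in the acceptance
tests) stays well under 0.5%.

The simulator emulates the statistical structure the pipeline assumes —
segmental copy number, junction support, SNV accretion, allelic imbalance —
not sequence-level realism: no reads, no alignment artifacts, no
mappability structure, no replication timing, no selection. Passing tests
therefore validate the inference machinery against its own generative
assumptions; they do not certify performance on real sequencing data,
where depth correction and junction calling quality dominate.

## Problem sizes and numerical choices

The worked compendium is 13 clones over a ~30-segment prototype with an
integer cap near 20 — the scale at which exact branch-and-bound proves
optimality in seconds to a few minutes on one core. Exhaustive-oracle
cross-checks run on randomized compendia of up to 4 prototype segments,
2 variant edges, 3 clones, and copy cap 4, where full enumeration is
tractable. Simplex tolerances are 1e-7 on reduced costs and feasibility
and 1e-9 on pivots; integrality tolerance is 1e-6; Bland's rule engages
after a run of degenerate pivots to preclude cycling. Depth bins are
assigned to segments by midpoint; zero-bin segments carry zero residual
weight and are reported. Degenerate inputs (zero-depth SNV entries,
zero-mean depth windows, priors at 0 or 1, all-zero SNV columns,
negative NJ branch lengths) are clamped or flagged rather than silently
dropped, as documented on each function.

## Known limitations

* The joint program is exact but exponential in the worst case; very
  junction-dense prototypes need region restriction (as does the walk
  enumerator via `max_walks`).
* Loose ends are modeled at every interstitial segment side; the cost of a
  spurious loose end is governed entirely by `lambda`/`slack_penalty`, and
  small events spanning few bins can legitimately be flattened instead of
  explained — the staircase of penalties is the model, not a bug.
* Purity/ploidy transformation, GC/mappability correction, junction
  calling, and read realignment are upstream of this package and are taken
  as given.
* The walk combination step reproduces curated reconstructions; it does
  not search over alternative splicings.
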