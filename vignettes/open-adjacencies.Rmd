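---
title: "Detecting simultaneous rearrangements with open adjacencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting simultaneous rearrangements with open adjacencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(openadj)
```

## The model

Somatic structural variation in a cancer genome is modeled as a sequence of
*k*-breaks applied to the reference genome: each event cuts the genome at
*k* locations and fuses all 2*k* resulting free ends in some aberrant
configuration. A 2-break is the classical double-cut-and-join operation
(translocation, inversion, or excision of a circle whose loss is a
deletion); chromothripsis and chromoplexy — tens of breakpoints acquired in
one catastrophic event — correspond to *k*-breaks with *k* > 2.

Every break between nucleotides *n* and *n*+1 produces a pair of
*counterpart breakends* (*n*, +) and (*n*+1, −), where "+" marks the side
retaining the lower coordinates. A fused pair of breakends is an
*adjacency*. The model makes two assumptions: breakpoints are never reused,
and all breakends are fused (no new telomeres; new circular chromosomes are
allowed).

Under these assumptions an adjacency {x, y} created by a 2-break is
*closed*: its counterparts x′ and y′ had no other fusion partners
available, so {x′, y′} is also an adjacency. Adjacencies created by
(*k* > 2)-breaks are *open* — the counterparts went to other partners.
Counting open adjacencies therefore bounds, from below, the number of
adjacencies formed in simultaneous multi-break events.

Two observable signatures identify open adjacencies:

* **Counterpart-asymmetry.** If x's observed counterpart x′ is fused to
  some breakend w that is not y's counterpart, then {x′, y′} cannot exist
  (no breakpoint reuse) and {x, y} is open.
* **Copy-number asymmetry.** Define Δ(x) := N(x′) − N(x), the copy number
  on the counterpart side of the break minus the copy number on the
  retained side. Closed adjacencies always satisfy Δ(x) = Δ(y): after the
  fusion the two breakends are physically locked together and their copy
  numbers can only change jointly, while the counterpart pair {x′, y′} is
  likewise locked. Hence Δ(x) ≠ Δ(y) proves {x, y} open. The converse does
  not hold — an open adjacency may be copy-symmetric by coincidence.

The per-set summary statistics are

* **OAR** (open adjacency rate): the fraction of an adjacency set flagged
  open by either signature, `OAR = |O| / |A|`. With exact data it is a
  lower bound on the true (*k* > 2)-break adjacency fraction.
* **CAE** (copy-number asymmetry enrichment): `CAE = |C| / (2 p_Δ (1 −
  p_Δ) |A|)`, where C is the copy-asymmetric subset and p_Δ the fraction of
  the set's breakends with Δ ≠ 0. Treating Δ values as Bernoulli variables
  that are shared within 2-break adjacencies and independent within
  (*k* > 2)-break adjacencies, E|C| = 2 p_Δ (1 − p_Δ) |A^k|, so CAE is an
  unbiased estimate of the (*k* > 2)-break fraction that ignores breakend
  positions entirely — useful because adjacency sets are often *defined* by
  breakend clustering, which inflates position-based evidence.

## Tunable parameters

* `D` (bp, default 2000): maximum distance between counterpart candidates.
  In principle counterparts sit 1 bp apart, but breakpoint calls have
  finite resolution and small "deletion bridges" occur at junctions; 2 kb
  absorbs both. The convergent-orientation excess against the uniform 1/4
  null (`orientation_spectrum`, `convergence_enrichment`) is the empirical
  check that a chosen `D` still captures genuine counterparts;
  `sweep_orientation_spectrum` reproduces the distance-threshold curves.
* `L` (bp, default 10000): length of the breakpoint interval centered on a
  copy-number segment boundary. Segmentation boundaries are much less
  precise than split-read breakpoints, hence the wider window.
* `min_set_size` (default 15): adjacency sets smaller than this carry too
  little information for a stable rate and are dropped.
* `scope` (`"set"` or `"genome"`): whether counterpart evidence is
  restricted to the analyzed adjacency set or pooled across all sets of the
  input. Per-set is the default, matching how clustered event candidates
  are evaluated; genome-wide mirrors pooling all adjacencies of a genome.

## Numerical and design choices

* **Coordinates.** Positions are 1-based nucleotide indices internally; the
  (n, +)/(n+1, −) counterpart convention forces this choice. BEDPE input
  and output is converted at the I/O boundary (the breakend position is the
  end coordinate of its 1-bp interval).
* **Signed, orientation-aware Δ.** A matched boundary interval carries the
  sign of the left-to-right copy change; a "+" breakend receives that sign
  and a "−" breakend its negation, implementing Δ(x) = N(x′) − N(x)
  literally. This matters: with an orientation-blind step function every
  deletion adjacency (Δ = −1 at both ends) would appear copy-asymmetric.
  Magnitudes are collapsed to {−1, 0, +1} because absolute tumor copy
  number is unreliable; gains participate in p_Δ and in the asymmetry
  comparison even though the CAE calibration model assumes deletions only —
  a documented approximation.
* **Boundary intervals** are centered on the midpoint between the left
  segment's end and the right segment's start (the boundary's location is
  not specified more precisely by the segmentation); zero-change
  boundaries, chromosome ends, and gaps wider than `L` produce no interval.
  A breakend lying in two overlapping intervals is ambiguous and left
  unmatched, mirroring the unique-occupancy rule for intervals.
* **Matching ties.** Each breakend joins at most one counterpart pair.
  Conflicts can only arise through coincident breakends; candidates are
  accepted greedily, tighter pairs first, then in deterministic
  coordinate/uid order. Distance-first greediness keeps the accepted
  pairing monotone in `D`. Coincident convergent breakends (distance 0) are
  accepted: exact-resolution calls can coincide.
* **Asymmetry with an unmatched endpoint.** If x is matched to x′ (fused to
  w) while y has no matched counterpart, the adjacency is called
  counterpart-asymmetric: had w been y's true counterpart, the matcher
  would have paired them.
* **Small-group rank-sum tests** (`group_compare`) are computed by full
  enumeration of the permutation null (valid under ties) when the combined
  group size is at most 16; larger cohorts use the tie-corrected normal
  approximation. Correlations with external annotations use the Pearson
  test.

## The simulator

`simulate_history` applies a configurable sequence of k-breaks to linear
reference chromosomes. Cut sites are sampled uniformly over the retained
derivative genome; the fusion of the 2k free ends is a uniform perfect
matching conditioned on no counterpart re-fusion (otherwise the break would
be ineffective); circular products are lost with probability
`circle_loss_p` (default 1, so same-chromosome circle excisions read as
deletions). The probability law of cut placement and matching is a
simulator convention — the underlying rearrangement model does not
prescribe one.

Cut sites keep a minimum reference-coordinate spacing (default 6000 bp =
3 × the default `D`) between *all* cuts of a history. This guarantees that
on exact data counterpart matching has no spurious candidates and every
boundary interval has a unique occupant, isolating signature behavior from
resolution artifacts; setting `min_spacing = 1` disables the guarantee for
a harsher regime. `observe` derives the observable dataset: novel junctions
on retained chromosomes with per-adjacency truth labels (generating event
and its k), the true copy profile by base-coverage counting over a constant
homologue baseline (default 1, so single-copy losses read 2 → 1), optional
binomial detection dropout, and integer Gaussian positional jitter clipped
at ±3 sd.

What the simulator emulates: breakpoint sparsity, deletion-driven copy
changes, event mixtures with known (*k* > 2)-break fractions, detection
dropout, and finite breakpoint resolution. What it does not emulate:
sequence context (microhomology, repeats), breakage-fusion-bridge cycles,
subclonal mixtures, segmentation error in the copy profile, and false
positive adjacency calls. Passing the validation suites therefore
demonstrates correctness of the method under its stated assumptions, not
robustness to every failure mode of real tumor sequencing.

`bernoulli_cohort` generates the idealized endpoint-Δ cohorts of the CAE
derivation directly (shared Δ within 2-break adjacencies, independent Δ
within (*k* > 2)-break adjacencies, values in {−1, 0}), which is the right
ground truth for calibration of the estimator itself.

## Validation problem sizes

The shipped suites run at desk scale, chosen to make the checks sharp while
keeping the suite quick: 100 seeded exact histories mixing 2-breaks with
k ∈ 3..6 on two 1.5-Mb chromosomes for the closed-adjacency safety and
open-call soundness properties; CAE calibration over p_Δ ∈ {0.2, 0.5, 0.8}
× truth fractions {0, 0.25, 0.5, 0.75, 1} with 50 cohorts of 2000
adjacencies per cell (mean error below 0.05); 500 random instances of up to
200 breakends against brute-force oracles for matching and Δ assignment;
and a 20-vs-8-set cohort comparison (16 sequential 2-breaks per stepwise
set, one 25-break per one-off set, on three 3-Mb chromosomes) separated by
the rank-sum test at α = 0.01.

## Worked example

```{r toy}
bedpe <- system.file("extdata", "toy.bedpe", package = "openadj")
seg <- system.file("extdata", "toy.seg", package = "openadj")
fit <- openadj(bedpe, seg, min_set_size = 1)
fit
summary(fit)
```

The toy genome contains twelve adjacencies: an inversion pair, a deletion,
and three translocation-style closed pairs, plus one 3-break whose three
adjacencies are open by construction — recovered here as OAR = 0.25. The
deletion shows Δ = −1 at both endpoints and is correctly left closed.

## Limitations

OAR and CAE are local, per-adjacency measures: they gain robustness to a
single missing adjacency at the cost of ignoring the global configuration
of a rearrangement chain. Sparse detection depresses counterpart evidence,
so OAR is a lower bound, not an estimate; CAE inherits the deletion-only,
independence, and shared-p_Δ assumptions of its calibration model; and
intra-tumor heterogeneity (an event present in a fraction of cells) dilutes
both signals. Sets defined by breakend clustering can inflate
counterpart-based evidence, which is the motivation for reporting CAE
alongside OAR.
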