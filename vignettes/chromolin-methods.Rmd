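---
title: "Models and methods behind chromolin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromolin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromolin)
```

## The scientific problem

In slow-growing *E. coli*, the two chromosome arms occupy opposite cell
halves (left-*oriC*-right), replication extends this into a translationally
symmetric L-R-L-R arrangement of the sister chromosomes, and — because
lagging-strand templates are directed toward midcell while leading-strand
templates face the poles — the sister chromosome carrying the older
("ancestral") template strand is preferentially delivered to the daughter
cell that inherits the older cell pole.  The SMC complex MukBEF and the
ter-organizing factor MatP maintain this order: without MukBEF the arm
pattern degrades and chromosome loss produces anucleate daughters biased to
the newer pole; without MatP the nucleoid is free to rotate, observed as
frequent inversions ("flips") of the arm-marker order along the long axis.

chromolin implements the quantitative pipeline used to establish these
claims from tracked single-cell microscopy — division forests with pole-age
propagation, anucleate detection, locus demographs, arm-configuration
classification, debounced flip counting, replisome/clamp colocalization, and
pulse-chase strand-retention scoring — together with a generative simulator
that stands in for the (undeposited) raw microscopy, so that every stage can
be verified by parameter recovery at desk scale.

## Coordinate and bookkeeping conventions

* Positions are signed distances (micrometres) from midcell along the long
  axis; the "negative pole" is the cell end with the smaller coordinate.
* Frames are 0-based and map to minutes through the frame interval
  (5 min in mother-machine runs, 10 min on agarose pads, both configurable).
* At each division two new poles (age 0) appear at the septum; each
  daughter's distal pole inherits the corresponding mother pole aged by one
  generation.  Cells present in the first frame have unknown pole identity
  until their first observed division anchors the chain; the analysis
  excludes such cells from pole-side statistics rather than guessing.
* Chromosome orientation is the sign of `pos(R3) - pos(L3)` while both arm
  markers show single foci; after arm-locus duplication the tracked state is
  the four-focus configuration (translational L-R-L-R vs mirror L-R-R-L)
  and its identity (which arm leads from the negative pole).

## The simulator

`simulate_experiment()` grows cells exponentially (`L(t) = L_b e^{rt}`,
with `r` set so each cell doubles from its birth length toward a homeostatic
division size of twice the 2.2 um mean birth length), divides them at
midcell plus Gaussian septum noise (SD 0.08 um; anucleate divisions use the
published near-symmetric 0.467/0.533 split), and tracks per-cycle latent
state: orientation and its flips, sister-configuration choice, strand pairs,
pole ages, label tokens, and polar chemoreceptor intensities.  Two layouts
are supported: the mother machine (the cell at the closed channel end is
followed indefinitely, its sibling for a configurable washout window — the
standard way such data are analysed) and the pad (full division tree).
Founders start at a uniformly random point of their cycle so the population
is asynchronous.

The cell cycle is divided into B (0–25%), C (25–70%) and D (70–100%)
phases.  Marker duplication times follow replication order: the origin at
the start of C, the arm loci L3/R3 at 71% of C (their chromosomal position
~128 degrees along the arms), the terminus at the end of C.

### Two modes

*Mechanistic* mode implements the proposed mechanism: a length-dependent
flip hazard (linear in length, doubling between birth and arm-locus
duplication, calibrated in closed form to the strain's flips-per-cycle
mean); translational segregation with probability `p_translational`; and
strand-polarity continuity — under translational segregation the sister
chromosome templated by the older strand returns to the old-pole half, and
every flip inverts that polarity; mirror segregation randomizes it.  Strand
ages advance at replication, so the ancestral strand is always the
oldest-age strand; retention of the ancestral strand at the old pole is
then an *emergent* observable: exactly 1 in the no-flip, always-translational
limit, and 0.5 when orientation is re-randomized every cycle (both asserted
on ground truth in the test suite).

*Phenomenological* mode gives every pipeline observable a direct governing
parameter (opposite-half probability, translational probability,
mother-to-daughter retention, flips per cycle, clamp colocalization,
strand retention, pole-call accuracy, …) whose defaults are the published
strain statistics.  This is the mode used for acceptance: with ideal
detection every pipeline statistic converges to its governing parameter,
so parameter recovery within 3 binomial/Monte-Carlo standard errors is a
sharp correctness check of the analysis code.

Phenomenological draws are made per observation unit that the matching
statistic counts: per cell cycle for cell-level fractions (the acceptance
measurements then take one frame per cell, as in the snapshot imaging that
produced the published numbers) and per focus-frame for pair-level
statistics, keeping binomial standard errors valid.

### Observation model

True foci acquire truncated-Gaussian position jitter; same-marker foci
closer than the merge radius (0.3 um, the diffraction limit) are reported
as one focus at their intensity-weighted mean — this is what makes origin
foci undercounted in cells whose sister origins fail to separate, the
signature exploited by the anucleate analysis; foci are dropped
independently at the detection-miss rate (0 by default: "ideal detection").
Replisome (DnaQ, DnaB) foci are emitted once the simulated forks are at
least 0.5 um apart (unresolved early/late forks are not emitted, mirroring
the mid-replication gating of the published analysis), and the sliding-clamp
(DnaN) focus of each fork either colocalizes with it (probability
`p_colocal`, displacement truncated at 0.28 um) or sits near midcell at
0.16–0.40 um, at least 0.31 um from every replisome focus.  These bounds
guarantee that no merge or cross-pairing can reclassify a pair, so the
measured sub-threshold fraction estimates `p_colocal` without bias.  The
price is stylized geometry: real distance distributions are smooth across
the 300 nm threshold, real ones are 2D; the package's distances are 1D
long-axis distances, a documented simplification under which the published
thresholds keep their meaning in phenomenological mode.

### Pulse-chase labeling

`apply_edu_pulse_chase()` re-runs the recorded simulation call with a label
pulse active; since all latent draws are unconditional, the lineages and all
non-label observables are byte-identical.  In mechanistic mode strands
synthesized while the pulse is active are flagged and the label then follows
semiconservative inheritance: first-round cells show label on both sister
nucleoids, second-round cells on exactly one — the one holding the *newer*
template — so scoring the label-free nucleoid against the Tsr-called older
pole measures ancestral-strand retention.  In phenomenological mode an
equivalent label token is passed down the lineage with the side chosen by
`p_retention_old_pole`.  From the third round on, the labeled strand is
itself the ancestral one and the assay's sign inverts; the 15-min pulse +
3-h chase protocol (generation time ~150 min) scores before third-round
cells reach the two-nucleoid stage, and the simulator reproduces exactly
that selection.

### Pole-age reporter

Tsr accumulates linearly with pole age (100 a.u. per generation over a
30 a.u. baseline).  In phenomenological mode the published validation
accuracy is the direct parameter: the intensity ranking is inverted with
probability `1 - p_tsr_correct` (0.8%), so the measured accuracy recovers
the parameter under any layout or pole-age structure.  In mechanistic mode
Gaussian intensity noise is calibrated so that per-cell accuracy equals the
target under the stationary pole-age distribution (old-pole age k with
probability 2^-k).  Pole-call errors propagate into retention without
correction: the measured fraction is `a + (1 - 2a) p` for miscall rate `a`,
an attenuation of ~0.3 percentage points at the validated accuracy — far
inside the acceptance tolerance, and quantifiable against the simulator's
truth table.

## Analysis choices that the sources leave open

* **Anucleate call**: a daughter with no focus in any chromosomal channel
  and relative length change < 2% over its observation window (>= 3
  frames).  The 2% threshold separates non-growing cells from slow growers;
  daughters lost earlier are excluded and tallied.
* **Flip debouncing**: a sign change counts only if the new sign persists
  >= 2 frames; undefined gaps <= 2 frames are bridged, longer gaps censor
  the interval.  Two flips within one frame are unobservable by
  construction (aliasing); the phenomenological generator therefore places
  flips at least two frames apart and truncates the per-cycle Poisson count
  at the feasible maximum, a < 1.5% bias at the highest published rate.
* **Flip probability vs length** is a per-cell-frame hazard: flips in a
  length bin divided by *pre-duplication* cell-frames in that bin (frames in
  which a flip could still occur).  A per-cell normalization would be an
  equally defensible reading of how such curves are usually reported; the
  per-frame hazard is the quantity the simulator's generative process
  defines, so that is what the package estimates.
* **Configuration ties**: foci closer than 10 nm along the axis are below
  position resolution and yield UNDETERMINED, as do focus-count patterns
  other than 2+2 (for example three foci after a merge artifact).
* **Opposite halves** uses the midcell of the segmented cell (not of the
  nucleoid); a focus exactly at 0 takes its side from the nearest previous
  frame, else the negative half.
* **FWHM** is measured on a 3-bin moving-average of the 0.05-um histogram
  by linear interpolation across the half-maximum crossings; more than two
  crossings report the widest span and a multimodality flag.
* **Replication gating** for colocalization statistics: frames between the
  first and last DnaQ focus of a cycle (in the simulator, identical to the
  fork-separation gate).
* **Binucleate cells** (the sisters of anucleate daughters) divide into two
  mononucleate daughters without an intervening replication round — a
  simplification; their published 9.1% repeat-anucleate probability and
  72-min generation time are modeled.  Because the published 15.7%
  anucleate rate is measured over *all* divisions while binucleate-born
  mothers divide anucleate at only 9.1%, the per-mononucleate parameter is
  solved from the stationary mixture of the two printed statistics
  (`p = 0.1661`), so the simulated population-wide rate reproduces 15.7%.
* Strain values the sources do not report fall back to wild type (deltaMukB
  flips per cycle, mother-daughter retention) or to 0.5 (wild-type
  anucleate pole bias); none of these back a target statistic.

## What a green test does and does not establish

The phenomenological acceptance checks establish that each analysis stage
recovers a known generating parameter, at the published sample scales,
through the full simulate → CSV → forest → statistic path, within 3 standard
errors.  They do not establish that the simulator reproduces real
image-derived noise: there is no point-spread function, no short-axis
coordinate, no segmentation error, no photobleaching; locus position
*distributions* are modeling choices (the sources publish heatmaps, not
distribution families).  Mechanistic-mode tests establish the internal
consistency of the proposed mechanism (strand conservation, retention
limits, hazard calibration against a closed-form expectation), not its
truth.

## Numerical and reproducibility notes

Each lineage consumes an independent RNG substream derived from the root
seed, so enlarging an experiment extends it without reshuffling existing
lineages; identical calls are byte-identical, and run manifests record MD5
hashes of every stage output.  Truncated-normal jitters are clamped at
stated caps so that geometric invariants (focus order, half membership,
merge-safety margins) hold surely rather than with high probability.
Generation times are truncated at 3 SD and at 30% of the mean; degenerate
inputs (empty tables, missing markers, zero-variance samples, empty pair
sets) return typed empty results or named errors as documented per
function.
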