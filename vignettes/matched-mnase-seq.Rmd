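---
title: "Matched MNase-seq: digestion simulation, lane matching, and track comparison"
author: "MNaseMatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched MNase-seq: digestion simulation, lane matching, and track comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MNaseMatch)
library(GenomicRanges)
```

## The problem: MNase-seq signal depends on the extent of digestion

Micrococcal nuclease (MNase) digests unprotected linker DNA far faster than
nucleosome-wrapped DNA. MNase-seq therefore reads out nucleosome occupancy by
sequencing the mono-nucleosome-sized DNA that survives digestion and size
selection. The catch is that a nucleosome's DNA enters the mono-nucleosome
pool only once cuts have landed on *both* of its sides, within a fragment
size captured by the gel excision (~115–195 bp). Both cuts arrive sooner when
a nucleosome is flanked by long linkers, so at partial digestion,
long-linker-flanked nucleosomes are over-represented relative to nucleosomes
embedded in tightly spaced arrays — a *neighborhood effect* that has nothing
to do with occupancy. Two experiments digested to different extents will
disagree genome-wide for purely technical reasons.

This package implements the computational side of a standardized MNase-seq
workflow: (i) a stochastic digestion simulator that makes the neighborhood
effect measurable; (ii) densitometry-based selection of *matched* digests
(equivalently digested chromatin preparations); (iii) genome-wide comparison
of coverage tracks with dissimilar-region detection; and (iv) an enrichment
test of binding signal at dissimilar regions against a random-region null.

## The digestion model

A `ChromatinTemplate` is a linear DNA molecule with non-overlapping 147-bp
nucleosome footprints at 100% occupancy; everything else is linker/naked DNA.
The reference template (`referenceTemplate()`) is 4 kb and carries six
nucleosomes spaced 15 bp apart except for a 142-bp central linker (its
midpoint on the template midpoint) and a 30-bp linker upstream of the first
nucleosome — the average promoter-proximal organization of budding yeast.
Template DNA outside the array is naked. Since linker and naked DNA share the
same (maximal) cut probability, the placement of the array on the template is
the only free choice; we center it so that the reported central kilobase
covers the array symmetrically.

Cut sites are the `L − 1` inter-base positions. The per-site cut probability
is exactly 1 in linker/naked DNA and `1/protection` inside a nucleosome,
where protection interpolates from 50× at the footprint edge to 1000× at the
dyad (base `start + 73` of the 147-bp footprint), mirrored about the dyad.
The exact in vivo protection curve is known only by its range and positional
dependence, so the default is a linear interpolation, with a raised-cosine
alternative (`shape = "cosine"`) to probe sensitivity; both respect the edge
and dyad values, symmetry, and monotonicity.

A digestion with `n` cuts draws `n` candidate sites uniformly and realizes
each with the local profile probability (rejection sampling); duplicate
realized sites collapse to one cut. This reading of "n randomly distributed
cuts" treats `n` as *attempted* cuts; the alternative reading, `n`
*realized* cuts, is available as `cutMode = "realized"` (candidates are drawn
until `n` are accepted). The two modes differ only in the mapping from `n` to
the extent of digestion. Each cut number is iterated over a population of
10,000 templates.

Fragments are the runs between consecutive cuts (template ends close the
terminal fragments, so lengths always sum to the template length).
Size selection retains fragments of 115–195 bp inclusive; the inclusive
reading resolves the ambiguous "115 < bp > 195" notation in favor of the
unambiguous "~115–195-bp" phrasing used elsewhere. The extent of digestion,

\[ \%\,\mathrm{Monos} = \frac{\#\{115 \le \mathrm{bp} \le 195\}}{\#\{\mathrm{bp} \ge 115\}}, \]

uses an inclusive denominator for consistency with the numerator (a
`denomInclusive = FALSE` switch restricts both to `> 115`). Selected
fragments are tabulated base-by-base over the template ("paired-end"
tabulation: the whole fragment, no tag extension), standardized to a fixed
selected-fragment total (10^6 by default — only ratios matter), and divided
by the mean signal over template coordinates 2501–3500 so that the
normalization region sits at exactly 1 in every simulation. Only the central
kilobase (1501–2500) is reported, which removes the template-end edge effect.

`neighborhoodEffect()` summarizes a titration as the ratio of mean
normalized signal over the two nucleosomes flanking the longest internal
linker to that over nucleosomes whose two internal linkers both equal the
modal (15-bp) spacing.

**A note on the titration range.** Under the attempted-cut model on the 4-kb
template, cut numbers 2–50 span roughly 4% to 55% Monos: most candidate cuts
fall in naked DNA, and with at most 50 candidates the 15-bp linkers are
rarely all cut. Near-complete digestion (>95% Monos, every linker cut)
requires on the order of 10^3 attempted cuts, which is what the lane-matching
and specificity analyses use for their "complete digest" condition. The
qualitative claims — the neighborhood excess at partial digestion and its
monotone decay toward 1 as digestion completes — are unaffected by which
reading of `n` is used.

Two independent oracles guard the simulator. `expectedFragmentLengthDist()`
computes the exact per-template expected fragment-length histogram by
inclusion–exclusion over boundary cuts and interior non-cuts (no simulation),
and the test suite requires the Monte-Carlo engine to agree with it within
3σ across length bins at 10^6 templates. On always-cut DNA, realized cut
counts are checked against their binomial expectation.

## Matched-digest selection from gel densitometry

The wet-lab protocol runs a titration of digests on a gel and selects
preparations that are equivalently digested. The package consumes exported
densitometry traces (`distance`, `intensity` TSV per lane) rather than gel
images. A ladder run on the same gel (`calibrateLadder()`) provides a
strictly monotone size↔distance mapping, interpolated linearly in log-size
(standard agarose mobility); `laneToSizeProfile()` resamples each lane onto a
common 1-bp fragment-size grid over 0–400 bp (clipped to the calibrated
span), multiplying by the local |d distance/d size| Jacobian so band areas
are preserved under the change of variable. Correlating calibrated size
profiles rather than raw migration traces makes lanes from different gels
comparable.

A digest is *complete* when its di-nucleosome band is invisible. "Visible by
eye" is operationalized as: peak intensity within the di-nucleosome window
(250–350 bp) below 5% of the mono-nucleosome peak (115–195 bp); both windows
and the 5% threshold are configurable. *Matched* digests are pairs of
complete lanes with Pearson r strictly above 0.9. The fixture generator
`simulateGelLane()` maps any fragment multiset to a lane under log-linear
mobility with Gaussian band spread and intercalating-dye (mass ∝ count ×
length) intensities, which is how the lane module is tested end-to-end
against the digestion simulator: two complete digests from different seeds
match at r > 0.999, while a ~30% Monos digest fails both the completeness
check and the correlation threshold.

## Genome-wide track comparison

`CoverageTrack` holds binned signal (default 10-bp bins) per chromosome;
tracks are built from aligned fragment intervals (`coverageFromFragments()`,
optional 147-bp 3'-ward extension for single-end reads) or read from
bedGraph/wiggle (length-weighted averaging into bins; overlapping bedGraph
intervals are rejected). `standardizeTrack()` fixes a common genome-wide
total — the track analogue of standardizing read counts; Pearson
correlations are invariant to it.

"1000-bp windows at 10-bp resolution" is resolved as: signal binned at
10 bp; *histogram* windows tile the genome without overlap at 1000 bp;
*dissimilar-region detection* slides the 1000-bp window at 10-bp steps. Both
window and step are explicit arguments, so either convention can be forced.
Window correlations use rolling sums over globally centered values (one pass,
numerically stable; the suite checks equality with naive per-window `cor()`
at 1e-10). Windows with zero variance in either track are flagged NA,
excluded from histograms, and never called dissimilar — constancy is absence
of evidence, not similarity or dissimilarity. Genome-to-genome correlation is
a single Pearson r at 100-bp resolution.

Dissimilar regions are maximal unions of overlapping-or-abutting sliding
windows with r < 0.5, retained when spanning at least 1000 bp, annotated
with the minimum window r. Merged-window union bounds overshoot a true
breakpoint by up to half a window on each side — the price of the sliding
convention; at the domain sizes of interest (several kb and larger) the
overshoot is a small fraction of the region.

Reference-anchored profiles (`annotateLinkers()`,
`linkerClassProfiles()`) classify each reference nucleosome's two adjacent
linkers as normal (10–20 bp, centered on the mean yeast linker) or long
(21–221 bp, up to ~1.5 nucleosome templates), select nucleosomes whose two
sides agree, and average dyad-aligned signal per class.

## Binding enrichment at dissimilar regions

`continuousBindingProfile()` converts probe-level log2 ratios into a
continuous profile by the sliding-window mean of probe midpoints
(the ChIPOTle convention; 500-bp windows stepping 250 bp by default — the
conventional parameters for that approach, exposed as arguments since no
single standard exists). Bins without probe support are missing, and regions
whose bins are all missing are excluded (and counted) rather than imputed.
The test compares per-region mean binding at the observed (dissimilar)
regions against 10,000 random regions sized to the mean dissimilar-region
width — chromosomes drawn proportionally to their number of valid
placements, starts uniform — using a one-tailed Welch (heteroscedastic)
t-test in the enrichment direction (observed > null).

## What the synthetic data emulate — and what they do not

`synthTrackPair()` generates replicate-like track pairs from a shared
occupancy landscape: Gaussian peaks (sd 40 bp) on a 162-bp repeat
(147 + 15), a flat baseline at 10% of peak amplitude, and a long (142-bp)
linker every 10th repeat mimicking promoter NDRs. Each track then receives
independent per-bin Poisson counting noise at a mean depth of 100 counts per
10-bp bin — deeply sequenced yeast-scale data; `noise = "none"` yields the
deterministic expectation. Planted dissimilar regions replace the second
track's underlying signal with a quarter-repeat phase-shifted array:
uncorrelated with the original (a half shift would be anticorrelated, which
no real chromatin change produces), so planted windows sit near r ≈ 0.

Digestion extent enters through a single per-track bias factor `b` — the
neighborhood over-representation ratio measured by the simulator at that
extent (b = 1 at complete digestion). A bias b > 1 reshapes the underlying
signal the way under-digested preparations are distorted in vivo:
long-flanked peaks are amplified b-fold, the flanking cores are drawn 40 bp
per unit of (b − 1) toward the NDR, and a narrower sub-nucleosomal particle
(amplitude 0.75 per unit of (b − 1), width 0.6× a nucleosome peak) appears
inside the NDR — the MNase-sensitive fragile particles reported in
under-digested chromatin. Comparing two tracks at the *same* bias cancels
these distortions exactly; comparing different biases produces spurious
dissimilar calls at promoters genome-wide, which is precisely the
technical-artifact inflation that matched digests eliminate.

The generator does **not** model sequence-dependent MNase preference (AT
bias), fragment-length variation and size-selection breadth, mappability,
chromatin heterogeneity across the population, or inter-replicate occupancy
drift. Passing the planted-recovery and specificity tests therefore shows
that the detection and enrichment machinery behaves correctly under the
stated noise model — not that real unmatched experiments are fully described
by a single bias factor.

## Numerical choices and degenerate inputs

* Coordinates are 1-based closed in memory (`IRanges`/`GRanges`); BED and
  bedGraph are 0-based half-open on disk, wiggle is 1-based, conversions at
  the file boundary.
* Duplicate candidate cut sites collapse; a zero-cut digest yields one
  full-length fragment and 0% Monos (denominator counts it).
* An empty %-Monos denominator returns 0 with a warning.
* Zero-variance lanes or windows give NA correlations (flagged, never
  silently 0), and a zero normalization region is an error.
* Ladder calibration refuses non-monotone band tables and flags
  extrapolation beyond the band span.
* The Welch test requires two non-missing per-region means per group and
  refuses degenerate all-constant inputs.
* All randomness flows through per-call seeds (`withSeed` restores the
  caller's RNG state); fixed seed implies bit-identical output everywhere.

## Problem sizes used by the test suite

The suite exercises the study conditions at sizes chosen to make sampling
error negligible relative to the tested effects: 10^6 templates for the
fragment-distribution oracle (n = 3 cuts on a 300-bp single-nucleosome toy
template); 10,000–25,000 templates per titration point on the 4-kb
reference template; a 1-Mb two-chromosome synthetic genome with one 25-kb
planted region per chromosome (5% of the genome) for recovery and
specificity; 200 seeded repetitions (1000-region nulls) for null
calibration of the enrichment p-value, plus a single 10,000-region null for
the powered case. The neighborhood-effect decay is checked at three widely
separated extents (~18%, ~62%, and ~99% Monos) where the Monte-Carlo error
of the class ratio is small compared to the decay.

## Known limitations

* The protection curve between the 50× edge and 1000× dyad anchor points is
  a modeling choice (linear by default); absolute %-Monos-vs-n mappings
  shift slightly between the linear and cosine shapes and between attempted
  and realized cut modes.
* Completeness ("no visible di-band") depends on densitometry quality; the
  5% threshold is a proxy for a judgment the bench scientist makes by eye.
* Dissimilar-region boundaries inherit half-window uncertainty from the
  sliding convention.
* The enrichment null randomizes location only; it does not preserve probe
  density or chromatin composition of the observed regions beyond excluding
  probe-free regions.
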