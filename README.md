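# MNaseMatch

Tools for **standardized MNase-seq**: simulating the DNA-sampling bias of
micrococcal nuclease digestion, selecting *matched* (equivalently digested)
chromatin preparations from gel densitometry, and comparing MNase-seq
coverage tracks genome-wide.

## The scientific problem

MNase-seq infers nucleosome occupancy from the mono-nucleosome-sized DNA
(~115–195 bp) that survives MNase digestion and size selection. A
nucleosome's DNA is recovered only after cuts land on **both** of its sides
within the captured size range. Both cuts arrive sooner when the nucleosome
is flanked by long linker DNA — linkers are digested 50–1000× faster than
nucleosomal DNA, depending on a base pair's position within the nucleosome
(protection rises from ~50× at the edge to ~1000× at the dyad). The result
is a *neighborhood effect*: at partial digestion, long-linker-flanked
nucleosomes (e.g. those beside promoter nucleosome-depleted regions) are
over-represented for purely technical reasons, and the over-representation
decays only as digestion approaches completion:

* per-site cut probability: `p(x) = 1` in linker/naked DNA,
  `p(x) = 1/protection(x)` inside a nucleosome, with `protection` rising
  from 50 (edge) to 1000 (dyad);
* extent of digestion:
  `%Monos = #{115 ≤ bp ≤ 195} / #{bp ≥ 115}` over the fragment population;
* matched digests: two *complete* digests (no visible di-nucleosome band,
  operationalized as di-band peak < 5% of the mono-band peak on a calibrated
  0–400 bp size profile) whose lane profiles correlate at Pearson `r > 0.9`;
* dissimilar chromatin regions between two tracks: merged sliding 1000-bp
  windows (10-bp step) with `r < 0.5`, spanning ≥ 1000 bp;
* enrichment of binding at dissimilar regions: one-tailed Welch *t*-test of
  per-region mean log2 binding against 10,000 random regions of equal size.

Comparing experiments digested to different extents inflates dissimilar
region calls genome-wide; this package quantifies that inflation in
simulation and provides the matching workflow that removes it.

Who this is for: groups running MNase-seq (or reanalyzing public MNase-seq)
who need to decide whether two datasets are comparable, select matched
digests from a titration, and restrict downstream claims to differences that
survive matching.

## Worked example

Simulate a digestion titration of the six-nucleosome reference template and
measure the neighborhood effect:

```r
library(MNaseMatch)

tpl <- referenceTemplate()
tpl
#> ChromatinTemplate of 4000 bp with 6 nucleosome(s)
#>   nucleosome widths: 147, 147, 147, 147, 147, 147
#>   linker widths:     1458, 15, 15, 142, 15, 15, 1458

tt <- runTitration(tpl, nCutsValues = c(10, 100, 1000),
                   nTemplates = 5000, seed = 1)
neighborhoodEffect(tt, tpl)
#>   nCuts percentMonos nSelected ratio
#> 1    10        0.176      5823  3.90
#> 2   100        0.620     21826  2.06
#> 3  1000        0.984     28352  1.02
```

At 18% Monos the two nucleosomes flanking the 142-bp central linker collect
**3.9×** the normalized signal of the 15-bp-spaced nucleosomes — same
template, same occupancy, different sampling. By near-complete digestion
(98% Monos) the ratio has collapsed to 1.02: every linker has been cut, so
every nucleosome is sampled equally. A single digest prints as:

```r
simulatePopulation(tpl, nCuts = 1000, nTemplates = 2000, seed = 2)
#> DigestResult: n = 1000 cuts x 2000 templates; 1382283 fragments,
#>   11258 selected; 98.2% Monos
```

Downstream, `simulateGelLane()` + `calibrateLadder()` +
`laneToSizeProfile()` + `selectMatched()` reproduce the gel-based matching
step; `synthTrackPair()` + `windowCorrelations()` + `dissimilarRegions()` +
`enrichmentAnalysis()` run the genome-wide comparison. A thin command-line
front end (`inst/scripts/mnasematch`) exposes the same steps as
`simulate`, `match`, `compare`, `enrich` and `synth` subcommands over
bedGraph/BED/TSV files.

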