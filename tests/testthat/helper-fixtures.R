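# Shared fixtures built in code.

suppressPackageStartupMessages({
    library(IRanges)
    library(GenomicRanges)
})

# A Qiagen-like 100-bp ladder under the log-linear mobility model used by
# simulateGelLane (distance = 220 - 65 log10(size)).
standardLadder <- function(sizes = seq(100, 1000, by = 100)) {
    calibrateLadder(data.frame(size = sizes,
        distance = 220 - 65 * log10(sizes)))
}

# Build a CoverageTrack directly from per-chromosome bin vectors.
makeTrack <- function(..., binBp = 10L) {
    vals <- list(...)
    seqlengths <- vapply(vals, function(v) length(v) * binBp, 1L)
    CoverageTrack(vals, binBp, seqlengths)
}

# A fragment set with prescribed fragment lengths (one synthetic template).
fragmentSetOfLengths <- function(lengths) {
    ends <- cumsum(lengths)
    starts <- ends - lengths + 1L
    fragmentsFromCuts(buildTemplate(sum(lengths), integer(0)),
        head(ends, -1L))
}

# One-nucleosome 300-bp toy template (dyad at base 150).
toyTemplate <- function() buildTemplate(300, 77)

# Gel lane for a simulated digest of the reference template.
digestLane <- function(nCuts, seed, nTemplates = 2000) {
    res <- simulatePopulation(referenceTemplate(), nCuts = nCuts,
        nTemplates = nTemplates, seed = seed)
    simulateGelLane(fragmentLengths(allFragments(res)))
}
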