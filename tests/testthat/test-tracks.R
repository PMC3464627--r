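test_that("binned coverage tabulates fragment intervals", {
    gr <- GRanges("chrI", IRanges(11, 160))   # one 150-bp fragment
    tr <- coverageFromFragments(gr, c(chrI = 1000L))
    v <- trackValues(tr, "chrI")
    expect_equal(v[2:16], rep(1, 15))
    expect_equal(sum(v > 0), 15)
    # conservation: signal mass equals summed interval lengths
    set.seed(3)
    gr2 <- GRanges("chrI", IRanges(start = sample(1:800, 50, TRUE),
        width = sample(50:150, 50, TRUE)))
    gr2 <- gr2[end(gr2) <= 1000]
    tr2 <- coverageFromFragments(gr2, c(chrI = 1000L))
    expect_equal(sum(trackValues(tr2, "chrI") * 10), sum(width(gr2)))
    # empty input and unknown chromosomes
    expect_equal(sum(trackValues(coverageFromFragments(GRanges(),
        c(chrI = 100L)), "chrI")), 0)
    expect_error(coverageFromFragments(GRanges("chrX", IRanges(1, 10)),
        c(chrI = 100L)), "chrX")
})

test_that("single-end extension resizes reads 3'-ward", {
    gr <- GRanges("chrI", IRanges(101, 101), strand = "+")
    tr <- coverageFromFragments(gr, c(chrI = 1000L), binBp = 1L,
        extendTo = 147L)
    expect_equal(sum(trackValues(tr, "chrI")), 147)
    expect_equal(which(trackValues(tr, "chrI") > 0), 101:247)
    grm <- GRanges("chrI", IRanges(500, 500), strand = "-")
    trm <- coverageFromFragments(grm, c(chrI = 1000L), binBp = 1L,
        extendTo = 147L)
    expect_equal(which(trackValues(trm, "chrI") > 0), 354:500)
})

test_that("standardization fixes totals and leaves correlations alone", {
    a <- makeTrack(chrI = runif(200) + 0.5)
    s <- standardizeTrack(a, 1e6)
    expect_equal(sum(trackValues(s, "chrI")), 1e6)
    expect_equal(sum(trackValues(standardizeTrack(s, 1e6), "chrI")), 1e6)
    b <- makeTrack(chrI = runif(200) + 0.5)
    expect_equal(genomeCorrelation(a, b, 10), genomeCorrelation(s, b, 10),
        tolerance = 1e-12)
    expect_error(standardizeTrack(makeTrack(chrI = rep(0, 10))), "zero")
})

test_that("window correlations match naive per-window recomputation", {
    set.seed(11)
    a <- makeTrack(chrI = rnorm(3000, 10), chrII = rnorm(2000, 10))
    b <- makeTrack(chrI = rnorm(3000, 10), chrII = rnorm(2000, 10))
    wcs <- windowCorrelations(a, b, windowBp = 1000, stepBp = 250)
    w <- correlationWindows(wcs)
    idx <- sample(length(w), 100)
    for (i in idx) {
        chr <- as.character(seqnames(w)[i])
        bins <- ((start(w)[i] - 1) %/% 10 + 1):(end(w)[i] %/% 10)
        naive <- cor(trackValues(a, chr)[bins], trackValues(b, chr)[bins])
        expect_equal(mcols(w)$r[i], naive, tolerance = 1e-10)
    }
    # self-correlation is exactly 1 everywhere
    self <- correlationWindows(windowCorrelations(a, a, 1000))
    expect_true(all(abs(mcols(self)$r - 1) < 1e-12))
    # white-noise null: mean r near zero
    expect_lt(abs(mean(mcols(w)$r)), 3 / sqrt(100 * length(w)) * 3 + 0.02)
})

test_that("correlations are invariant to positive affine rescaling", {
    set.seed(12)
    a <- makeTrack(chrI = rnorm(2000, 50, 5))
    b <- makeTrack(chrI = rnorm(2000, 50, 5))
    aScaled <- makeTrack(chrI = 2.5 * trackValues(a, "chrI") + 7)
    r1 <- mcols(correlationWindows(windowCorrelations(a, b, 1000)))$r
    r2 <- mcols(correlationWindows(windowCorrelations(aScaled, b, 1000)))$r
    expect_equal(r1, r2, tolerance = 1e-12)
    expect_equal(genomeCorrelation(a, b), genomeCorrelation(aScaled, b),
        tolerance = 1e-12)
})

test_that("zero-variance windows are flagged and excluded", {
    a <- makeTrack(chrI = c(rep(5, 100), rnorm(200, 10)))
    b <- makeTrack(chrI = c(rep(3, 100), rnorm(200, 10)))
    wcs <- windowCorrelations(a, b, windowBp = 1000)
    r <- mcols(correlationWindows(wcs))$r
    expect_true(is.na(r[1]))   # constant first kilobase
    h <- correlationHistogram(wcs)
    expect_equal(h$nUndefined, sum(is.na(r)))
    expect_equal(sum(h$counts), h$nDefined)
})

test_that("correlation histogram summarizes fractions", {
    a <- makeTrack(chrI = rnorm(1000, 10))
    h <- correlationHistogram(windowCorrelations(a, a, 1000))
    expect_equal(h$fractionAbove0.9, 1)
    expect_equal(h$fractionBelow0.5, 0)
})

test_that("genome correlation equals one whole-genome window", {
    set.seed(13)
    a <- makeTrack(chrI = rnorm(500, 20), binBp = 100L)
    b <- makeTrack(chrI = rnorm(500, 20), binBp = 100L)
    g <- genomeCorrelation(a, b, resolutionBp = 100)
    w <- windowCorrelations(a, b, windowBp = 50000, stepBp = 50000)
    expect_equal(g, mcols(correlationWindows(w))$r, tolerance = 1e-10)
    expect_equal(genomeCorrelation(a, a), 1)
    # mean-reversed signal correlates negatively
    rev <- makeTrack(chrI = 2 * mean(trackValues(a, "chrI")) -
        trackValues(a, "chrI"), binBp = 100L)
    expect_lt(genomeCorrelation(a, rev), 0)
})

test_that("dissimilar regions recover planted decorrelation and merge rules", {
    sameA <- makeTrack(chrI = rnorm(2000, 10))
    expect_length(dissimilarRegionRanges(dissimilarRegions(sameA, sameA)), 0)
    # two plants separated by correlated signal give two regions
    sl <- c(chrI = 100000L)
    plants <- GRanges("chrI", IRanges(c(20001, 70001), width = 6000))
    pair <- synthTrackPair(SyntheticTrackSpec(seqlengths = sl,
        plants = plants, seed = 21))
    dr <- dissimilarRegions(pair$a, pair$b)
    called <- dissimilarRegionRanges(dr)
    expect_equal(length(called), 2L)
    ov <- width(GenomicRanges::intersect(called, plants))
    jaccard <- sum(ov) / (sum(width(called)) + sum(width(plants)) - sum(ov))
    expect_gte(jaccard, 0.8)
    expect_true(all(mcols(called)$minR < 0.5))
    # step refinement never loses a plant of length >= 3 windows
    dr20 <- dissimilarRegions(pair$a, pair$b, stepBp = 20)
    dr10 <- dissimilarRegions(pair$a, pair$b, stepBp = 10)
    for (d in list(dr20, dr10))
        expect_equal(S4Vectors::queryHits(findOverlaps(plants,
            dissimilarRegionRanges(d))), 1:2)
})

test_that("deeper sequencing tightens replicate concordance", {
    fr <- vapply(c(10, 50, 250), function(depth) {
        pair <- synthTrackPair(SyntheticTrackSpec(
            seqlengths = c(chrI = 200000L), depth = depth, seed = 31))
        correlationHistogram(windowCorrelations(pair$a, pair$b,
            1000))$fractionAbove0.9
    }, numeric(1))
    expect_true(all(diff(fr) > 0))
})

test_that("linker annotation classifies nucleosome neighborhoods", {
    sl <- c(chrI = 5000L, chrII = 5000L)
    ref <- c(
        GRanges("chrI", IRanges(start = c(1000, 1162, 1324, 1486),
            width = 147), seqlengths = sl),    # gaps 15, 15, 15
        GRanges("chrII", IRanges(start = c(500, 747, 944, 1151),
            width = 147), seqlengths = sl))    # gaps 100, 50, 60
    ann <- annotateLinkers(ref)
    cls <- mcols(ann)$bothClass
    # chrI interior nucleosomes have normal (15, 15) linkers
    expect_equal(cls[2:3], c("normal", "normal"))
    # chrII interior: (100, 50) and (50, 60) are long-long
    expect_equal(cls[6:7], c("long", "long"))
    # chromosome-end nucleosomes have an undefined side
    expect_equal(cls[c(1, 4, 5, 8)], rep("mixed", 4))
    expect_equal(mcols(ann)$leftLinker[2], 15L)
    expect_equal(mcols(ann)$rightLinker[6], 50L)
})

test_that("dyad-aligned class profiles expose planted contrasts", {
    starts <- seq(1000, 55000, by = 400)   # 253-bp gaps throughout
    ref <- GRanges("chrI", IRanges(start = starts, width = 147))
    ann <- annotateLinkers(ref, normal = c(200, 300), long = c(301, 500))
    # uniform track: both class profiles flat and equal
    uni <- makeTrack(chrI = rep(4, 6000))
    prof <- linkerClassProfiles(uni, ann, normal = c(200, 300),
        long = c(301, 500), flankBp = 500)
    expect_true(all(abs(prof$normal - 4) < 1e-12))
    # planted contrast: elevate coverage only at long-linker nucleosomes
    ref2 <- GRanges("chrI", IRanges(
        start = c(seq(2000, 20000, by = 320), seq(30000, 50000, by = 500)),
        width = 147))
    ann2 <- annotateLinkers(ref2, normal = c(150, 200), long = c(300, 400))
    v <- rep(1, 6000)
    longNucs <- ann2[mcols(ann2)$bothClass == "long"]
    expect_gt(length(longNucs), 3)
    for (i in seq_along(longNucs)) {
        bins <- (start(longNucs)[i] %/% 10):(end(longNucs)[i] %/% 10)
        v[bins] <- 3
    }
    tr <- makeTrack(chrI = v)
    prof2 <- linkerClassProfiles(tr, ann2, normal = c(150, 200),
        long = c(300, 400), flankBp = 300)
    mid <- (length(prof2$offset) + 1) %/% 2
    expect_gt(prof2$long[mid], prof2$normal[mid])
})
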