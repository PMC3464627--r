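test_that("binding profile equals direct window means of probe midpoints", {
    sl <- c(chrI = 10000L)
    # single probe covering one window
    one <- GRanges("chrI", IRanges(100, 160), log2ratio = 1.7)
    prof <- continuousBindingProfile(one, sl)
    v <- trackValues(prof, "chrI")
    expect_equal(v[1], 1.7)       # window 1-500 contains midpoint 130
    expect_true(all(is.na(v[-1])))   # no other window covers the probe
    # constant probes give a constant profile where defined
    const <- synthBinding(sl, backgroundMean = 2, noiseSd = 0, seed = 1)
    cp <- trackValues(continuousBindingProfile(const, sl), "chrI")
    expect_true(all(abs(cp[!is.na(cp)] - 2) < 1e-12))
    # random probes: brute-force oracle per window
    set.seed(9)
    probes <- GRanges("chrI", IRanges(start = sort(sample(1:9900, 60)),
        width = 40))
    mcols(probes)$log2ratio <- rnorm(60)
    bp <- continuousBindingProfile(probes, sl, windowBp = 500, stepBp = 250)
    v2 <- trackValues(bp, "chrI")
    mids <- (start(probes) + end(probes)) %/% 2
    for (k in seq_along(v2)) {
        ws <- (k - 1) * 250 + 1
        sel <- mids >= ws & mids <= min(ws + 499, 10000)
        if (!any(sel)) expect_true(is.na(v2[k]))
        else expect_equal(v2[k], mean(mcols(probes)$log2ratio[sel]),
            tolerance = 1e-12)
    }
})

test_that("region means average covered bins and count exclusions", {
    sl <- c(chrI = 10000L)
    const <- synthBinding(sl, backgroundMean = 3, noiseSd = 0, seed = 2)
    prof <- continuousBindingProfile(const, sl)
    rm1 <- regionMeanBinding(prof, GRanges("chrI", IRanges(1000, 3000)))
    expect_equal(unname(rm1$means), 3)
    expect_equal(rm1$nExcluded, 0L)
    # a profile with a missing stretch: regions fully inside it are excluded
    gap <- GRanges("chrI", IRanges(c(100, 5000), c(400, 5600)),
        log2ratio = c(1, 2))
    gp <- continuousBindingProfile(gap, sl)
    rm2 <- regionMeanBinding(gp, GRanges("chrI",
        IRanges(c(2000, 5000), c(3000, 5500))))
    expect_equal(rm2$nExcluded, 1L)
    expect_equal(unname(rm2$means), 2)
    # fuzzed agreement with direct recomputation
    set.seed(10)
    probes <- synthBinding(sl, noiseSd = 1, seed = 3)
    p3 <- continuousBindingProfile(probes, sl)
    v <- trackValues(p3, "chrI")
    regions <- GRanges("chrI", IRanges(start = sample(1:9000, 20),
        width = sample(300:900, 20, TRUE)))
    regions <- regions[end(regions) <= 10000]
    rm3 <- regionMeanBinding(p3, regions)
    for (i in which(rm3$kept)) {
        b1 <- (start(regions)[i] - 1) %/% 250 + 1
        b2 <- min((end(regions)[i] - 1) %/% 250 + 1, length(v))
        expect_equal(unname(rm3$means[as.character(i)]),
            mean(v[b1:b2], na.rm = TRUE), tolerance = 1e-12)
    }
})

test_that("random regions are in bounds and length-weighted by chromosome", {
    sl <- c(chrI = 300000L, chrII = 100000L)
    rr <- randomRegions(sl, count = 10000, sizeBp = 2000, seed = 4)
    expect_length(rr, 10000)
    expect_true(all(width(rr) == 2000))
    expect_true(all(start(rr) >= 1))
    expect_true(all(end(rr) <= sl[as.character(seqnames(rr))]))
    # chromosome frequencies track placeable length (chi-square-style 3 sigma)
    p1 <- (300000 - 1999) / (300000 - 1999 + 100000 - 1999)
    n1 <- sum(seqnames(rr) == "chrI")
    expect_lt(abs(n1 - 10000 * p1), 3 * sqrt(10000 * p1 * (1 - p1)))
    expect_error(randomRegions(sl, count = 10, sizeBp = 5e5), "exceeds")
    # determinism per seed
    rr2 <- randomRegions(sl, count = 10000, sizeBp = 2000, seed = 4)
    expect_identical(as.data.frame(rr), as.data.frame(rr2))
})

test_that("Welch test matches the hand-computed formula and extremes", {
    x <- c(3.1, 2.7, 3.9, 3.4)
    y <- c(2.2, 2.9, 2.4, 2.6)
    res <- enrichmentTest(x, y)
    sx <- var(x) / 4; sy <- var(y) / 4
    tHand <- (mean(x) - mean(y)) / sqrt(sx + sy)
    dfHand <- (sx + sy)^2 / (sx^2 / 3 + sy^2 / 3)
    pHand <- stats::pt(tHand, dfHand, lower.tail = FALSE)
    expect_equal(res@t, tHand, tolerance = 1e-10)
    expect_equal(enrichmentP(res), pHand, tolerance = 1e-10)
    # extreme separation
    set.seed(6)
    big <- enrichmentTest(rnorm(50, 10), rnorm(200, 0))
    expect_lt(enrichmentP(big), 1e-6)
    expect_error(enrichmentTest(rep(1, 5), rep(1, 5)), "variance")
    expect_error(enrichmentTest(1, rnorm(5)), "at least 2")
})

test_that("synthetic binding tiles probes deterministically", {
    sl <- c(chrI = 10000L, chrII = 4000L)
    pr <- synthBinding(sl, noiseSd = 0.3, seed = 7)
    nExp <- sum(vapply(sl, function(L) floor((L - 1) / 250) + 1, 1))
    expect_length(pr, nExp)
    pr2 <- synthBinding(sl, noiseSd = 0.3, seed = 7)
    expect_identical(as.data.frame(pr), as.data.frame(pr2))
})

test_that("planted binding effects are detected with power rising in delta", {
    sl <- c(chrI = 200000L)
    regions <- evenlySpacedRegions(sl, nPerChrom = 10, sizeBp = 2000)
    ps <- vapply(c(0.5, 1, 2), function(delta) {
        probes <- synthBinding(sl, regions, effect = delta, noiseSd = 0.5,
            seed = 17)
        enrichmentP(enrichmentAnalysis(probes, regions, sl, nRandom = 1000,
            seed = 18))
    }, numeric(1))
    expect_true(all(diff(ps) < 0))
    expect_lt(ps[3], 1e-4)
})

test_that("null binding yields calibrated p-values", {
    sl <- c(chrI = 100000L)
    regions <- evenlySpacedRegions(sl, nPerChrom = 10, sizeBp = 2000)
    ps <- vapply(1:40, function(s) {
        probes <- synthBinding(sl, regions, effect = 0, noiseSd = 0.5,
            seed = 100 + s)
        enrichmentP(enrichmentAnalysis(probes, regions, sl, nRandom = 500,
            seed = 200 + s))
    }, numeric(1))
    expect_gt(median(ps), 0.2)
    expect_lt(median(ps), 0.8)
})

test_that("matched pipeline without planted differences stays quiet", {
    sl <- c(chrI = 50000L)
    nonsig <- vapply(1:20, function(s) {
        pair <- synthTrackPair(SyntheticTrackSpec(seqlengths = sl,
            seed = 300 + s))
        called <- dissimilarRegionRanges(dissimilarRegions(pair$a, pair$b))
        if (length(called) == 0)
            return(TRUE)   # nothing dissimilar: no enrichment claim
        probes <- synthBinding(sl, effect = 0, noiseSd = 0.5, seed = 400 + s)
        enrichmentP(enrichmentAnalysis(probes, called, sl, nRandom = 500,
            seed = 500 + s)) > 0.05
    }, logical(1))
    expect_gte(mean(nonsig), 0.9)
})
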