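test_that("fragments partition the template", {
    tpl <- buildTemplate(4000, integer(0))
    expect_equal(fragmentLengths(fragmentsFromCuts(tpl, integer(0))), 4000L)
    expect_equal(fragmentLengths(fragmentsFromCuts(tpl, c(1000, 2000))),
        c(1000L, 1000L, 2000L))
    # fuzzed partition property
    set.seed(101)
    for (i in 1:200) {
        cuts <- sort(sample.int(3999, sample(0:30, 1)))
        fs <- fragmentsFromCuts(tpl, cuts)
        expect_equal(sum(fragmentLengths(fs)), 4000L)
        expect_true(all(fragmentLengths(fs) >= 1L))
    }
})

test_that("cut realization follows the probability profile", {
    naked <- buildTemplate(100, integer(0))
    prof <- cutProbabilityProfile(naked)
    expect_length(simulateCuts(prof, 0, seed = 1), 0)
    cuts <- simulateCuts(prof, 5, seed = 1)
    expect_lte(length(cuts), 5)           # duplicates collapse
    expect_true(all(cuts >= 1 & cuts <= 99))
    # expected realized count on naked DNA: 5 x (1 - collision correction)
    nReal <- replicate(2000, length(simulateCuts(prof, 5)))
    expected <- 99 * (1 - (1 - 1 / 99)^5)   # distinct-site expectation
    se <- sd(nReal) / sqrt(length(nReal))
    expect_lt(abs(mean(nReal) - expected), 3 * se + 1e-9)
})

test_that("uniformly protected template realizes binomial cut counts", {
    # all bases at maximal protection: p = 1/1000 everywhere
    shielded <- buildTemplate(149, 1, width = 149)
    prof <- cutProbabilityProfile(shielded, ProtectionParams(1000, 1000))
    expect_true(all(abs(cutProbabilities(prof) - 0.001) < 1e-12))
    res <- simulatePopulation(shielded, ProtectionParams(1000, 1000),
        nCuts = 50, nTemplates = 20000, seed = 9)
    # realized cuts per template = fragments - 1
    meanCuts <- (length(fragmentRanges(allFragments(res))) - 20000) / 20000
    p <- 0.001
    se <- sqrt(50 * p * (1 - p) / 20000)
    expect_lt(abs(meanCuts - 50 * p), 3 * se)
})

test_that("size selection is inclusive, idempotent and validated", {
    fs <- fragmentSetOfLengths(c(100L, 115L, 150L, 195L, 196L))
    sel <- sizeSelect(fs)
    expect_equal(sort(fragmentLengths(sel)), c(115L, 150L, 195L))
    expect_equal(fragmentLengths(sizeSelect(sel)), fragmentLengths(sel))
    expect_length(fragmentLengths(sizeSelect(fragmentSetOfLengths(50L))), 0)
    expect_error(sizeSelect(fs, 200, 100), "minBp")
    # fuzzed idempotence
    set.seed(5)
    for (i in 1:20) {
        f <- fragmentSetOfLengths(sample(50:400, 30, replace = TRUE))
        once <- sizeSelect(f)
        expect_equal(fragmentLengths(sizeSelect(once)), fragmentLengths(once))
    }
})

test_that("percent monos counts mono fragments over remaining fragments", {
    expect_equal(percentMonos(fragmentSetOfLengths(c(150L, 150L, 4000L))),
        2 / 3)
    expect_equal(percentMonos(fragmentSetOfLengths(rep(150L, 5))), 1)
    expect_warning(pm <- percentMonos(fragmentSetOfLengths(c(50L, 60L))),
        "denominator")
    expect_equal(pm, 0)
    # exclusive denominator drops 115-bp fragments from both counts
    fs <- fragmentSetOfLengths(c(115L, 150L, 400L))
    expect_equal(percentMonos(fs), 2 / 3)
    expect_equal(percentMonos(fs, denomInclusive = FALSE), 1 / 2)
})

test_that("population digestion is deterministic given a seed", {
    tpl <- referenceTemplate()
    a <- simulatePopulation(tpl, nCuts = 15, nTemplates = 500, seed = 42)
    b <- simulatePopulation(tpl, nCuts = 15, nTemplates = 500, seed = 42)
    expect_identical(as.data.frame(fragmentRanges(allFragments(a))),
        as.data.frame(fragmentRanges(allFragments(b))))
    expect_identical(percentMonosValue(a), percentMonosValue(b))
    c <- simulatePopulation(tpl, nCuts = 15, nTemplates = 500, seed = 43)
    expect_false(identical(as.data.frame(fragmentRanges(allFragments(a))),
        as.data.frame(fragmentRanges(allFragments(c)))))
    # zero cuts: one full-length fragment per template, no monos
    z <- simulatePopulation(tpl, nCuts = 0, nTemplates = 50, seed = 1)
    expect_equal(percentMonosValue(z), 0)
    expect_equal(fragmentLengths(allFragments(z)), rep(4000L, 50))
})

test_that("signal tabulation conserves fragment mass", {
    tpl <- buildTemplate(4000, integer(0))
    one <- fragmentsFromCuts(tpl, c(1000, 1150))
    tr <- tabulateSignal(one, tpl)
    s <- signalValues(tr)
    expect_equal(s[1001:1150], rep(1, 150))
    expect_equal(sum(s), 4000)   # all three fragments tabulated
    # overlapping fragments stack
    res <- simulatePopulation(referenceTemplate(), nCuts = 25,
        nTemplates = 300, seed = 2)
    sel <- selectedFragments(res)
    tr2 <- tabulateSignal(sel, referenceTemplate())
    expect_equal(sum(signalValues(tr2)), sum(fragmentLengths(sel)))
})

test_that("normalization fixes the norm-region mean at 1 and is scale-free", {
    tpl <- buildTemplate(4000, integer(0))
    uniform <- new("SignalTrack", signal = rep(3.7, 4000))
    norm <- normalizeSignal(uniform, totalSelected = 1234)
    expect_equal(signalValues(norm), rep(1, 4000))
    ramp <- new("SignalTrack", signal = as.numeric(1:4000))
    n1 <- normalizeSignal(ramp, 100)
    n2 <- normalizeSignal(new("SignalTrack", signal = 5 * as.numeric(1:4000)),
        100)
    expect_equal(signalValues(n1), signalValues(n2))
    expect_equal(mean(signalValues(n1)[2501:3500]), 1)
    zero <- new("SignalTrack", signal = c(rep(1, 2000), rep(0, 2000)))
    expect_error(normalizeSignal(zero, 10), "zero signal")
})

test_that("titration reports the central kilobase across cut numbers", {
    tt <- runTitration(referenceTemplate(), nCutsValues = c(10, 30),
        nTemplates = 1500, seed = 3)
    expect_equal(nrow(tt$summary), 2)
    expect_equal(dim(tt$signal), c(1000L, 2L))
    expect_true(all(is.finite(tt$signal)))
    ne <- neighborhoodEffect(tt, referenceTemplate())
    expect_true(all(ne$ratio > 0))
})

test_that("simulated fragment lengths match the closed-form expectation", {
    toy <- toyTemplate()
    prof <- cutProbabilityProfile(toy)
    for (mode in c("attempted", "realized")) {
        e <- expectedFragmentLengthDist(prof, 2, cutMode = mode)
        expect_equal(sum(e * seq_along(e)), 300, tolerance = 1e-9)  # mass
        res <- simulatePopulation(toy, nCuts = 2, nTemplates = 50000,
            seed = 11, cutMode = mode)
        fd <- fragmentLengthDist(allFragments(res))
        sel <- e > 2e-4
        z <- (fd$mean[sel] - e[sel]) / pmax(fd$se[sel], 1e-12)
        expect_gte(mean(abs(z) <= 3), 0.99)
        expect_lt(max(abs(z)), 5)
    }
})

test_that("realized mode equals attempted mode on always-cut DNA", {
    naked <- buildTemplate(200, integer(0))
    prof <- cutProbabilityProfile(naked)
    # p = 1 everywhere: every candidate is realized in both modes
    a <- simulateCuts(prof, 7, cutMode = "attempted", seed = 21)
    r <- simulateCuts(prof, 7, cutMode = "realized", seed = 21)
    expect_equal(a, r)
})
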