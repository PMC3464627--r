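#' Continuous binding profile from probe-level data
#'
#' Sliding-window averaging of probe log2 ratios (as popularized by ChIPOTle
#' for ChIP-chip data): each window's value is the mean log2 ratio of probes
#' whose midpoints fall inside it, assigned to the step-resolution bin at the
#' window start. Bins whose window contains no probe midpoint are missing
#' (NA).
#'
#' @param probes a \linkS4class{GRanges} with metadata column
#'   \code{log2ratio}, or a data.frame with columns \code{chrom},
#'   \code{start}, \code{end}, \code{log2ratio} (1-based closed).
#' @param seqlengths named vector of sequence lengths.
#' @param windowBp sliding window size (default 500).
#' @param stepBp window step = output bin width (default 250).
#' @return a [BindingProfile-class].
#' @export
continuousBindingProfile <- function(probes, seqlengths, windowBp = 500L,
        stepBp = 250L) {
    if (windowBp < stepBp)
        stop("windowBp must be >= stepBp")
    seqlengths <- checkSeqlengths(seqlengths)
    if (is.data.frame(probes))
        probes <- GRanges(probes$chrom, IRanges(probes$start, probes$end),
            log2ratio = probes$log2ratio)
    if (is.null(mcols(probes)$log2ratio))
        stop("probes need a 'log2ratio' metadata column")
    mid <- (start(probes) + end(probes)) %/% 2L
    chr <- as.character(seqnames(probes))
    vals <- lapply(names(seqlengths), function(cn) {
        L <- seqlengths[[cn]]
        binStarts <- .binStarts(L, stepBp)
        out <- rep(NA_real_, length(binStarts))
        sel <- chr == cn
        if (!any(sel))
            return(out)
        m <- mid[sel]; v <- mcols(probes)$log2ratio[sel]
        win <- IRanges(start = binStarts,
            end = pmin(binStarts + windowBp - 1L, L))
        hits <- findOverlaps(IRanges(m, m), win)
        if (length(hits)) {
            s <- tapply(v[queryHits(hits)], subjectHits(hits), mean)
            out[as.integer(names(s))] <- as.numeric(s)
        }
        out
    })
    names(vals) <- names(seqlengths)
    new("BindingProfile", values = vals, binWidth = as.integer(stepBp),
        seqlengths = seqlengths, windowBp = as.integer(windowBp))
}

setMethod("show", "BindingProfile", function(object) {
    nb <- sum(vapply(object@values, length, 1L))
    miss <- sum(vapply(object@values, function(v) sum(is.na(v)), 1L))
    cat(sprintf(
        "BindingProfile: %d bins of %d bp (window %d bp), %d missing\n",
        nb, object@binWidth, object@windowBp, miss))
})

#' Mean binding signal per region
#'
#' Averages the non-missing profile bins overlapping each region. Regions
#' with no covered (non-NA) bins are excluded from the returned means and
#' counted.
#'
#' @param profile a [BindingProfile-class].
#' @param regions a \linkS4class{GRanges}.
#' @return list with \code{means} (numeric, one per retained region, named by
#'   region index), \code{nExcluded} (regions without data) and
#'   \code{kept} (logical per input region).
#' @export
regionMeanBinding <- function(profile, regions) {
    bin <- profile@binWidth
    chr <- as.character(seqnames(regions))
    means <- vapply(seq_along(regions), function(i) {
        v <- profile@values[[chr[i]]]
        if (is.null(v))
            return(NA_real_)
        b1 <- (start(regions)[i] - 1L) %/% bin + 1L
        b2 <- (end(regions)[i] - 1L) %/% bin + 1L
        b2 <- min(b2, length(v))
        if (b1 > b2)
            return(NA_real_)
        vv <- v[b1:b2]
        if (all(is.na(vv)))
            return(NA_real_)
        mean(vv, na.rm = TRUE)
    }, numeric(1L))
    kept <- !is.na(means)
    list(means = stats::setNames(means[kept], which(kept)),
        nExcluded = sum(!kept), kept = kept)
}

#' Random genomic regions of fixed size
#'
#' Samples \code{count} regions of exactly \code{sizeBp}, chromosomes chosen
#' proportionally to their number of valid placements and start positions
#' uniform among them; the random-region null for enrichment testing.
#'
#' @param seqlengths named vector of sequence lengths.
#' @param count number of regions (default 10000).
#' @param sizeBp region size in bp (typically the mean dissimilar-region
#'   size).
#' @param seed optional integer seed.
#' @return a \linkS4class{GRanges} of \code{count} regions.
#' @export
randomRegions <- function(seqlengths, count = 10000L, sizeBp, seed = NULL) {
    seqlengths <- checkSeqlengths(seqlengths)
    placeable <- pmax(seqlengths - as.integer(sizeBp) + 1L, 0L)
    if (all(placeable == 0L))
        stop("sizeBp exceeds every chromosome length")
    withSeed(seed, {
        chrIdx <- sample.int(length(seqlengths), count, replace = TRUE,
            prob = placeable)
        starts <- floor(runif(count) * placeable[chrIdx]) + 1L
        GRanges(names(seqlengths)[chrIdx],
            IRanges(start = as.integer(starts), width = as.integer(sizeBp)),
            seqlengths = seqlengths)
    })
}

#' Binding enrichment test against a random-region null
#'
#' One-tailed heteroscedastic (Welch) t-test comparing the distribution of
#' per-region mean binding at the observed (e.g. dissimilar) regions against
#' the per-region means of a random-region null, testing for observed >
#' null.
#'
#' @param observedMeans per-region means at the observed regions (>= 2
#'   values).
#' @param nullMeans per-region means at the random regions (>= 2 values).
#' @return an [EnrichmentResult-class].
#' @export
enrichmentTest <- function(observedMeans, nullMeans) {
    observedMeans <- observedMeans[!is.na(observedMeans)]
    nullMeans <- nullMeans[!is.na(nullMeans)]
    if (length(observedMeans) < 2L || length(nullMeans) < 2L)
        stop("need at least 2 non-missing values per group")
    if (stats::sd(observedMeans) == 0 && stats::sd(nullMeans) == 0)
        stop("degenerate (zero) variance in both groups")
    ht <- t.test(observedMeans, nullMeans, alternative = "greater",
        var.equal = FALSE)
    new("EnrichmentResult", observedMeans = unname(observedMeans),
        nullMeans = unname(nullMeans),
        t = unname(ht$statistic), p = ht$p.value,
        nObserved = length(observedMeans), nNull = length(nullMeans))
}

#' p-value of an EnrichmentResult
#' @param x an [EnrichmentResult-class].
#' @return one-tailed p-value.
#' @export
enrichmentP <- function(x) x@p

setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf(
        "EnrichmentResult: mean %.3f (n = %d) vs null %.3f (n = %d); Welch t = %.3f, one-tailed p = %.3g\n",
        mean(object@observedMeans), object@nObserved,
        mean(object@nullMeans), object@nNull, object@t, object@p))
})

#' Full enrichment analysis of dissimilar regions
#'
#' Convenience wrapper: builds the continuous binding profile, computes
#' per-region means for the dissimilar regions, draws the random-region null
#' (sized to the mean dissimilar-region length) and runs the one-tailed
#' Welch test.
#'
#' @param probes probe-level binding records (see
#'   [continuousBindingProfile()]).
#' @param regions dissimilar regions (\linkS4class{GRanges}).
#' @param seqlengths named vector of sequence lengths.
#' @param nRandom number of random regions (default 10000).
#' @param windowBp,stepBp sliding-window parameters for the binding profile.
#' @param seed optional integer seed for the random regions.
#' @return an [EnrichmentResult-class]; the numbers of regions excluded for
#'   missing data are in \code{attr(result, "excluded")}.
#' @export
enrichmentAnalysis <- function(probes, regions, seqlengths, nRandom = 10000L,
        windowBp = 500L, stepBp = 250L, seed = NULL) {
    prof <- continuousBindingProfile(probes, seqlengths, windowBp = windowBp,
        stepBp = stepBp)
    obs <- regionMeanBinding(prof, regions)
    sizeBp <- max(1L, as.integer(round(mean(width(regions)))))
    rnd <- randomRegions(seqlengths, count = nRandom, sizeBp = sizeBp,
        seed = seed)
    nul <- regionMeanBinding(prof, rnd)
    res <- enrichmentTest(obs$means, nul$means)
    attr(res, "excluded") <- c(observed = obs$nExcluded, null = nul$nExcluded)
    res
}
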