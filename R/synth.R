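#' Specification of a synthetic MNase-seq track pair
#'
#' Describes the generative model for a pair of synthetic coverage tracks
#' that emulate the statistical structure replicate MNase-seq comparisons
#' assume: a shared underlying nucleosome occupancy signal, independent
#' per-bin counting (Poisson) noise in each track, optional planted
#' "dissimilar" regions where the second track's underlying signal is
#' replaced by an independent one, and optional digestion-extent sampling
#' bias per track.
#'
#' The occupancy signal is a train of Gaussian peaks at nucleosome dyads
#' spaced \code{spacingBp} apart (yeast-like ~165 bp), on a flat baseline.
#' Every \code{longLinkerPeriod}-th linker is widened by
#' \code{longLinkerExtraBp}, mimicking promoter nucleosome-depleted regions
#' (NDRs). Each track carries a digestion bias (\code{biasA}, \code{biasB}):
#' the neighborhood over-representation factor of long-flanked nucleosomes
#' measured at that track's extent of digestion (1 = complete digestion).
#' A bias b > 1 distorts the track's underlying signal the way
#' under-digested chromatin preparations are distorted in vivo: the two
#' nucleosome peaks flanking each long linker are amplified b-fold and drawn
#' toward the NDR, and a narrower sub-nucleosomal particle of amplitude
#' proportional to (b - 1) appears inside the NDR (the MNase-sensitive
#' fragile particles of under-digested preparations). At b = 1 all of these
#' vanish and the track reflects the clean occupancy landscape.
#'
#' @param seqlengths named vector of sequence lengths (default two 500-kb
#'   chromosomes).
#' @param binBp bin width (default 10).
#' @param spacingBp nucleosome repeat length (default 162 = 147 + 15).
#' @param peakSdBp Gaussian peak standard deviation (default 40).
#' @param amplitude peak amplitude over baseline (default 1).
#' @param baseline flat background occupancy (default 0.1).
#' @param depth mean per-bin count at unit relative signal (default 100,
#'   i.e. deeply sequenced yeast-scale data).
#' @param plants \linkS4class{GRanges} of planted dissimilar regions
#'   (default none).
#' @param longLinkerPeriod every k-th linker is long (default 10).
#' @param longLinkerExtraBp extra width of long linkers (default 127, making
#'   142-bp linkers from 15-bp ones).
#' @param biasA,biasB digestion-bias factors for tracks a and b (default 1 =
#'   complete digestion).
#' @param noise \code{"poisson"} (default) for per-bin counting noise at the
#'   given depth, or \code{"none"} for the deterministic expected signal.
#' @param seed integer seed.
#' @return a list of class \code{SyntheticTrackSpec}.
#' @seealso [synthTrackPair()]
#' @export
SyntheticTrackSpec <- function(seqlengths = c(chrI = 500000L, chrII = 500000L),
        binBp = 10L, spacingBp = 162L, peakSdBp = 40, amplitude = 1,
        baseline = 0.1, depth = 100, plants = GRanges(),
        longLinkerPeriod = 10L, longLinkerExtraBp = 127L,
        biasA = 1, biasB = 1, noise = c("poisson", "none"), seed = NULL) {
    noise <- match.arg(noise)
    seqlengths <- checkSeqlengths(seqlengths)
    if (length(plants)) {
        bad <- setdiff(unique(as.character(seqnames(plants))),
            names(seqlengths))
        if (length(bad))
            stop("plants on unknown chromosome(s): ",
                paste(bad, collapse = ", "))
    }
    stopifnot(depth > 0, amplitude >= 0, baseline >= 0)
    structure(list(seqlengths = seqlengths, binBp = as.integer(binBp),
        spacingBp = as.integer(spacingBp), peakSdBp = peakSdBp,
        amplitude = amplitude, baseline = baseline, depth = depth,
        plants = plants, longLinkerPeriod = as.integer(longLinkerPeriod),
        longLinkerExtraBp = as.integer(longLinkerExtraBp),
        biasA = biasA, biasB = biasB, noise = noise, seed = seed),
        class = "SyntheticTrackSpec")
}

# Dyad positions for one chromosome, with flags for the nucleosomes
# preceding/following each long linker and the long-linker (NDR) midpoints;
# phase shifts the whole array (used for the independent replacement signal
# inside plants).
.dyadLayout <- function(L, spacingBp, longLinkerPeriod, longLinkerExtraBp,
        phase = 0L) {
    pos <- 80L + phase
    dyads <- integer(0); preLong <- logical(0)
    k <- 0L
    while (pos <= L) {
        dyads <- c(dyads, pos)
        k <- k + 1L
        isLong <- longLinkerPeriod > 0L && k %% longLinkerPeriod == 0L
        preLong <- c(preLong, isLong)
        pos <- pos + spacingBp + if (isLong) longLinkerExtraBp else 0L
    }
    postLong <- c(FALSE, preLong[-length(preLong)])
    ndrMid <- as.integer(round(dyads[preLong] +
        (spacingBp + longLinkerExtraBp) / 2))
    ndrMid <- ndrMid[ndrMid <= L]
    list(dyads = dyads, preLong = preLong, postLong = postLong,
        longFlanked = preLong | postLong, ndrMid = ndrMid)
}

# How a digestion bias b (the neighborhood over-representation factor of
# long-flanked nucleosomes; 1 at complete digestion) distorts the partial
# digest's occupancy signal, following what under-digested preparations show
# in vivo: long-flanked peaks amplified b-fold, flanking cores drawn toward
# the NDR, and a narrower sub-nucleosomal particle appearing inside the NDR.
.BIAS_SHIFT_BP_PER_UNIT <- 40      # flank repositioning per unit of (b - 1)
.BIAS_NDR_AMP_PER_UNIT <- 0.75    # NDR particle amplitude per unit of (b - 1)
.BIAS_NDR_SD_FRACTION <- 0.6      # NDR particle width relative to peakSdBp

# Expected occupancy per bin for one chromosome given a dyad layout and a
# digestion bias.
.occupancyLambda <- function(L, binBp, layout, peakSdBp, amplitude, baseline,
        bias) {
    centers <- .binStarts(L, binBp) + (binBp - 1) / 2
    lam <- rep(baseline, length(centers))
    w <- ifelse(layout$longFlanked, bias, 1)
    shift <- .BIAS_SHIFT_BP_PER_UNIT * (bias - 1)
    pos <- layout$dyads +
        ifelse(layout$preLong & !layout$postLong, shift, 0) -
        ifelse(layout$postLong & !layout$preLong, shift, 0)
    addPeak <- function(lam, d, amp, sd) {
        span <- 4 * sd
        j <- which(centers >= d - span & centers <= d + span)
        lam[j] <- lam[j] + amp * exp(-((centers[j] - d)^2) / (2 * sd^2))
        lam
    }
    for (i in seq_along(pos))
        lam <- addPeak(lam, pos[i], amplitude * w[i], peakSdBp)
    ndrAmp <- amplitude * .BIAS_NDR_AMP_PER_UNIT * (bias - 1)
    if (ndrAmp > 0)
        for (d in layout$ndrMid)
            lam <- addPeak(lam, d, ndrAmp,
                peakSdBp * .BIAS_NDR_SD_FRACTION)
    lam
}

#' Generate a synthetic MNase-seq coverage track pair with planted truth
#'
#' Builds two coverage tracks from a [SyntheticTrackSpec()]: both share the
#' underlying occupancy signal (with each track's own digestion bias);
#' inside the planted regions, track b's underlying signal is replaced by an
#' independent occupancy signal (a half-repeat phase-shifted nucleosome
#' array), making those regions genuinely decorrelated. Independent Poisson
#' counting noise is then drawn per track. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a [SyntheticTrackSpec()].
#' @return list with \code{a}, \code{b} ([CoverageTrack-class]) and
#'   \code{truth} (the planted regions, \linkS4class{GRanges}).
#' @examples
#' spec <- SyntheticTrackSpec(seqlengths = c(chr = 50000L), seed = 1)
#' pair <- synthTrackPair(spec)
#' genomeCorrelation(pair$a, pair$b)
#' @export
synthTrackPair <- function(spec) {
    stopifnot(inherits(spec, "SyntheticTrackSpec"))
    withSeed(spec$seed, {
        valsA <- list(); valsB <- list()
        for (chr in names(spec$seqlengths)) {
            L <- spec$seqlengths[[chr]]
            base <- .dyadLayout(L, spec$spacingBp, spec$longLinkerPeriod,
                spec$longLinkerExtraBp)
            # quarter-repeat phase shift: the replacement array is
            # uncorrelated with the base array (a half shift would be
            # anticorrelated, which no real chromatin change produces)
            alt <- .dyadLayout(L, spec$spacingBp, spec$longLinkerPeriod,
                spec$longLinkerExtraBp, phase = spec$spacingBp %/% 4L)
            lamA <- .occupancyLambda(L, spec$binBp, base, spec$peakSdBp,
                spec$amplitude, spec$baseline, spec$biasA)
            lamB <- .occupancyLambda(L, spec$binBp, base, spec$peakSdBp,
                spec$amplitude, spec$baseline, spec$biasB)
            plantsHere <- spec$plants[seqnames(spec$plants) == chr]
            if (length(plantsHere)) {
                lamAlt <- .occupancyLambda(L, spec$binBp, alt, spec$peakSdBp,
                    spec$amplitude, spec$baseline, spec$biasB)
                for (i in seq_along(plantsHere)) {
                    b1 <- (start(plantsHere)[i] - 1L) %/% spec$binBp + 1L
                    b2 <- min((end(plantsHere)[i] - 1L) %/% spec$binBp + 1L,
                        length(lamB))
                    lamB[b1:b2] <- lamAlt[b1:b2]
                }
            }
            scale <- spec$depth / mean(lamA)
            if (identical(spec$noise, "none")) {
                valsA[[chr]] <- lamA * scale
                valsB[[chr]] <- lamB * scale
            } else {
                valsA[[chr]] <- as.numeric(rpois(length(lamA), lamA * scale))
                valsB[[chr]] <- as.numeric(rpois(length(lamB), lamB * scale))
            }
        }
        list(a = CoverageTrack(valsA, spec$binBp, spec$seqlengths,
                metadata = list(source = "synthetic", role = "a")),
            b = CoverageTrack(valsB, spec$binBp, spec$seqlengths,
                metadata = list(source = "synthetic", role = "b")),
            truth = spec$plants)
    })
}

#' Evenly spaced planted regions
#'
#' Deterministic helper placing \code{nPerChrom} equal-sized regions at even
#' intervals along each chromosome — convenient ground truth for
#' planted-recovery experiments.
#'
#' @param seqlengths named vector of sequence lengths.
#' @param nPerChrom regions per chromosome.
#' @param sizeBp region size.
#' @return a \linkS4class{GRanges}.
#' @export
evenlySpacedRegions <- function(seqlengths, nPerChrom, sizeBp) {
    seqlengths <- checkSeqlengths(seqlengths)
    pieces <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        centers <- round(L * (seq_len(nPerChrom) - 0.5) / nPerChrom)
        starts <- pmax(1L, as.integer(centers - sizeBp %/% 2L))
        GRanges(chr, IRanges(start = starts, width = sizeBp),
            seqlengths = seqlengths)
    })
    do.call(c, pieces)
}

#' Generate synthetic probe-level binding data
#'
#' Tiles probes along the genome and assigns each a log2 ratio of
#' \code{backgroundMean}, plus \code{effect} when the probe midpoint falls
#' inside one of \code{regions}, plus Gaussian noise. Deterministic per
#' seed.
#'
#' @param seqlengths named vector of sequence lengths.
#' @param regions \linkS4class{GRanges} carrying the planted effect.
#' @param backgroundMean background log2 ratio (default 0).
#' @param effect added log2 ratio inside regions (default 0).
#' @param probeSpacing distance between probe starts (default 250).
#' @param probeWidth probe width in bp (default 50).
#' @param noiseSd Gaussian noise standard deviation (default 0.5).
#' @param seed optional integer seed.
#' @return a \linkS4class{GRanges} with metadata column \code{log2ratio}.
#' @export
synthBinding <- function(seqlengths, regions = GRanges(), backgroundMean = 0,
        effect = 0, probeSpacing = 250L, probeWidth = 50L, noiseSd = 0.5,
        seed = NULL) {
    seqlengths <- checkSeqlengths(seqlengths)
    pieces <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        starts <- .binStarts(L, probeSpacing)
        GRanges(chr, IRanges(start = starts,
            end = pmin(starts + probeWidth - 1L, L)),
            seqlengths = seqlengths)
    })
    probes <- do.call(c, pieces)
    mid <- (start(probes) + end(probes)) %/% 2L
    inRegion <- rep(FALSE, length(probes))
    if (length(regions)) {
        hits <- findOverlaps(GRanges(seqnames(probes), IRanges(mid, mid)),
            regions)
        inRegion[unique(queryHits(hits))] <- TRUE
    }
    withSeed(seed, {
        mcols(probes)$log2ratio <- backgroundMean + effect * inRegion +
            rnorm(length(probes), sd = noiseSd)
    })
    probes
}
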