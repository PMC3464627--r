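#' CoverageTrack constructor
#'
#' @param values named list of per-sequence numeric bin vectors.
#' @param binWidth bin width in bp.
#' @param seqlengths named vector of sequence lengths; bins must tile each
#'   sequence from base 1 (last bin may be partial).
#' @param metadata optional list of provenance metadata.
#' @return a [CoverageTrack-class].
#' @export
CoverageTrack <- function(values, binWidth, seqlengths, metadata = list()) {
    seqlengths <- checkSeqlengths(seqlengths)
    new("CoverageTrack", values = lapply(values[names(seqlengths)], as.numeric),
        binWidth = as.integer(binWidth), seqlengths = seqlengths,
        metadata = metadata)
}

#' Per-sequence bin values of a track
#' @param x a [CoverageTrack-class] or [BindingProfile-class].
#' @param seqname optional sequence name; when omitted, the full named list.
#' @return numeric vector or named list of numeric vectors.
#' @export
trackValues <- function(x, seqname = NULL) {
    if (is.null(seqname)) x@values else x@values[[seqname]]
}

#' Bin width of a track
#' @param x a [CoverageTrack-class] or [BindingProfile-class].
#' @return integer bin width in bp.
#' @export
trackBinWidth <- function(x) x@binWidth

#' Sequence lengths of a track
#' @param x a [CoverageTrack-class] or [BindingProfile-class].
#' @return named integer vector.
#' @export
trackSeqlengths <- function(x) x@seqlengths

setMethod("show", "CoverageTrack", function(object) {
    tot <- sum(vapply(object@values, sum, 1))
    cat(sprintf(
        "CoverageTrack: %d sequence(s), %d-bp bins, %d bins, total signal %.4g\n",
        length(object@seqlengths), object@binWidth,
        sum(vapply(object@values, length, 1L)), tot))
})

.binStarts <- function(L, bin) seq.int(1L, L, by = bin)

#' Binned coverage from aligned fragment intervals
#'
#' Tabulates per-bin mean per-base coverage from fragment (or read) intervals,
#' the downstream representation of already-aligned MNase-seq data.
#' Single-end reads can optionally be extended 3'-ward to a fixed fragment
#' length before tabulation.
#'
#' @param fragments a \linkS4class{GRanges} of fragment intervals (strand is
#'   only used when extending).
#' @param seqlengths named vector of sequence lengths.
#' @param binBp bin width in bp (default 10).
#' @param extendTo optional length (bp) to which each record is resized
#'   3'-ward (e.g. 147 for single-end MNase reads); NULL (default) uses
#'   records as-is.
#' @return a [CoverageTrack-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chrI", IRanges::IRanges(11, 160))
#' tr <- coverageFromFragments(gr, c(chrI = 1000))
#' trackValues(tr, "chrI")[1:4]
#' @export
coverageFromFragments <- function(fragments, seqlengths, binBp = 10L,
        extendTo = NULL) {
    seqlengths <- checkSeqlengths(seqlengths)
    bad <- setdiff(unique(as.character(seqnames(fragments))), names(seqlengths))
    if (length(bad))
        stop("unknown chromosome(s) in fragments: ", paste(bad, collapse = ", "))
    if (!is.null(extendTo))
        fragments <- GenomicRanges::resize(fragments, width = extendTo,
            fix = "start")
    vals <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        r <- IRanges::ranges(fragments[seqnames(fragments) == chr])
        r <- IRanges::restrict(r, start = 1L, end = L)
        cov <- coverage(r, width = L)
        starts <- .binStarts(L, binBp)
        v <- Views(cov, start = starts, end = pmin(starts + binBp - 1L, L))
        viewMeans(v)
    })
    names(vals) <- names(seqlengths)
    CoverageTrack(vals, binBp, seqlengths,
        metadata = list(source = "fragments",
            extendTo = if (is.null(extendTo)) NA_integer_ else extendTo))
}

#' Standardize a track to a fixed genome-wide total
#'
#' Scales the track so its genome-wide total signal equals
#' \code{targetTotal}, the track analogue of standardizing the number of
#' sequence reads between experiments. Pearson correlations are invariant to
#' this scaling; it only fixes a common unit.
#'
#' @param track a [CoverageTrack-class].
#' @param targetTotal target genome-wide total (default 1e6).
#' @return the rescaled [CoverageTrack-class].
#' @export
standardizeTrack <- function(track, targetTotal = 1e6) {
    tot <- sum(vapply(track@values, sum, 1))
    if (tot <= 0)
        stop("cannot standardize a track with zero total signal")
    sc <- targetTotal / tot
    md <- track@metadata
    md$standardizedTo <- targetTotal
    CoverageTrack(lapply(track@values, `*`, sc), track@binWidth,
        track@seqlengths, md)
}

#' Re-bin a track to a coarser resolution
#'
#' @param track a [CoverageTrack-class].
#' @param newBinBp new bin width, a multiple of the current one.
#' @return a [CoverageTrack-class] whose bins are means of the constituent
#'   fine bins.
#' @export
rebinTrack <- function(track, newBinBp) {
    if (newBinBp %% track@binWidth != 0L)
        stop("newBinBp must be a multiple of the current bin width")
    k <- newBinBp %/% track@binWidth
    if (k == 1L)
        return(track)
    vals <- lapply(track@values, function(v) {
        grp <- (seq_along(v) - 1L) %/% k
        as.numeric(tapply(v, grp, mean))
    })
    CoverageTrack(vals, newBinBp, track@seqlengths, track@metadata)
}

.checkComparable <- function(a, b) {
    if (!identical(a@seqlengths, b@seqlengths))
        stop("tracks are on different genomes (seqlengths differ)")
    if (a@binWidth != b@binWidth)
        stop("tracks have different bin widths")
    invisible(TRUE)
}

# Rolling-sum Pearson correlations of two bin vectors for windows of wBins
# bins starting every sBins bins. Globally pre-centered for numerical
# stability; returns NA for zero-variance windows.
.rollingPearson <- function(x, y, wBins, sBins) {
    n <- length(x)
    if (n < wBins)
        return(list(startBin = integer(0), r = numeric(0)))
    x <- x - mean(x); y <- y - mean(y)
    cx <- c(0, cumsum(x)); cy <- c(0, cumsum(y))
    cxx <- c(0, cumsum(x * x)); cyy <- c(0, cumsum(y * y))
    cxy <- c(0, cumsum(x * y))
    s <- seq.int(1L, n - wBins + 1L, by = sBins)
    e <- s + wBins - 1L
    Sx <- cx[e + 1L] - cx[s]; Sy <- cy[e + 1L] - cy[s]
    Sxx <- cxx[e + 1L] - cxx[s]; Syy <- cyy[e + 1L] - cyy[s]
    Sxy <- cxy[e + 1L] - cxy[s]
    vx <- Sxx - Sx^2 / wBins
    vy <- Syy - Sy^2 / wBins
    cv <- Sxy - Sx * Sy / wBins
    tolx <- 1e-10 * (Sxx + 1e-300)
    toly <- 1e-10 * (Syy + 1e-300)
    r <- ifelse(vx > tolx & vy > toly, cv / sqrt(pmax(vx, 0) * pmax(vy, 0)),
        NA_real_)
    r <- pmin(pmax(r, -1), 1)
    list(startBin = s, r = r)
}

#' Windowed Pearson correlations between two tracks
#'
#' Computes the Pearson correlation of binned signal in fixed-size windows,
#' either tiling (step = window, the default) or sliding at a finer step.
#' Windows with zero variance in either track are flagged with \code{r = NA}.
#'
#' @param a,b [CoverageTrack-class] objects on the same genome and bin width.
#' @param windowBp window size in bp (default 1000), a multiple of the bin
#'   width.
#' @param stepBp step between window starts (default \code{windowBp}, i.e.
#'   non-overlapping tiling), a multiple of the bin width.
#' @return a [WindowCorrelationSet-class].
#' @export
windowCorrelations <- function(a, b, windowBp = 1000L, stepBp = windowBp) {
    .checkComparable(a, b)
    bin <- a@binWidth
    if (windowBp %% bin != 0L || stepBp %% bin != 0L)
        stop("windowBp and stepBp must be multiples of the track bin width")
    wBins <- windowBp %/% bin
    sBins <- stepBp %/% bin
    pieces <- lapply(names(a@seqlengths), function(chr) {
        rp <- .rollingPearson(a@values[[chr]], b@values[[chr]], wBins, sBins)
        if (!length(rp$startBin))
            return(NULL)
        g <- GRanges(chr, IRanges(start = (rp$startBin - 1L) * bin + 1L,
            width = windowBp), seqlengths = a@seqlengths)
        mcols(g)$r <- rp$r
        g
    })
    pieces <- pieces[!vapply(pieces, is.null, TRUE)]
    gr <- if (length(pieces)) do.call(c, pieces)
        else GRanges(seqlengths = a@seqlengths)
    new("WindowCorrelationSet", windows = gr,
        windowBp = as.integer(windowBp), stepBp = as.integer(stepBp))
}

#' Windows (with r values) of a WindowCorrelationSet
#' @param x a [WindowCorrelationSet-class].
#' @return a \linkS4class{GRanges} with metadata column \code{r}.
#' @export
correlationWindows <- function(x) x@windows

setMethod("show", "WindowCorrelationSet", function(object) {
    r <- mcols(object@windows)$r
    cat(sprintf(
        "WindowCorrelationSet: %d windows of %d bp (step %d bp), %d undefined\n",
        length(object@windows), object@windowBp, object@stepBp,
        sum(is.na(r))))
    if (any(!is.na(r)))
        cat(sprintf("  r: median %.3f, fraction > 0.9: %.3f, fraction < 0.5: %.3f\n",
            stats::median(r, na.rm = TRUE), mean(r > 0.9, na.rm = TRUE),
            mean(r < 0.5, na.rm = TRUE)))
})

#' Histogram and summary fractions of window correlations
#'
#' @param set a [WindowCorrelationSet-class].
#' @param binEdges histogram bin edges over [-1, 1] (default width 0.05).
#' @return list with \code{breaks}, \code{counts}, \code{fractionAbove0.9},
#'   \code{fractionBelow0.5}, \code{nDefined}, \code{nUndefined}. Fractions
#'   are over defined (non-NA) windows; undefined windows are excluded and
#'   counted.
#' @export
correlationHistogram <- function(set, binEdges = seq(-1, 1, by = 0.05)) {
    r <- mcols(set@windows)$r
    def <- r[!is.na(r)]
    counts <- if (length(def))
        graphics::hist(def, breaks = binEdges, plot = FALSE,
            include.lowest = TRUE)$counts
    else
        integer(length(binEdges) - 1L)
    list(breaks = binEdges, counts = counts,
        fractionAbove0.9 = if (length(def)) mean(def > 0.9) else NA_real_,
        fractionBelow0.5 = if (length(def)) mean(def < 0.5) else NA_real_,
        nDefined = length(def), nUndefined = sum(is.na(r)))
}

#' Genome-to-genome Pearson correlation between two tracks
#'
#' A single correlation over all genome bins at the given resolution
#' (default 100 bp).
#'
#' @param a,b [CoverageTrack-class] objects on the same genome.
#' @param resolutionBp resolution for the comparison (default 100), a
#'   multiple of the bin width.
#' @return Pearson r, or NA when either rebinned track has zero variance.
#' @export
genomeCorrelation <- function(a, b, resolutionBp = 100L) {
    .checkComparable(a, b)
    ra <- rebinTrack(a, resolutionBp)
    rb <- rebinTrack(b, resolutionBp)
    x <- unlist(ra@values, use.names = FALSE)
    y <- unlist(rb@values, use.names = FALSE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        return(NA_real_)
    cor(x, y)
}

#' Detect dissimilar chromatin regions between two tracks
#'
#' Slides a Pearson-correlation window across the genome, marks windows whose
#' correlation falls below \code{rCutoff}, merges overlapping or abutting
#' marked windows, and retains merged regions spanning at least
#' \code{minSpanBp}. Zero-variance windows are never marked (insufficient
#' evidence).
#'
#' @param a,b [CoverageTrack-class] objects on the same genome and bin width.
#' @param rCutoff correlation cutoff (default 0.5; a window is marked when
#'   \code{r < rCutoff}).
#' @param minSpanBp minimum merged span retained (default 1000).
#' @param windowBp sliding window size (default 1000).
#' @param stepBp sliding step (default 10).
#' @return a [DissimilarRegionSet-class].
#' @export
dissimilarRegions <- function(a, b, rCutoff = 0.5, minSpanBp = 1000L,
        windowBp = 1000L, stepBp = 10L) {
    wcs <- windowCorrelations(a, b, windowBp = windowBp, stepBp = stepBp)
    w <- wcs@windows
    r <- mcols(w)$r
    marked <- w[!is.na(r) & r < rCutoff]
    merged <- reduce(marked)
    merged <- merged[width(merged) >= minSpanBp]
    if (length(merged)) {
        hits <- findOverlaps(merged, marked)
        minR <- tapply(mcols(marked)$r[subjectHits(hits)], queryHits(hits), min)
        mcols(merged)$minR <- as.numeric(minR)
    } else {
        mcols(merged)$minR <- numeric(0)
    }
    new("DissimilarRegionSet", regions = merged, rCutoff = rCutoff,
        minSpanBp = as.integer(minSpanBp), windowBp = as.integer(windowBp),
        stepBp = as.integer(stepBp))
}

#' Regions of a DissimilarRegionSet
#' @param x a [DissimilarRegionSet-class].
#' @return a \linkS4class{GRanges} with metadata column \code{minR}.
#' @export
dissimilarRegionRanges <- function(x) x@regions

setMethod("show", "DissimilarRegionSet", function(object) {
    cat(sprintf(
        "DissimilarRegionSet: %d region(s) (r < %g, span >= %d bp; window %d bp, step %d bp)\n",
        length(object@regions), object@rCutoff, object@minSpanBp,
        object@windowBp, object@stepBp))
})

#' Annotate reference nucleosomes with adjacent linker sizes and classes
#'
#' For each reference nucleosome, computes the distance to its neighbors on
#' the same chromosome (left and right adjacent linkers) and classifies each
#' side as \code{normal} (within \code{normal} bp), \code{long} (within
#' \code{long} bp), or \code{other} (outside both, or no neighbor).
#'
#' @param ref a \linkS4class{GRanges} of nucleosome positions.
#' @param normal inclusive normal-linker size range (default \code{c(10, 20)},
#'   centered on the mean yeast linker).
#' @param long inclusive long-linker size range (default \code{c(21, 221)},
#'   up to ~1.5x a nucleosome template).
#' @return the sorted \code{ref} with metadata columns \code{leftLinker},
#'   \code{rightLinker}, \code{leftClass}, \code{rightClass} and
#'   \code{bothClass} (\code{normal}/\code{long} when the two sides agree,
#'   else \code{mixed}).
#' @export
annotateLinkers <- function(ref, normal = c(10, 20), long = c(21, 221)) {
    ref <- sort(ref)
    chr <- as.character(seqnames(ref))
    left <- rep(NA_integer_, length(ref))
    right <- rep(NA_integer_, length(ref))
    samePrev <- c(FALSE, chr[-1L] == chr[-length(chr)])
    gapPrev <- start(ref) - c(0L, end(ref)[-length(ref)]) - 1L
    left[samePrev] <- gapPrev[samePrev]
    sameNext <- c(chr[-length(chr)] == chr[-1L], FALSE)
    gapNext <- c(start(ref)[-1L], 0L) - end(ref) - 1L
    right[sameNext] <- gapNext[sameNext]
    classify <- function(w) {
        cl <- rep("other", length(w))
        cl[!is.na(w) & w >= normal[1L] & w <= normal[2L]] <- "normal"
        cl[!is.na(w) & w >= long[1L] & w <= long[2L]] <- "long"
        cl
    }
    mcols(ref)$leftLinker <- left
    mcols(ref)$rightLinker <- right
    mcols(ref)$leftClass <- classify(left)
    mcols(ref)$rightClass <- classify(right)
    both <- rep("mixed", length(ref))
    agree <- mcols(ref)$leftClass == mcols(ref)$rightClass &
        mcols(ref)$leftClass %in% c("normal", "long")
    both[agree] <- mcols(ref)$leftClass[agree]
    mcols(ref)$bothClass <- both
    ref
}

#' Average dyad-aligned profiles by linker class
#'
#' Selects reference nucleosomes whose two adjacent linkers belong to the
#' same size class (both normal, or both long), aligns the track signal on
#' each nucleosome's dyad, and averages per class over \code{±flankBp}.
#'
#' @param track a [CoverageTrack-class].
#' @param ref nucleosome reference \linkS4class{GRanges} (annotated with
#'   [annotateLinkers()] on the fly if needed).
#' @param normal,long linker class definitions, see [annotateLinkers()].
#' @param flankBp half-width of the profile around the dyad (default 1000).
#' @return list with \code{offset} (bp relative to dyad, bin-resolution),
#'   \code{normal} and \code{long} (mean profiles), \code{nNormal},
#'   \code{nLong} (nucleosomes averaged).
#' @export
linkerClassProfiles <- function(track, ref, normal = c(10, 20),
        long = c(21, 221), flankBp = 1000L) {
    if (is.null(mcols(ref)$bothClass))
        ref <- annotateLinkers(ref, normal = normal, long = long)
    bin <- track@binWidth
    flankBins <- as.integer(flankBp) %/% bin
    offsets <- (-flankBins):flankBins
    classMean <- function(cls) {
        sel <- ref[mcols(ref)$bothClass == cls]
        if (!length(sel))
            return(list(mean = rep(NA_real_, length(offsets)), n = 0L))
        chr <- as.character(seqnames(sel))
        dyadBin <- ((start(sel) + end(sel)) %/% 2L - 1L) %/% bin + 1L
        rows <- lapply(seq_along(sel), function(i) {
            v <- track@values[[chr[i]]]
            idx <- dyadBin[i] + offsets
            if (is.null(v) || idx[1L] < 1L || idx[length(idx)] > length(v))
                return(NULL)
            v[idx]
        })
        rows <- rows[!vapply(rows, is.null, TRUE)]
        if (!length(rows))
            return(list(mean = rep(NA_real_, length(offsets)), n = 0L))
        list(mean = colMeans(do.call(rbind, rows)), n = length(rows))
    }
    nrm <- classMean("normal")
    lng <- classMean("long")
    list(offset = offsets * bin, normal = nrm$mean, long = lng$mean,
        nNormal = nrm$n, nLong = lng$n)
}
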