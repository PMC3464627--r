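#' Build a chromatin template
#'
#' Constructs and validates a [ChromatinTemplate-class]: a linear DNA template
#' with non-overlapping nucleosome footprints; everything between or around
#' footprints is linker/naked DNA, cut by MNase at every hit.
#'
#' @param length template length in bp.
#' @param nucleosomes an \linkS4class{IRanges} of nucleosome footprints
#'   (1-based, closed), or a numeric vector of start positions combined with
#'   \code{width}.
#' @param width footprint width in bp used when \code{nucleosomes} is a vector
#'   of starts (default 147, the canonical nucleosome core).
#' @return a validated [ChromatinTemplate-class].
#' @examples
#' tpl <- buildTemplate(600, c(101, 263))
#' linkerRanges(tpl)   # one internal 15-bp linker
#' @export
buildTemplate <- function(length, nucleosomes, width = 147L) {
    if (!is(nucleosomes, "IRanges"))
        nucleosomes <- IRanges(start = as.integer(nucleosomes),
            width = as.integer(width))
    new("ChromatinTemplate", templateLength = as.integer(length),
        nucleosomes = nucleosomes)
}

#' Template length
#' @param x a [ChromatinTemplate-class].
#' @return integer length in bp.
#' @export
templateLength <- function(x) x@templateLength

#' Nucleosome footprints of a template
#' @param x a [ChromatinTemplate-class].
#' @return an \linkS4class{IRanges}.
#' @export
nucleosomes <- function(x) x@nucleosomes

#' Linker/naked intervals of a template
#'
#' The complement of the nucleosome footprints within the template.
#'
#' @param x a [ChromatinTemplate-class].
#' @return an \linkS4class{IRanges} of linker/naked intervals.
#' @export
linkerRanges <- function(x)
    gaps(x@nucleosomes, start = 1L, end = x@templateLength)

#' Dyad positions of a template's nucleosomes
#'
#' The dyad is the maximally protected central base; for a 147-bp footprint it
#' sits 73 bp from either edge.
#'
#' @param x a [ChromatinTemplate-class].
#' @return integer vector of dyad coordinates.
#' @export
dyadPositions <- function(x)
    as.integer(start(x@nucleosomes) + (width(x@nucleosomes) - 1L) %/% 2L)

#' The six-nucleosome reference simulation template
#'
#' A 4-kb template carrying an array of six 147-bp nucleosomes at 100%
#' occupancy, modeled on the average nucleosome organization upstream of yeast
#' transcription start sites: nucleosomes spaced 15 bp apart, except a 142-bp
#' central linker between the third and fourth nucleosome, plus a 30-bp linker
#' immediately upstream of the first nucleosome. The array is placed so that
#' the midpoint of the central 142-bp linker falls at the template midpoint
#' (2 kb); template DNA outside the array is naked.
#'
#' @return a [ChromatinTemplate-class] of length 4000 with 6 nucleosomes.
#' @examples
#' tpl <- referenceTemplate()
#' width(linkerRanges(tpl))
#' @export
referenceTemplate <- function() {
    nucWidth <- 147L
    linkers <- c(15L, 15L, 142L, 15L, 15L)
    tplLength <- 4000L
    # place the central linker's midpoint at the template midpoint
    centralStart <- tplLength %/% 2L - linkers[3L] %/% 2L + 1L   # 1930
    starts3 <- centralStart - cumsum(rep(nucWidth + 15L, 3L))[3:1] + 15L
    starts6 <- centralStart + linkers[3L] +
        c(0L, cumsum(rep(nucWidth + 15L, 2L)))
    buildTemplate(tplLength, c(starts3, starts6), width = nucWidth)
}

#' Per-base MNase cut-probability profile of a template
#'
#' Linker/naked DNA is always cut when hit (probability 1). Inside a
#' nucleosome the cut probability is \code{1/protection}, where protection
#' interpolates from \code{minProtection} at the footprint edge to
#' \code{maxProtection} at the dyad, mirrored about the dyad:
#' \itemize{
#'   \item \code{shape = "linear"}: protection decreases linearly with
#'     distance from the dyad;
#'   \item \code{shape = "cosine"}: a raised-cosine ramp, flatter near the
#'     dyad and steeper mid-wrap.
#' }
#'
#' @param template a [ChromatinTemplate-class].
#' @param params a [ProtectionParams-class].
#' @return a [CutProbabilityProfile-class].
#' @examples
#' prof <- cutProbabilityProfile(referenceTemplate(), ProtectionParams())
#' range(cutProbabilities(prof))
#' @export
cutProbabilityProfile <- function(template, params = ProtectionParams()) {
    validObject(template); validObject(params)
    prob <- rep(1, template@templateLength)
    nuc <- template@nucleosomes
    dy <- dyadPositions(template)
    for (i in seq_along(nuc)) {
        pos <- start(nuc)[i]:end(nuc)[i]
        halfSpan <- max(dy[i] - start(nuc)[i], end(nuc)[i] - dy[i])
        frac <- abs(pos - dy[i]) / halfSpan          # 0 at dyad, 1 at edge
        prot <- switch(params@shape,
            linear = params@maxProtection -
                (params@maxProtection - params@minProtection) * frac,
            cosine = params@minProtection +
                (params@maxProtection - params@minProtection) *
                (1 + cos(pi * frac)) / 2)
        prob[pos] <- 1 / prot
    }
    new("CutProbabilityProfile", prob = prob, template = template,
        params = params)
}

#' Cut probabilities of a profile
#' @param x a [CutProbabilityProfile-class].
#' @return numeric vector over template bases.
#' @export
cutProbabilities <- function(x) x@prob

#' @describeIn buildTemplate show method
#' @param object a [ChromatinTemplate-class].
#' @export
setMethod("show", "ChromatinTemplate", function(object) {
    cat(sprintf("ChromatinTemplate of %d bp with %d nucleosome(s)\n",
        object@templateLength, length(object@nucleosomes)))
    if (length(object@nucleosomes)) {
        lk <- linkerRanges(object)
        cat("  nucleosome widths:",
            paste(width(object@nucleosomes), collapse = ", "), "\n")
        cat("  linker widths:    ", paste(width(lk), collapse = ", "), "\n")
    }
})

setMethod("show", "ProtectionParams", function(object) {
    cat(sprintf("ProtectionParams: %gx (edge) to %gx (dyad), %s shape\n",
        object@minProtection, object@maxProtection, object@shape))
})

setMethod("show", "CutProbabilityProfile", function(object) {
    cat(sprintf(
        "CutProbabilityProfile over %d bp (min %.3g at dyads, 1 in linkers)\n",
        length(object@prob), min(object@prob)))
})

#' Read/write template nucleosome layouts as BED
#'
#' Nucleosome footprints are stored as BED intervals (0-based half-open on
#' disk) on a pseudo-chromosome named \code{template}; the template length is
#' carried in a companion chrom.sizes record.
#'
#' @param template a [ChromatinTemplate-class].
#' @param bedPath path for the nucleosome BED file.
#' @param sizesPath path for the one-line chrom.sizes file.
#' @return \code{writeTemplateBed} returns the paths invisibly;
#'   \code{readTemplateBed} returns a [ChromatinTemplate-class].
#' @export
writeTemplateBed <- function(template, bedPath, sizesPath) {
    nuc <- template@nucleosomes
    writeLines(sprintf("template\t%d\t%d", start(nuc) - 1L, end(nuc)), bedPath)
    writeLines(sprintf("template\t%d", template@templateLength), sizesPath)
    invisible(c(bedPath, sizesPath))
}

#' @rdname writeTemplateBed
#' @export
readTemplateBed <- function(bedPath, sizesPath) {
    sizes <- readChromSizes(sizesPath)
    bed <- rtracklayer::import(bedPath, format = "bed")
    buildTemplate(sizes[[1L]], IRanges::ranges(bed))
}
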