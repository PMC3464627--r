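#' @import methods
#' @importFrom S4Vectors isSorted metadata
#' @importFrom IRanges IRanges
NULL

#' ChromatinTemplate: nucleosome/linker geometry on a linear DNA template
#'
#' A linear DNA template of fixed length carrying an ordered set of
#' non-overlapping nucleosome footprints (canonically 147 bp each, at 100%
#' occupancy). Every base not covered by a nucleosome is linker/naked DNA.
#' Coordinates are 1-based closed intervals (\linkS4class{IRanges}).
#'
#' @slot templateLength integer(1), template length in bp.
#' @slot nucleosomes an \linkS4class{IRanges} of nucleosome footprints, sorted
#'   and disjoint, all inside \code{[1, templateLength]}.
#'
#' @seealso [buildTemplate()], [referenceTemplate()], [linkerRanges()]
#' @exportClass ChromatinTemplate
setClass("ChromatinTemplate",
    representation(templateLength = "integer", nucleosomes = "IRanges"))

setValidity("ChromatinTemplate", function(object) {
    L <- object@templateLength
    nuc <- object@nucleosomes
    if (length(L) != 1L || is.na(L) || L < 1L)
        return("templateLength must be a single positive integer")
    if (length(nuc) == 0L)
        return(TRUE)
    if (any(IRanges::width(nuc) < 1L))
        return("nucleosome spans must have width >= 1")
    bad <- which(IRanges::start(nuc) < 1L | IRanges::end(nuc) > L)
    if (length(bad))
        return(sprintf("nucleosome span %d (%d-%d) lies outside [1, %d]",
            bad[1L], IRanges::start(nuc)[bad[1L]], IRanges::end(nuc)[bad[1L]], L))
    if (!S4Vectors::isSorted(IRanges::start(nuc)))
        return("nucleosome spans must be sorted by start")
    if (length(nuc) > 1L) {
        ov <- which(IRanges::start(nuc)[-1L] <= IRanges::end(nuc)[-length(nuc)])
        if (length(ov))
            return(sprintf("nucleosome spans %d and %d overlap", ov[1L], ov[1L] + 1L))
    }
    TRUE
})

#' ProtectionParams: the MNase protection model inside a nucleosome
#'
#' Linker/naked DNA is always cut when hit; nucleosomal DNA is protected by a
#' positive fold-factor that grows from \code{minProtection} at the nucleosome
#' edge to \code{maxProtection} at the dyad (in vivo estimates span roughly
#' 50x to 1000x relative to naked DNA). The per-base cut probability inside a
#' nucleosome is \code{1/protection}.
#'
#' @slot minProtection numeric(1) >= 1, protection fold at the nucleosome edge.
#' @slot maxProtection numeric(1) >= minProtection, protection fold at the dyad.
#' @slot shape character(1), \code{"linear"} or \code{"cosine"} interpolation of
#'   protection between edge and dyad.
#'
#' @exportClass ProtectionParams
setClass("ProtectionParams",
    representation(minProtection = "numeric", maxProtection = "numeric",
        shape = "character"),
    prototype(minProtection = 50, maxProtection = 1000, shape = "linear"))

setValidity("ProtectionParams", function(object) {
    if (length(object@minProtection) != 1L || length(object@maxProtection) != 1L)
        return("minProtection and maxProtection must be single numbers")
    if (!(object@minProtection >= 1))
        return("minProtection must be >= 1")
    if (object@maxProtection < object@minProtection)
        return("maxProtection must be >= minProtection")
    if (!(object@shape %in% c("linear", "cosine")))
        return("shape must be 'linear' or 'cosine'")
    TRUE
})

#' Constructor for ProtectionParams
#'
#' @param minProtection protection fold at the nucleosome edge (default 50).
#' @param maxProtection protection fold at the dyad (default 1000).
#' @param shape edge-to-dyad interpolation, \code{"linear"} (default) or
#'   \code{"cosine"}.
#' @return a [ProtectionParams-class] object.
#' @examples
#' ProtectionParams(50, 1000)
#' @export
ProtectionParams <- function(minProtection = 50, maxProtection = 1000,
        shape = c("linear", "cosine")) {
    shape <- match.arg(shape)
    new("ProtectionParams", minProtection = as.numeric(minProtection),
        maxProtection = as.numeric(maxProtection), shape = shape)
}

#' CutProbabilityProfile: per-base MNase cut probability over a template
#'
#' Probability, per potential cut site, that an MNase hit at that site is
#' realized: exactly 1 in linker/naked DNA, \code{1/protection} inside
#' nucleosomes, minimal at the dyad and symmetric within each nucleosome.
#'
#' @slot prob numeric vector of length \code{templateLength}; values in (0, 1].
#' @slot template the [ChromatinTemplate-class] the profile was built from.
#' @slot params the [ProtectionParams-class] used.
#'
#' @seealso [cutProbabilityProfile()]
#' @exportClass CutProbabilityProfile
setClass("CutProbabilityProfile",
    representation(prob = "numeric", template = "ChromatinTemplate",
        params = "ProtectionParams"))

setValidity("CutProbabilityProfile", function(object) {
    if (length(object@prob) != object@template@templateLength)
        return("prob length must equal templateLength")
    if (any(object@prob <= 0 | object@prob > 1))
        return("all cut probabilities must lie in (0, 1]")
    TRUE
})

#' FragmentSet: a multiset of digestion fragments pooled over templates
#'
#' Fragments produced by cutting one or many copies of a template. Per
#' template, fragments partition \code{[1, templateLength]}.
#'
#' @slot fragments an \linkS4class{IRanges} of fragment intervals in template
#'   coordinates, pooled over the population.
#' @slot templateId integer vector parallel to \code{fragments}: which template
#'   copy each fragment came from.
#' @slot templateLength integer(1) template length in bp.
#' @slot nCuts integer(1) cuts attempted per template (NA when unknown).
#' @slot nTemplates integer(1) number of template copies digested.
#'
#' @exportClass FragmentSet
setClass("FragmentSet",
    representation(fragments = "IRanges", templateId = "integer",
        templateLength = "integer", nCuts = "integer", nTemplates = "integer"))

setValidity("FragmentSet", function(object) {
    if (length(object@fragments) != length(object@templateId))
        return("templateId must be parallel to fragments")
    TRUE
})

#' DigestResult: one simulated MNase digestion of a template population
#'
#' @slot fragmentSet all fragments ([FragmentSet-class]).
#' @slot selected the size-selected mono-nucleosome fragments.
#' @slot percentMonos numeric(1) in [0, 1]: mono-sized fragments over all
#'   fragments at or above the mono lower bound.
#' @slot nCuts integer(1) cuts per template.
#' @slot nTemplates integer(1) population size.
#' @slot seed integer(1) RNG seed used (NA if none was set).
#'
#' @exportClass DigestResult
setClass("DigestResult",
    representation(fragmentSet = "FragmentSet", selected = "FragmentSet",
        percentMonos = "numeric", nCuts = "integer", nTemplates = "integer",
        seed = "integer"))

#' SignalTrack: per-base aligned fragment signal on one template
#'
#' @slot signal numeric vector over template bases.
#' @slot normalized logical(1): has [normalizeSignal()] been applied.
#' @slot standardTotal numeric(1): fragment-count standardization target.
#' @slot normRegionMean numeric(1): mean raw (standardized) signal over the
#'   normalization region (NA before normalization).
#'
#' @exportClass SignalTrack
setClass("SignalTrack",
    representation(signal = "numeric", normalized = "logical",
        standardTotal = "numeric", normRegionMean = "numeric"),
    prototype(normalized = FALSE, standardTotal = NA_real_,
        normRegionMean = NA_real_))

#' LaneProfile: gel densitometry trace of one lane
#'
#' Intensity against migration distance, as exported from densitometry
#' software; distances strictly increasing, intensities non-negative.
#'
#' @slot distance numeric vector, strictly increasing migration distances
#'   (arbitrary units).
#' @slot intensity numeric vector, non-negative intensities.
#'
#' @exportClass LaneProfile
setClass("LaneProfile",
    representation(distance = "numeric", intensity = "numeric"))

setValidity("LaneProfile", function(object) {
    if (length(object@distance) != length(object@intensity))
        return("distance and intensity must have equal length")
    if (length(object@distance) > 1L && any(diff(object@distance) <= 0))
        return("migration distances must be strictly increasing")
    if (any(object@intensity < 0))
        return("intensities must be >= 0")
    TRUE
})

#' LaneProfile constructor
#' @param distance strictly increasing migration distances.
#' @param intensity non-negative intensities, same length.
#' @return a [LaneProfile-class].
#' @export
LaneProfile <- function(distance, intensity)
    new("LaneProfile", distance = as.numeric(distance),
        intensity = as.numeric(intensity))

#' LadderCalibration: size ladder mapping fragment size to migration distance
#'
#' Fitted from a band table of a standard ladder run on the same gel; the
#' mapping is strictly monotone decreasing in size (larger fragments migrate
#' less) and interpolates linearly in log-size.
#'
#' @slot bands data.frame with columns \code{size} (bp) and \code{distance}.
#' @slot sizeRange numeric(2): calibrated size span (smallest, largest band).
#'
#' @seealso [calibrateLadder()], [sizeToDistance()], [distanceToSize()]
#' @exportClass LadderCalibration
setClass("LadderCalibration",
    representation(bands = "data.frame", sizeRange = "numeric"))

#' SizeProfile: lane intensity on a calibrated fragment-size grid
#'
#' @slot size integer-valued grid of fragment sizes (bp), 1-bp spacing.
#' @slot intensity numeric intensities (density per bp), non-negative.
#'
#' @exportClass SizeProfile
setClass("SizeProfile",
    representation(size = "numeric", intensity = "numeric"))

#' MatchReport: pairwise lane matching outcome
#'
#' @slot r numeric matrix of pairwise Pearson correlations (unit diagonal,
#'   symmetric; NA where undefined).
#' @slot complete logical vector: completeness flag per lane.
#' @slot matched logical matrix: both lanes complete and r strictly above the
#'   threshold.
#' @slot rThreshold numeric(1).
#'
#' @exportClass MatchReport
setClass("MatchReport",
    representation(r = "matrix", complete = "logical", matched = "matrix",
        rThreshold = "numeric"))

#' CoverageTrack: binned coverage signal over a genome
#'
#' Per named sequence, a numeric signal at a fixed bin width, bins tiling each
#' sequence from its first base (the last bin may be partial).
#'
#' @slot values named list of numeric vectors, one per sequence.
#' @slot binWidth integer(1) bin width in bp.
#' @slot seqlengths named integer vector of sequence lengths.
#' @slot metadata list of normalization/provenance metadata.
#'
#' @seealso [coverageFromFragments()], [readBedGraphTrack()],
#'   [standardizeTrack()]
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    representation(values = "list", binWidth = "integer",
        seqlengths = "integer", metadata = "list"),
    prototype(metadata = list()))

setValidity("CoverageTrack", function(object) {
    if (is.null(names(object@seqlengths)) || anyDuplicated(names(object@seqlengths)))
        return("seqlengths must have unique names")
    if (!identical(names(object@values), names(object@seqlengths)))
        return("values must be named like seqlengths, in order")
    nbin <- ceiling(object@seqlengths / object@binWidth)
    ok <- vapply(object@values, length, 1L) == nbin
    if (!all(ok))
        return(sprintf("sequence '%s' has wrong number of bins",
            names(object@values)[!ok][1L]))
    TRUE
})

#' WindowCorrelationSet: windowed Pearson correlations between two tracks
#'
#' @slot windows a \linkS4class{GRanges} of windows with metadata column
#'   \code{r} (NA for zero-variance windows).
#' @slot windowBp integer(1) window size.
#' @slot stepBp integer(1) step between window starts.
#'
#' @exportClass WindowCorrelationSet
setClass("WindowCorrelationSet",
    representation(windows = "GRanges", windowBp = "integer",
        stepBp = "integer"))

#' DissimilarRegionSet: merged regions where two tracks decorrelate
#'
#' @slot regions a \linkS4class{GRanges} of merged regions with metadata
#'   column \code{minR} (minimum window r inside the region).
#' @slot rCutoff numeric(1) correlation cutoff used.
#' @slot minSpanBp integer(1) minimum merged span retained.
#' @slot windowBp integer(1) sliding window size.
#' @slot stepBp integer(1) sliding step.
#'
#' @exportClass DissimilarRegionSet
setClass("DissimilarRegionSet",
    representation(regions = "GRanges", rCutoff = "numeric",
        minSpanBp = "integer", windowBp = "integer", stepBp = "integer"))

#' BindingProfile: continuous binding signal from probe-level data
#'
#' Sliding-window mean of probe log2 ratios, assigned to step-resolution bins;
#' bins without probe support are NA (missing).
#'
#' @slot values named list of numeric vectors (NA = no probe support).
#' @slot binWidth integer(1), equal to the sliding step.
#' @slot seqlengths named integer vector.
#' @slot windowBp integer(1) sliding window size.
#'
#' @exportClass BindingProfile
setClass("BindingProfile",
    representation(values = "list", binWidth = "integer",
        seqlengths = "integer", windowBp = "integer"))

#' EnrichmentResult: binding enrichment at regions vs a random-region null
#'
#' @slot observedMeans per-region mean binding at the test regions.
#' @slot nullMeans per-region mean binding at the random regions.
#' @slot t numeric(1) Welch t statistic (unequal variances).
#' @slot p numeric(1) one-tailed p (observed > null).
#' @slot nObserved,nNull integer(1) group sizes entering the test.
#'
#' @exportClass EnrichmentResult
setClass("EnrichmentResult",
    representation(observedMeans = "numeric", nullMeans = "numeric",
        t = "numeric", p = "numeric", nObserved = "integer",
        nNull = "integer"))
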