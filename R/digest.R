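#' Simulate MNase cuts on one template
#'
#' Cut sites are the \code{L - 1} inter-base positions of the template; site
#' \code{k} separates base \code{k} from base \code{k + 1}. In the default
#' \code{"attempted"} mode, \code{nCuts} candidate sites are drawn uniformly
#' and each candidate is realized with the profile probability at its base
#' (rejection model); in \code{"realized"} mode candidates are drawn until
#' \code{nCuts} of them are realized. Duplicate realized sites collapse to a
#' single cut.
#'
#' @param profile a [CutProbabilityProfile-class].
#' @param nCuts number of cuts (candidates attempted, or realizations
#'   required, depending on \code{cutMode}).
#' @param cutMode \code{"attempted"} (default) or \code{"realized"}.
#' @param seed optional integer seed; when given, the caller's RNG state is
#'   left untouched.
#' @return sorted unique integer vector of realized cut sites.
#' @examples
#' prof <- cutProbabilityProfile(referenceTemplate())
#' simulateCuts(prof, 10, seed = 1)
#' @export
simulateCuts <- function(profile, nCuts, cutMode = c("attempted", "realized"),
        seed = NULL) {
    cutMode <- match.arg(cutMode)
    stopifnot(nCuts >= 0)
    withSeed(seed, {
        hits <- drawCutHits(profile@prob, as.integer(nCuts), 1L, cutMode)
        sort(unique(hits$site))
    })
}

# Draw accepted cut sites for nTemplates independent templates.
# Returns list(id, site) of accepted (not yet deduplicated) hits.
drawCutHits <- function(prob, nCuts, nTemplates, cutMode) {
    L <- length(prob)
    nSites <- L - 1L
    if (nCuts == 0L || nSites < 1L)
        return(list(id = integer(0), site = integer(0)))
    if (cutMode == "attempted") {
        total <- nCuts * nTemplates
        cand <- sample.int(nSites, total, replace = TRUE)
        acc <- runif(total) < prob[cand]
        list(id = rep(seq_len(nTemplates), each = nCuts)[acc],
            site = cand[acc])
    } else {
        deficit <- rep(nCuts, nTemplates)
        id <- integer(0); site <- integer(0)
        while (any(deficit > 0L)) {
            need <- which(deficit > 0L)
            reps <- rep(need, deficit[need])
            cand <- sample.int(nSites, length(reps), replace = TRUE)
            acc <- runif(length(reps)) < prob[cand]
            id <- c(id, reps[acc]); site <- c(site, cand[acc])
            got <- tabulate(reps[acc], nTemplates)
            deficit <- deficit - got
        }
        list(id = id, site = site)
    }
}

#' Fragments from a set of cuts on one template
#'
#' Fragments are the intervals between consecutive cuts, with the template
#' ends closing the first and last fragment; fragment lengths always sum to
#' the template length.
#'
#' @param template a [ChromatinTemplate-class].
#' @param cuts sorted integer cut sites in \code{[1, length - 1]} (site k cuts
#'   between bases k and k + 1).
#' @return a [FragmentSet-class] for a single template.
#' @examples
#' fs <- fragmentsFromCuts(buildTemplate(4000, integer(0)), c(1000, 2000))
#' width(fragmentRanges(fs))
#' @export
fragmentsFromCuts <- function(template, cuts) {
    L <- template@templateLength
    cuts <- as.integer(cuts)
    if (length(cuts)) {
        if (is.unsorted(cuts, strictly = TRUE))
            cuts <- sort(unique(cuts))
        stopifnot(all(cuts >= 1L), all(cuts <= L - 1L))
    }
    bounds <- c(0L, cuts, L)
    frag <- IRanges(start = head(bounds, -1L) + 1L, end = bounds[-1L])
    new("FragmentSet", fragments = frag,
        templateId = rep(1L, length(frag)), templateLength = L,
        nCuts = length(cuts), nTemplates = 1L)
}

# Pool fragments over a population given accepted cut hits (id, site).
poolFragments <- function(L, hits, nCuts, nTemplates) {
    ord <- order(hits$id, hits$site)
    id <- hits$id[ord]; site <- hits$site[ord]
    if (length(id)) {
        dup <- c(FALSE, id[-1L] == id[-length(id)] &
            site[-1L] == site[-length(site)])
        id <- id[!dup]; site <- site[!dup]
    }
    m <- tabulate(id, nTemplates)          # realized cuts per template
    nFrag <- m + 1L
    total <- sum(nFrag)
    lastIdx <- cumsum(nFrag)
    firstIdx <- lastIdx - m
    isFirst <- logical(total); isFirst[firstIdx] <- TRUE
    isLast <- logical(total); isLast[lastIdx] <- TRUE
    starts <- integer(total); ends <- integer(total)
    starts[isFirst] <- 1L
    starts[!isFirst] <- site + 1L
    ends[isLast] <- L
    ends[!isLast] <- site
    new("FragmentSet", fragments = IRanges(start = starts, end = ends),
        templateId = rep(seq_len(nTemplates), nFrag),
        templateLength = as.integer(L), nCuts = as.integer(nCuts),
        nTemplates = as.integer(nTemplates))
}

#' Fragment intervals of a FragmentSet
#' @param x a [FragmentSet-class].
#' @return an \linkS4class{IRanges}.
#' @export
fragmentRanges <- function(x) x@fragments

#' Fragment lengths of a FragmentSet
#' @param x a [FragmentSet-class].
#' @return integer vector of fragment lengths (bp).
#' @export
fragmentLengths <- function(x) width(x@fragments)

#' Simulate MNase digestion of a chromatin template population
#'
#' Digests \code{nTemplates} independent copies of the template with
#' \code{nCuts} cuts each (see [simulateCuts()] for the cut model), pools the
#' resulting fragments, size-selects mono-nucleosome fragments and computes
#' the extent of digestion (\% Monos).
#'
#' @param template a [ChromatinTemplate-class].
#' @param params a [ProtectionParams-class].
#' @param nCuts cuts per template.
#' @param nTemplates population size (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param cutMode cut-count interpretation, see [simulateCuts()].
#' @param monoRange inclusive mono-nucleosome size-selection window in bp
#'   (default \code{c(115, 195)}).
#' @param denomMin lower size bound for the \% Monos denominator (default 115).
#' @param denomInclusive whether the denominator bound is inclusive (default
#'   TRUE).
#' @return a [DigestResult-class].
#' @examples
#' res <- simulatePopulation(referenceTemplate(), nCuts = 20,
#'     nTemplates = 500, seed = 1)
#' percentMonosValue(res)
#' @export
simulatePopulation <- function(template, params = ProtectionParams(), nCuts,
        nTemplates = 10000L, seed = NULL,
        cutMode = c("attempted", "realized"), monoRange = c(115L, 195L),
        denomMin = 115L, denomInclusive = TRUE) {
    cutMode <- match.arg(cutMode)
    stopifnot(nTemplates >= 1L)
    profile <- cutProbabilityProfile(template, params)
    fs <- withSeed(seed, {
        hits <- drawCutHits(profile@prob, as.integer(nCuts),
            as.integer(nTemplates), cutMode)
        poolFragments(template@templateLength, hits, nCuts, nTemplates)
    })
    sel <- sizeSelect(fs, monoRange[1L], monoRange[2L])
    pm <- percentMonos(fs, monoRange = monoRange, denomMin = denomMin,
        denomInclusive = denomInclusive)
    new("DigestResult", fragmentSet = fs, selected = sel,
        percentMonos = pm, nCuts = as.integer(nCuts),
        nTemplates = as.integer(nTemplates),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Size-select mono-nucleosome fragments
#'
#' Retains fragments whose length lies in the inclusive window
#' \code{[minBp, maxBp]}, emulating gel excision of mono-nucleosomal DNA.
#' Idempotent.
#'
#' @param fragments a [FragmentSet-class].
#' @param minBp,maxBp inclusive size bounds in bp (defaults 115 and 195).
#' @return a [FragmentSet-class] containing the retained fragments.
#' @export
sizeSelect <- function(fragments, minBp = 115L, maxBp = 195L) {
    if (minBp > maxBp)
        stop("minBp must be <= maxBp")
    keep <- width(fragments@fragments) >= minBp &
        width(fragments@fragments) <= maxBp
    new("FragmentSet", fragments = fragments@fragments[keep],
        templateId = fragments@templateId[keep],
        templateLength = fragments@templateLength,
        nCuts = fragments@nCuts, nTemplates = fragments@nTemplates)
}

#' Extent of digestion (\% Monos)
#'
#' The number of mono-nucleosome-sized fragments divided by the number of all
#' remaining fragments at or above the mono lower bound. Returns 0 (with a
#' warning) when the denominator is empty.
#'
#' @param fragments a [FragmentSet-class].
#' @param monoRange inclusive mono size window (default \code{c(115, 195)}).
#' @param denomMin denominator size bound in bp (default 115).
#' @param denomInclusive if TRUE (default) the denominator counts lengths
#'   \code{>= denomMin}, else strictly \code{> denomMin}; the numerator is
#'   always restricted to the denominator so the result stays in [0, 1].
#' @return fraction in [0, 1].
#' @examples
#' fs <- fragmentsFromCuts(buildTemplate(4300, integer(0)), c(150, 300))
#' percentMonos(fs)   # lengths 150, 150, 4000 -> 2/3
#' @export
percentMonos <- function(fragments, monoRange = c(115L, 195L),
        denomMin = 115L, denomInclusive = TRUE) {
    w <- width(fragments@fragments)
    inDen <- if (denomInclusive) w >= denomMin else w > denomMin
    num <- sum(w >= monoRange[1L] & w <= monoRange[2L] & inDen)
    den <- sum(inDen)
    if (den == 0L) {
        warning("no fragments at or above the denominator bound; ",
            "returning 0")
        return(0)
    }
    num / den
}

#' \% Monos of a DigestResult
#' @param x a [DigestResult-class].
#' @return fraction in [0, 1].
#' @export
percentMonosValue <- function(x) x@percentMonos

#' Size-selected fragments of a DigestResult
#' @param x a [DigestResult-class].
#' @return a [FragmentSet-class].
#' @export
selectedFragments <- function(x) x@selected

#' All fragments of a DigestResult (before size selection)
#' @param x a [DigestResult-class].
#' @return a [FragmentSet-class].
#' @export
allFragments <- function(x) x@fragmentSet

#' Tabulate aligned fragment signal on the template
#'
#' Adds +1 coverage on every base spanned by each retained fragment — the
#' equivalent of aligning fully sequenced (paired-end) fragments back to the
#' template, with no tag extension.
#'
#' @param selected a (typically size-selected) [FragmentSet-class].
#' @param template the [ChromatinTemplate-class] digested.
#' @return a raw (un-normalized) [SignalTrack-class].
#' @export
tabulateSignal <- function(selected, template) {
    cov <- coverage(selected@fragments, width = template@templateLength)
    new("SignalTrack", signal = as.numeric(cov), normalized = FALSE)
}

#' Normalize an aligned signal track
#'
#' Two-step normalization used to compare simulations run at different
#' digestion extents: counts are first standardized to a fixed total number
#' of selected fragments (\code{standardTotal}), then divided by the mean
#' standardized signal over a normalization region so that region's mean is
#' exactly 1 in every simulation.
#'
#' @param track a raw [SignalTrack-class].
#' @param totalSelected the number of selected fragments that produced the
#'   track.
#' @param normRegion an \linkS4class{IRanges} (or \code{c(start, end)})
#'   normalization region in template coordinates; default 2501-3500.
#' @param standardTotal fragment-count standardization target (default 1e6;
#'   only ratios matter).
#' @return a normalized [SignalTrack-class] (norm-region mean = 1).
#' @export
normalizeSignal <- function(track, totalSelected,
        normRegion = IRanges(2501L, 3500L), standardTotal = 1e6) {
    if (!is(normRegion, "IRanges"))
        normRegion <- IRanges(normRegion[1L], normRegion[2L])
    L <- length(track@signal)
    if (start(normRegion) < 1L || end(normRegion) > L)
        stop("normRegion must lie inside the template")
    if (totalSelected <= 0)
        stop("totalSelected must be positive")
    scaled <- track@signal * (standardTotal / totalSelected)
    m <- mean(scaled[start(normRegion):end(normRegion)])
    if (m == 0)
        stop("zero signal in the normalization region; cannot normalize")
    new("SignalTrack", signal = scaled / m, normalized = TRUE,
        standardTotal = standardTotal, normRegionMean = m)
}

#' Signal values of a SignalTrack
#' @param x a [SignalTrack-class].
#' @return numeric vector over template bases.
#' @export
signalValues <- function(x) x@signal

#' Run a digestion titration
#'
#' Simulates a range of cut numbers to mimic different extents of digestion,
#' reporting \% Monos and the normalized aligned signal restricted to a
#' central window of the template (which removes the edge effect of the
#' template ends).
#'
#' @param template a [ChromatinTemplate-class].
#' @param params a [ProtectionParams-class].
#' @param nCutsValues integer vector of cut numbers (default \code{2:50}).
#' @param nTemplates templates per cut number (default 10000).
#' @param seed optional integer seed covering the whole titration.
#' @param window central reporting window (\linkS4class{IRanges}; default
#'   1501-2500, the central 1000 bp of the 4-kb reference template).
#' @param normRegion normalization region passed to [normalizeSignal()].
#' @param ... further arguments to [simulatePopulation()].
#' @return a list with \code{summary} (data.frame: nCuts, percentMonos,
#'   nSelected), \code{signal} (matrix, window positions x cut numbers, of
#'   normalized signal) and \code{window}.
#' @examples
#' tt <- runTitration(referenceTemplate(), nCutsValues = c(5, 30),
#'     nTemplates = 300, seed = 1)
#' tt$summary
#' @export
runTitration <- function(template, params = ProtectionParams(),
        nCutsValues = 2:50, nTemplates = 10000L, seed = NULL,
        window = IRanges(1501L, 2500L), normRegion = IRanges(2501L, 3500L),
        ...) {
    if (!is(window, "IRanges"))
        window <- IRanges(window[1L], window[2L])
    idx <- start(window):end(window)
    withSeed(seed, {
        sig <- matrix(NA_real_, nrow = length(idx),
            ncol = length(nCutsValues),
            dimnames = list(NULL, paste0("n", nCutsValues)))
        pm <- numeric(length(nCutsValues))
        nSel <- integer(length(nCutsValues))
        for (i in seq_along(nCutsValues)) {
            res <- simulatePopulation(template, params,
                nCuts = nCutsValues[i], nTemplates = nTemplates, ...)
            pm[i] <- res@percentMonos
            nSel[i] <- length(res@selected@fragments)
            if (nSel[i] > 0L) {
                tr <- tabulateSignal(res@selected, template)
                tr <- normalizeSignal(tr, nSel[i], normRegion = normRegion)
                sig[, i] <- tr@signal[idx]
            }
        }
        list(summary = data.frame(nCuts = nCutsValues, percentMonos = pm,
                nSelected = nSel),
            signal = sig, window = window)
    })
}

#' Quantify the neighborhood effect across a titration
#'
#' Compares mean normalized signal over the nucleosomes flanking the
#' template's longest internal linker ("long-flanked") against nucleosomes
#' whose two internal linkers both equal the modal (short) linker width
#' ("normal-flanked"). At partial digestion, long-flanked nucleosomes are
#' over-sampled because the two cuts needed to release them are easier to
#' achieve in long linker DNA; the ratio decays toward 1 as digestion
#' approaches completion.
#'
#' @param titration result of [runTitration()].
#' @param template the template that was digested.
#' @return the titration summary data.frame with an added \code{ratio} column
#'   (long-flanked / normal-flanked mean normalized signal; NA when the
#'   normal-flanked class received no signal).
#' @export
neighborhoodEffect <- function(titration, template) {
    cls <- flankClasses(template)
    idx <- start(titration$window):end(titration$window)
    inWin <- function(ranges) {
        pos <- unlist(lapply(seq_along(ranges), function(i)
            start(ranges)[i]:end(ranges)[i]))
        match(intersect(pos, idx), idx)
    }
    longIdx <- inWin(cls$longFlanked)
    normIdx <- inWin(cls$normalFlanked)
    ratio <- apply(titration$signal, 2L, function(s) {
        denom <- mean(s[normIdx])
        if (!is.finite(denom) || denom == 0) NA_real_
        else mean(s[longIdx]) / denom
    })
    out <- titration$summary
    out$ratio <- unname(ratio)
    out
}

# Classify a template's nucleosomes by their flanking internal linkers:
# long-flanked = adjacent to the widest internal linker; normal-flanked =
# both internal linkers equal the modal internal linker width.
flankClasses <- function(template) {
    nuc <- template@nucleosomes
    if (length(nuc) < 3L)
        stop("template needs at least 3 nucleosomes to classify flanks")
    gapW <- start(nuc)[-1L] - end(nuc)[-length(nuc)] - 1L  # internal linkers
    modal <- as.integer(names(which.max(table(gapW))))
    iMax <- which.max(gapW)
    longFlanked <- nuc[c(iMax, iMax + 1L)]
    leftW <- c(NA, gapW); rightW <- c(gapW, NA)
    normal <- which(!is.na(leftW) & !is.na(rightW) &
        leftW == modal & rightW == modal)
    list(longFlanked = longFlanked, normalFlanked = nuc[normal],
        modalLinker = modal, maxLinker = gapW[iMax])
}

#' Closed-form expected fragment-length distribution
#'
#' Analytic expectation of the per-template fragment-length histogram under
#' the rejection cut model: each of \code{nCuts} candidates falls uniformly on
#' the \code{L - 1} cut sites and is realized with the local profile
#' probability (\code{"attempted"} mode), or exactly \code{nCuts} realized
#' sites are drawn i.i.d. from the acceptance-weighted site distribution
#' (\code{"realized"} mode). The probability that a given interval
#' \code{(a, b]} survives as a fragment follows by inclusion-exclusion over
#' cuts at its two boundaries and the absence of interior cuts.
#'
#' Exact (no simulation); used as an independent oracle for the Monte-Carlo
#' digestion engine.
#'
#' @param profile a [CutProbabilityProfile-class].
#' @param nCuts cuts per template.
#' @param cutMode \code{"attempted"} or \code{"realized"}.
#' @return numeric vector \code{e} with \code{e[l]} = expected number of
#'   fragments of length \code{l} per template, \code{l = 1..L}.
#' @export
expectedFragmentLengthDist <- function(profile, nCuts,
        cutMode = c("attempted", "realized")) {
    cutMode <- match.arg(cutMode)
    L <- length(profile@prob)
    n <- as.integer(nCuts)
    q <- profile@prob[seq_len(L - 1L)] / (L - 1L)  # site = base index
    if (cutMode == "realized") {
        if (n == 0L) { e <- numeric(L); e[L] <- 1; return(e) }
        q <- q / sum(q)   # accepted sites i.i.d. from normalized weights
    }
    S <- c(0, cumsum(q))  # S[i + 1] = sum over sites 1..i
    qa <- c(0, q)         # boundary weight at a (a = 0 -> template start)
    e <- numeric(L)
    pw <- function(x) pmax(x, 0)^n
    for (len in seq_len(L)) {
        a <- 0:(L - len)              # fragment covers bases a+1 .. a+len
        b <- a + len
        Qin <- S[b] - S[a + 1L]       # interior sites a+1 .. b-1
        wa <- qa[a + 1L]              # 0 when a = 0
        wb <- ifelse(b == L, 0, q[pmin(b, L - 1L)])
        p <- pw(1 - Qin)
        p <- p - ifelse(wa > 0, pw(1 - Qin - wa), 0)
        p <- p - ifelse(wb > 0, pw(1 - Qin - wb), 0)
        p <- p + ifelse(wa > 0 & wb > 0, pw(1 - Qin - wa - wb), 0)
        # boundary-only cases: subtract nothing twice
        p[wa == 0 & wb == 0] <- pw(1 - Qin[wa == 0 & wb == 0])
        e[len] <- sum(p)
    }
    e
}

#' Empirical fragment-length distribution with standard errors
#'
#' Mean per-template count of each fragment length across the population, with
#' the across-template standard error of that mean.
#'
#' @param fragments a [FragmentSet-class] pooled over templates.
#' @return data.frame with columns \code{length}, \code{mean} (per template)
#'   and \code{se}.
#' @export
fragmentLengthDist <- function(fragments) {
    L <- fragments@templateLength
    Tn <- fragments@nTemplates
    w <- width(fragments@fragments)
    id <- fragments@templateId
    ord <- order(id, w)
    key <- rle(paste0(id[ord], "_", w[ord]))
    # counts per (template, length) pair, then moments per length
    cnt <- key$lengths
    wlen <- as.integer(sub(".*_", "", key$values))
    sums <- rowsum(cbind(cnt, cnt^2), wlen)
    lens <- as.integer(rownames(sums))
    meanL <- numeric(L); sqL <- numeric(L)
    meanL[lens] <- sums[, 1L] / Tn
    sqL[lens] <- sums[, 2L] / Tn
    varL <- pmax(sqL - meanL^2, 0)
    data.frame(length = seq_len(L), mean = meanL,
        se = sqrt(varL / Tn))
}

setMethod("show", "FragmentSet", function(object) {
    cat(sprintf(
        "FragmentSet: %d fragments from %d template(s) of %d bp (nCuts = %s)\n",
        length(object@fragments), object@nTemplates, object@templateLength,
        ifelse(is.na(object@nCuts), "?", object@nCuts)))
})

setMethod("show", "DigestResult", function(object) {
    cat(sprintf(
        "DigestResult: n = %d cuts x %d templates; %d fragments, %d selected; %.1f%% Monos\n",
        object@nCuts, object@nTemplates,
        length(object@fragmentSet@fragments), length(object@selected@fragments),
        100 * object@percentMonos))
})
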