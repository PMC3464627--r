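#' Calibrate a size ladder
#'
#' Fits the monotone size-to-migration mapping from a standard ladder run on
#' the same gel, interpolating linearly in log-size (standard agarose
#' behavior: migration distance is close to linear in log fragment size).
#' Queries outside the band span are linearly extrapolated from the terminal
#' segments and flagged with a warning.
#'
#' @param bands data.frame with columns \code{size} (bp) and \code{distance}
#'   (migration, arbitrary units), at least 3 bands, distance strictly
#'   decreasing in size.
#' @return a [LadderCalibration-class].
#' @examples
#' cal <- calibrateLadder(data.frame(size = c(100, 200, 300, 400),
#'     distance = c(90, 70, 58, 50)))
#' sizeToDistance(cal, 150)
#' @export
calibrateLadder <- function(bands) {
    stopifnot(is.data.frame(bands), all(c("size", "distance") %in% names(bands)))
    bands <- bands[order(bands$size), , drop = FALSE]
    if (nrow(bands) < 3L)
        stop("ladder calibration needs at least 3 bands")
    if (any(bands$size <= 0))
        stop("band sizes must be positive")
    if (any(diff(bands$distance) >= 0))
        stop("band table is not monotone: distance must strictly decrease ",
            "with size")
    new("LadderCalibration",
        bands = data.frame(size = bands$size, distance = bands$distance),
        sizeRange = range(bands$size))
}

# piecewise-linear interpolation in (log size, distance) with linear
# extrapolation from the terminal segments
.ladderInterp <- function(xs, ys, x) {
    n <- length(xs)
    y <- approx(xs, ys, xout = x, rule = 2)$y
    lo <- x < xs[1L]
    hi <- x > xs[n]
    if (any(lo))
        y[lo] <- ys[1L] + (x[lo] - xs[1L]) * (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
    if (any(hi))
        y[hi] <- ys[n] + (x[hi] - xs[n]) * (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L])
    y
}

#' Map fragment size to migration distance
#' @param cal a [LadderCalibration-class].
#' @param size fragment sizes in bp.
#' @param warnExtrapolation warn when queries fall outside the calibrated
#'   band span (default TRUE).
#' @return migration distances.
#' @export
sizeToDistance <- function(cal, size, warnExtrapolation = TRUE) {
    if (warnExtrapolation && any(size < cal@sizeRange[1L] | size > cal@sizeRange[2L]))
        warning("extrapolating outside the calibrated size span")
    .ladderInterp(log(cal@bands$size), cal@bands$distance, log(size))
}

#' Map migration distance to fragment size
#' @param cal a [LadderCalibration-class].
#' @param distance migration distances.
#' @param warnExtrapolation warn outside the calibrated span (default TRUE).
#' @return fragment sizes in bp.
#' @export
distanceToSize <- function(cal, distance, warnExtrapolation = TRUE) {
    d <- cal@bands$distance
    if (warnExtrapolation && any(distance < min(d) | distance > max(d)))
        warning("extrapolating outside the calibrated distance span")
    exp(.ladderInterp(rev(d), rev(log(cal@bands$size)), distance))
}

#' Resample a lane profile onto a calibrated fragment-size grid
#'
#' Converts a densitometry trace (intensity vs. migration distance) into
#' intensity per bp on a fixed 1-bp size grid — the "relative front"
#' representation that makes lanes from different gels comparable. The
#' intensity is treated as a density over distance and multiplied by the local
#' |d distance / d size| Jacobian so that band areas are preserved under the
#' change of variable.
#'
#' @param lane a [LaneProfile-class].
#' @param cal a [LadderCalibration-class].
#' @param sizeRange analysis size range in bp (default \code{c(0, 400)});
#'   clipped to the calibrated band span.
#' @return a [SizeProfile-class] on a 1-bp grid.
#' @export
laneToSizeProfile <- function(lane, cal, sizeRange = c(0, 400)) {
    lo <- max(sizeRange[1L], cal@sizeRange[1L])
    hi <- min(sizeRange[2L], cal@sizeRange[2L])
    if (lo >= hi)
        stop("size range does not overlap the calibrated span")
    grid <- seq(ceiling(lo), floor(hi), by = 1)
    d <- sizeToDistance(cal, grid, warnExtrapolation = FALSE)
    if (max(d) < min(lane@distance) || min(d) > max(lane@distance))
        stop("lane does not overlap the calibrated migration region")
    intensity <- approx(lane@distance, lane@intensity, xout = d,
        rule = 2)$y
    # Jacobian |dd/ds| by central finite difference on the calibration
    eps <- 0.5
    jac <- abs(sizeToDistance(cal, grid + eps, warnExtrapolation = FALSE) -
        sizeToDistance(cal, grid - eps, warnExtrapolation = FALSE)) / (2 * eps)
    new("SizeProfile", size = grid, intensity = pmax(intensity * jac, 0))
}

#' Check a lane for complete digestion
#'
#' A digest is complete when it no longer shows a visible di-nucleosome band:
#' operationally, when the peak intensity in the di-nucleosome size window is
#' below \code{maxDiFraction} of the peak intensity in the mono-nucleosome
#' window.
#'
#' @param profile a [SizeProfile-class] covering the di-nucleosome range.
#' @param diRange di-nucleosome size window in bp (default \code{c(250, 350)}).
#' @param monoRange mono-nucleosome window (default \code{c(115, 195)}).
#' @param maxDiFraction visibility threshold (default 0.05).
#' @return list with \code{complete} (logical), \code{diPeak} and
#'   \code{monoPeak} intensities.
#' @export
completenessCheck <- function(profile, diRange = c(250, 350),
        monoRange = c(115, 195), maxDiFraction = 0.05) {
    if (min(profile@size) > diRange[1L] || max(profile@size) < diRange[2L])
        stop("profile does not cover the di-nucleosome size range")
    inDi <- profile@size >= diRange[1L] & profile@size <= diRange[2L]
    inMono <- profile@size >= monoRange[1L] & profile@size <= monoRange[2L]
    diPeak <- max(profile@intensity[inDi])
    monoPeak <- max(profile@intensity[inMono])
    list(complete = diPeak < maxDiFraction * monoPeak,
        diPeak = diPeak, monoPeak = monoPeak)
}

#' Pearson correlation between two size profiles
#'
#' Standard Pearson correlation of intensities over the common size grid.
#' Zero-variance profiles give an undefined correlation, returned as NA.
#'
#' @param a,b [SizeProfile-class] objects on identical grids.
#' @return Pearson r in [-1, 1], or NA if either profile has zero variance.
#' @export
matchScore <- function(a, b) {
    if (!identical(a@size, b@size))
        stop("size profiles must share an identical grid")
    if (stats::sd(a@intensity) == 0 || stats::sd(b@intensity) == 0)
        return(NA_real_)
    cor(a@intensity, b@intensity)
}

#' Select matched digests among candidate lanes
#'
#' Matched digests are pairs of lanes that are both completely digested (no
#' visible di-nucleosome band) and whose size profiles correlate with
#' Pearson r strictly greater than the threshold (default 0.9).
#'
#' @param profiles named list of [SizeProfile-class] objects (>= 2) on a
#'   common grid.
#' @param rThreshold correlation threshold; matching requires \code{r >
#'   rThreshold} strictly (default 0.9).
#' @param ... further arguments to [completenessCheck()].
#' @return a [MatchReport-class].
#' @export
selectMatched <- function(profiles, rThreshold = 0.9, ...) {
    n <- length(profiles)
    if (n < 2L)
        stop("need at least 2 profiles")
    nm <- names(profiles)
    if (is.null(nm))
        nm <- paste0("lane", seq_len(n))
    r <- diag(1, n)
    dimnames(r) <- list(nm, nm)
    for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
            r[i, j] <- r[j, i] <- matchScore(profiles[[i]], profiles[[j]])
    complete <- vapply(profiles,
        function(p) completenessCheck(p, ...)$complete, logical(1L))
    names(complete) <- nm
    matched <- outer(complete, complete, `&`) & !is.na(r) & r > rThreshold
    diag(matched) <- FALSE
    new("MatchReport", r = r, complete = complete, matched = matched,
        rThreshold = rThreshold)
}

#' Matched lane pairs of a MatchReport
#' @param x a [MatchReport-class].
#' @return data.frame with columns \code{laneA}, \code{laneB}, \code{r}.
#' @export
matchedPairs <- function(x) {
    idx <- which(x@matched & upper.tri(x@matched), arr.ind = TRUE)
    data.frame(laneA = rownames(x@r)[idx[, 1L]],
        laneB = colnames(x@r)[idx[, 2L]],
        r = x@r[idx])
}

#' Simulate a gel lane from a fragment-length multiset
#'
#' Fixture generator bridging the digestion simulator to lane matching: each
#' fragment length contributes a Gaussian band centered at its log-linear
#' migration position, with intensity proportional to molecule count times
#' length under the intercalating-dye (mass-weighted) model.
#'
#' @param fragmentLengths integer vector of fragment lengths (the multiset;
#'   repeats allowed) or a named table of counts.
#' @param bandSigma Gaussian band spread in distance units (default 1.5).
#' @param massWeighted intensity proportional to count x length (default
#'   TRUE); otherwise count only.
#' @param migrationA,migrationB log-linear mobility constants: distance =
#'   A - B log10(size).
#' @param noiseSd optional additive intensity noise (default 0).
#' @param distanceGrid sampling grid of migration distances; default spans
#'   the 30-700 bp migration span at 0.25-unit spacing.
#' @param seed optional seed for the intensity noise.
#' @return a [LaneProfile-class].
#' @export
simulateGelLane <- function(fragmentLengths, bandSigma = 1.5,
        massWeighted = TRUE, migrationA = 220, migrationB = 65,
        noiseSd = 0, distanceGrid = NULL, seed = NULL) {
    if (!is.null(names(fragmentLengths))) {
        sizes <- as.numeric(names(fragmentLengths))
        counts <- as.numeric(fragmentLengths)
    } else {
        tab <- table(fragmentLengths)
        sizes <- as.numeric(names(tab))
        counts <- as.numeric(tab)
    }
    if (length(sizes) == 0L)
        stop("fragment multiset is empty")
    mig <- function(s) migrationA - migrationB * log10(s)
    if (is.null(distanceGrid))
        distanceGrid <- seq(mig(700), mig(30), by = 0.25)
    weight <- if (massWeighted) counts * sizes else counts
    pos <- mig(sizes)
    intensity <- rowSums(vapply(seq_along(sizes), function(i)
        weight[i] * dnorm(distanceGrid, mean = pos[i], sd = bandSigma),
        numeric(length(distanceGrid))))
    if (noiseSd > 0)
        intensity <- withSeed(seed,
            pmax(intensity + rnorm(length(intensity), sd = noiseSd), 0))
    LaneProfile(distanceGrid, intensity)
}

setMethod("show", "LadderCalibration", function(object) {
    cat(sprintf("LadderCalibration: %d bands spanning %g-%g bp\n",
        nrow(object@bands), object@sizeRange[1L], object@sizeRange[2L]))
})

setMethod("show", "SizeProfile", function(object) {
    cat(sprintf("SizeProfile: %d-%d bp grid (%d points)\n",
        min(object@size), max(object@size), length(object@size)))
})

setMethod("show", "MatchReport", function(object) {
    np <- sum(object@matched & upper.tri(object@matched))
    cat(sprintf(
        "MatchReport: %d lanes, %d complete, %d matched pair(s) at r > %g\n",
        nrow(object@r), sum(object@complete), np, object@rThreshold))
})

#' Read a densitometry lane profile from TSV
#'
#' Expects two tab-separated columns, \code{distance} and \code{intensity},
#' with or without a header line.
#'
#' @param path lane TSV file.
#' @return a [LaneProfile-class].
#' @export
readLaneProfile <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("[A-Za-z]", first)
    df <- read.table(path, sep = "\t", header = hasHeader)
    LaneProfile(df[[1L]], df[[2L]])
}

#' Read a ladder band table from TSV
#'
#' Expects two tab-separated columns, \code{size} (bp) and \code{distance}.
#'
#' @param path ladder TSV file.
#' @return a [LadderCalibration-class].
#' @export
readLadder <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("[A-Za-z]", first)
    df <- read.table(path, sep = "\t", header = hasHeader)
    calibrateLadder(data.frame(size = df[[1L]], distance = df[[2L]]))
}
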