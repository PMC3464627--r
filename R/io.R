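#' Read and write chrom.sizes files
#'
#' Two tab-separated columns: sequence name and length.
#'
#' @param path file path.
#' @return \code{readChromSizes} returns a named integer vector;
#'   \code{writeChromSizes} returns the path invisibly.
#' @export
readChromSizes <- function(path) {
    df <- read.table(path, sep = "\t", header = FALSE,
        col.names = c("name", "length"),
        colClasses = c("character", "integer"))
    checkSeqlengths(stats::setNames(df$length, df$name))
}

#' @rdname readChromSizes
#' @param seqlengths named vector of sequence lengths.
#' @export
writeChromSizes <- function(seqlengths, path) {
    seqlengths <- checkSeqlengths(seqlengths)
    writeLines(sprintf("%s\t%d", names(seqlengths), seqlengths), path)
    invisible(path)
}

# Report the first malformed data line of a tab-separated interval file.
.firstBadLine <- function(path, minFields) {
    lines <- readLines(path)
    for (i in seq_along(lines)) {
        ln <- lines[i]
        if (grepl("^(track|browser|#)", ln) || ln == "" ||
                grepl("^(fixedStep|variableStep)", ln))
            next
        f <- strsplit(ln, "\t")[[1L]]
        if (length(f) < minFields || anyNA(suppressWarnings(
                as.numeric(f[2:min(length(f), minFields)]))))
            return(i)
    }
    NA_integer_
}

# Bin an interval+score GRanges into a CoverageTrack by length-weighted
# averaging (uncovered bases contribute 0).
.scoresToTrack <- function(gr, seqlengths, binBp, source) {
    seqlengths <- checkSeqlengths(seqlengths)
    bad <- setdiff(unique(as.character(seqnames(gr))), names(seqlengths))
    if (length(bad))
        stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    vals <- lapply(names(seqlengths), function(chr) {
        L <- seqlengths[[chr]]
        sel <- gr[seqnames(gr) == chr]
        r <- IRanges::restrict(IRanges::ranges(sel), start = 1L, end = L)
        cov <- coverage(r, width = L, weight = mcols(sel)$score)
        starts <- .binStarts(L, binBp)
        v <- Views(cov, start = starts, end = pmin(starts + binBp - 1L, L))
        viewMeans(v)
    })
    names(vals) <- names(seqlengths)
    CoverageTrack(vals, binBp, seqlengths, metadata = list(source = source))
}

#' Read a bedGraph file into a binned coverage track
#'
#' Intervals are 0-based half-open on disk and converted to the in-memory
#' 1-based convention; interval values are averaged into fixed-width bins
#' weighted by the number of bases each interval contributes to the bin.
#' Overlapping intervals are rejected.
#'
#' @param path bedGraph file.
#' @param seqlengths named vector of sequence lengths.
#' @param binBp bin width in bp (default 10).
#' @return a [CoverageTrack-class].
#' @export
readBedGraphTrack <- function(path, seqlengths, binBp = 10L) {
    gr <- tryCatch(rtracklayer::import(path, format = "bedGraph"),
        error = function(e) stop("malformed bedGraph '", path, "' (line ",
            .firstBadLine(path, 4L), "): ", conditionMessage(e)))
    red <- reduce(granges(gr))
    if (sum(as.numeric(width(red))) < sum(as.numeric(width(gr))))
        stop("overlapping intervals in bedGraph '", path, "'")
    .scoresToTrack(gr, seqlengths, binBp, source = path)
}

#' Write a coverage track as bedGraph
#'
#' Adjacent bins with identical values are collapsed into single intervals;
#' coordinates are written 0-based half-open.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBedGraphTrack <- function(track, path) {
    con <- file(path, open = "wt")
    on.exit(close(con))
    bin <- track@binWidth
    for (chr in names(track@seqlengths)) {
        v <- track@values[[chr]]
        L <- track@seqlengths[[chr]]
        runs <- rle(v)
        endBin <- cumsum(runs$lengths)
        startBin <- endBin - runs$lengths + 1L
        writeLines(sprintf("%s\t%d\t%d\t%s", chr,
            (startBin - 1L) * bin, pmin(endBin * bin, L),
            formatC(runs$values, format = "g", digits = 15)), con)
    }
    invisible(path)
}

#' Read a wiggle file into a binned coverage track
#'
#' Accepts both fixedStep and variableStep records (1-based on disk, per the
#' wiggle standard); values are length-weighted into bins exactly as for
#' [readBedGraphTrack()].
#'
#' @param path wiggle file.
#' @param seqlengths named vector of sequence lengths.
#' @param binBp bin width in bp (default 10).
#' @return a [CoverageTrack-class].
#' @export
readWiggleTrack <- function(path, seqlengths, binBp = 10L) {
    gr <- tryCatch(rtracklayer::import(path, format = "wig"),
        error = function(e) stop("malformed wiggle '", path, "' (line ",
            .firstBadLine(path, 1L), "): ", conditionMessage(e)))
    .scoresToTrack(gr, seqlengths, binBp, source = path)
}

#' Read/write BED interval files
#'
#' BED files are 0-based half-open on disk; in memory intervals are 1-based
#' closed \linkS4class{GRanges}.
#'
#' @param path BED file.
#' @param seqlengths optional named vector of sequence lengths to attach.
#' @return \code{readBedRegions} returns a \linkS4class{GRanges};
#'   \code{writeBedRegions} returns the path invisibly.
#' @export
readBedRegions <- function(path, seqlengths = NULL) {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
        error = function(e) stop("malformed BED '", path, "' (line ",
            .firstBadLine(path, 3L), "): ", conditionMessage(e)))
    if (!is.null(seqlengths)) {
        seqlengths <- checkSeqlengths(seqlengths)
        GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
        GenomeInfoDb::seqlengths(gr) <- seqlengths
    }
    gr
}

#' @rdname readBedRegions
#' @param regions a \linkS4class{GRanges}.
#' @param score optional numeric vector written as the BED score column.
#' @export
writeBedRegions <- function(regions, path, score = NULL) {
    lines <- if (is.null(score))
        sprintf("%s\t%d\t%d", as.character(seqnames(regions)),
            start(regions) - 1L, end(regions))
    else
        sprintf("%s\t%d\t%d\t.\t%g", as.character(seqnames(regions)),
            start(regions) - 1L, end(regions), score)
    writeLines(lines, path)
    invisible(path)
}

#' Read probe-level binding records
#'
#' Tab-separated columns \code{chrom}, \code{start}, \code{end},
#' \code{log2ratio} (0-based half-open starts, BED-like), with or without a
#' header.
#'
#' @param path probe TSV file.
#' @return a \linkS4class{GRanges} with metadata column \code{log2ratio}.
#' @export
readProbes <- function(path) {
    first <- readLines(path, n = 1L)
    hasHeader <- grepl("[A-Za-z]", strsplit(first, "\t")[[1L]][2L])
    df <- read.table(path, sep = "\t", header = hasHeader,
        col.names = c("chrom", "start", "end", "log2ratio"))
    GRanges(df$chrom, IRanges(df$start + 1L, df$end),
        log2ratio = df$log2ratio)
}

#' @rdname readProbes
#' @param probes a \linkS4class{GRanges} with \code{log2ratio}.
#' @export
writeProbes <- function(probes, path) {
    writeLines(sprintf("%s\t%d\t%d\t%g", as.character(seqnames(probes)),
        start(probes) - 1L, end(probes), mcols(probes)$log2ratio), path)
    invisible(path)
}
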