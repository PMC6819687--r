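#' Count read starts in fixed-width windows
#'
#' Tiles each chromosome with non-overlapping windows of \code{width} bp
#' (the final partial window is kept) and assigns every read to the window
#' containing its start position.
#'
#' @param readStarts Data frame with columns \code{chrom} and \code{pos}
#'   (1-based read start positions), or a named list of position vectors.
#' @param chromLengths Named numeric vector of chromosome lengths.
#' @param width Window width in bp (default 400).
#' @return A \linkS4class{GRanges} of windows with metadata column
#'   \code{raw} (read count), tiling each chromosome without gaps.
#' @export
windowCounts <- function(readStarts, chromLengths, width = 400L) {
    if (is.list(readStarts) && !is.data.frame(readStarts))
        readStarts <- data.frame(
            chrom = rep(names(readStarts), lengths(readStarts)),
            pos = unlist(readStarts, use.names = FALSE))
    si <- GenomeInfoDb::Seqinfo(names(chromLengths),
                                unname(chromLengths))
    out <- lapply(names(chromLengths), function(ch) {
        len <- chromLengths[[ch]]
        nwin <- ceiling(len / width)
        ws <- (seq_len(nwin) - 1L) * width + 1L
        we <- pmin(ws + width - 1L, len)
        pos <- readStarts$pos[readStarts$chrom == ch]
        if (any(pos < 1 | pos > len))
            stop("read position outside chromosome ", ch)
        cnt <- tabulate((sort(pos) - 1L) %/% width + 1L, nbins = nwin)
        GRanges(ch, IRanges(ws, we), raw = cnt, seqinfo = si)
    })
    do.call(c, out)
}

#' Correct window counts for GC bias
#'
#' Bins windows by GC content into \code{nBins} equal-width bins on [0, 1]
#' and rescales each window's count by the ratio of the global mean count to
#' its bin's mean count.  Bins holding fewer than \code{minBinSize} windows
#' inherit the global mean (no correction).  The output is rescaled so the
#' total corrected mass equals the total raw mass.
#'
#' @param counts Numeric vector of raw window counts.
#' @param gc Numeric vector of per-window GC fractions.
#' @param nBins Number of GC bins (default 50).
#' @param minBinSize Minimum windows per bin for correction (default 20).
#' @return Numeric vector of corrected counts.
#' @export
gcCorrect <- function(counts, gc, nBins = 50L, minBinSize = 20L) {
    stopifnot(length(counts) == length(gc))
    bin <- pmin(pmax(floor(gc * nBins) + 1L, 1L), nBins)
    globalMean <- mean(counts)
    binMean <- tapply(counts, bin, mean)
    binN <- tapply(counts, bin, length)
    factorByBin <- ifelse(binN >= minBinSize & binMean > 0,
                          globalMean / binMean, 1)
    corrected <- counts * factorByBin[as.character(bin)]
    tot <- sum(corrected)
    if (tot > 0) corrected <- corrected * sum(counts) / tot
    as.numeric(corrected)
}

#' Hook for cross-window absolute copy-number correction
#'
#' Placeholder for a correction that groups windows by sequence similarity
#' (segmental-duplication aware recalibration).  The default implementation
#' is the identity; supply \code{fun} to plug in a custom correction.
#'
#' @param counts Numeric vector of window counts.
#' @param fun Optional function \code{counts -> counts}.
#' @return The (possibly corrected) counts.
#' @export
similarityCorrect <- function(counts, fun = NULL) {
    if (is.null(fun)) counts else fun(counts)
}

#' Estimate integer copy number per window
#'
#' Standardises corrected counts against the genome-wide median (assumed
#' diploid) and rounds \code{2 * corrected / median} half away from zero,
#' capping at \code{maxCn}.
#'
#' @param corrected Numeric vector of corrected window counts.
#' @param maxCn Cap on the reported copy number (default 10).
#' @return Integer vector of per-window copy numbers.
#' @export
estimateCopyNumber <- function(corrected, maxCn = 10L) {
    m <- median(corrected)
    if (m == 0) stop("degenerate coverage: median corrected count is zero")
    pmin(as.integer(roundHalfUp(2 * corrected / m)), as.integer(maxCn))
}

#' Segment windows into read-depth CNV regions
#'
#' Maximal runs of non-diploid windows become regions; runs interrupted by
#' at most \code{bridge} consecutive diploid windows are bridged into one
#' region, and regions spanning fewer than \code{minRun} windows in total
#' are dropped.  Each region's copy number is the most frequent non-diploid
#' copy number among its windows.
#'
#' @param windows A \linkS4class{GRanges} of windows (from
#'   \code{\link{windowCounts}}) with metadata column \code{cn}.
#' @param minRun Minimum windows per region (default 5).
#' @param bridge Maximum diploid windows bridged inside a region (default 1).
#' @return A \linkS4class{GRanges} of depth CNV regions with metadata
#'   column \code{cn}.
#' @export
callDepthCnvrs <- function(windows, minRun = 5L, bridge = 1L) {
    si <- GenomeInfoDb::seqinfo(windows)
    out <- list()
    for (ch in seqlevelsInUse(windows)) {
        wi <- windows[seqnames(windows) == ch]
        cn <- mcols(wi)$cn
        alt <- which(cn != 2L)
        if (!length(alt)) next
        grp <- cumsum(c(1L, diff(alt) > bridge + 1L))
        for (g in unique(grp)) {
            run <- alt[grp == g]
            first <- run[1L]
            last <- run[length(run)]
            if (last - first + 1L < minRun) next
            cnRun <- cn[first:last]
            tb <- table(cnRun[cnRun != 2L])
            out[[length(out) + 1L]] <- GRanges(
                ch, IRanges(start(wi)[first], end(wi)[last]),
                cn = as.integer(names(tb)[which.max(tb)]), seqinfo = si)
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr)$cn <- integer(0)
        return(gr)
    }
    .sortNatural(do.call(c, out))
}

#' Confirm array CNVRs against read-depth regions
#'
#' A CNVR is confirmed when it overlaps (by at least 1 bp, or by the given
#' reciprocal fraction) a depth region of compatible polarity: gains require
#' depth copy number above 2, losses below 2, and mixed (both) regions
#' accept either.
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param depthCnvrs A \linkS4class{GRanges} with metadata column \code{cn}
#'   (from \code{\link{callDepthCnvrs}}).
#' @param reciprocal Optional minimum reciprocal overlap fraction in [0, 1];
#'   0 (default) requires a single shared base.
#' @return A list: \code{confirmed} (logical per CNVR) and \code{rate}
#'   (percentage confirmed, 2 decimals).
#' @export
validateCnvrs <- function(cnvrs, depthCnvrs, reciprocal = 0) {
    if (!length(cnvrs))
        return(list(confirmed = logical(0), rate = NA_real_))
    hit <- findOverlaps(cnvrs, depthCnvrs)
    ok <- logical(length(hit))
    if (length(hit)) {
        ev <- mcols(cnvrs)$event[queryHits(hit)]
        cn <- mcols(depthCnvrs)$cn[subjectHits(hit)]
        polarity <- (ev == "gain" & cn > 2L) | (ev == "loss" & cn < 2L) |
            (ev == "both" & cn != 2L)
        if (reciprocal > 0) {
            ints <- width(pintersect(granges(cnvrs)[queryHits(hit)],
                                     granges(depthCnvrs)[subjectHits(hit)]))
            frac <- ints / pmax(width(cnvrs)[queryHits(hit)],
                                width(depthCnvrs)[subjectHits(hit)])
            polarity <- polarity & frac >= reciprocal
        }
        ok <- polarity
    }
    confirmed <- logical(length(cnvrs))
    confirmed[unique(queryHits(hit)[ok])] <- TRUE
    list(confirmed = confirmed,
         rate = summaryPercent(sum(confirmed), length(cnvrs)))
}
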