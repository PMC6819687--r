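#' Cluster overlapping CNV calls
#'
#' Groups calls (across all samples, per chromosome) into maximal connected
#' components under pairwise positional overlap of at least 1 bp.  Abutting
#' calls do not merge.  Each cluster's raw extent is the union span of its
#' members.
#'
#' @param calls A \linkS4class{CnvCalls} object (or GRanges).
#' @return A list: \code{membership} (integer cluster id per call) and
#'   \code{regions} (GRanges of raw cluster extents, one per cluster, in
#'   genome order).
#' @export
mergeCalls <- function(calls) {
    if (!length(calls))
        return(list(membership = integer(0), regions = GRanges()))
    regions <- reduce(granges(calls), min.gapwidth = 0L)
    hit <- findOverlaps(calls, regions)
    membership <- integer(length(calls))
    membership[queryHits(hit)] <- subjectHits(hit)
    list(membership = membership, regions = regions)
}

#' Trim cluster boundaries at 2.5\% cumulative coverage
#'
#' Given the member calls of one cluster (1-based closed coordinates on one
#' chromosome), builds the per-base coverage profile c(x), and with total
#' mass M = sum of c(x) returns the consensus region that excludes the
#' outermost \code{q} of coverage mass on each side: the trimmed start is the
#' smallest base with at least \code{q * M} mass strictly before it, the
#' trimmed end the largest base with at least \code{q * M} mass strictly
#' after it.  Implemented as a breakpoint sweep, never materialising
#' per-base arrays.  If trimming would invert the interval (only possible
#' for extents of a few bases) the raw extent is returned unchanged.
#'
#' @param starts,ends Integer vectors of member call coordinates (closed).
#' @param q Cumulative-frequency fraction trimmed per side (default 0.025).
#' @return Integer vector \code{c(start, end)} (1-based closed).
#' @examples
#' trimBoundaries(c(1001, 1001), c(2000, 2000))  # c(1026, 1975)
#' @export
trimBoundaries <- function(starts, ends, q = 0.025) {
    stopifnot(length(starts) == length(ends), length(starts) >= 1,
              all(ends >= starts))
    bp <- sort(unique(c(starts, ends + 1)))
    segStart <- bp[-length(bp)]
    segEnd <- bp[-1] - 1
    cov <- vapply(segStart, function(x) sum(starts <= x & ends >= x),
                  numeric(1))
    segLen <- segEnd - segStart + 1
    mass <- cov * segLen
    M <- sum(mass)
    qm <- q * M
    cumBefore <- cumsum(c(0, mass[-length(mass)]))
    # trimmed start: smallest x with mass strictly before x >= qm
    a <- NA_integer_
    for (k in seq_along(mass)) {
        if (cov[k] > 0 && cumBefore[k] + cov[k] * segLen[k] >= qm) {
            need <- qm - cumBefore[k]
            a <- segStart[k] + max(0, ceiling(need / cov[k]))
            if (a <= segEnd[k] + 1) break
        }
    }
    cumAfter <- rev(cumsum(rev(c(mass[-1], 0))))
    # trimmed end: largest x with mass strictly after x >= qm
    b <- NA_integer_
    for (k in rev(seq_along(mass))) {
        if (cov[k] > 0 && cumAfter[k] + cov[k] * segLen[k] >= qm) {
            need <- qm - cumAfter[k]
            b <- segEnd[k] - max(0, ceiling(need / cov[k]))
            if (b >= segStart[k] - 1) break
        }
    }
    lo <- min(starts)
    hi <- max(ends)
    as.integer(if (is.na(a) || is.na(b) || a > b) c(lo, hi) else c(a, b))
}

#' Classify a cluster's event polarity
#'
#' @param copyNumbers Integer copy numbers of the supporting calls.
#' @return \code{"gain"} if all are above 2, \code{"loss"} if all below 2,
#'   \code{"both"} otherwise.
#' @export
classifyEvent <- function(copyNumbers) {
    stopifnot(length(copyNumbers) >= 1, all(copyNumbers != 2))
    if (all(copyNumbers > 2)) "gain"
    else if (all(copyNumbers < 2)) "loss"
    else "both"
}

#' Build population CNVRs from per-sample calls
#'
#' Merges overlapping calls into clusters, removes clusters supported by
#' fewer than \code{minIndividuals} distinct samples (two calls from the
#' same sample do not rescue a cluster), trims the survivors' boundaries at
#' the \code{q} cumulative-coverage quantile per side, classifies each
#' region as gain/loss/both, and labels regions CNVR1..CNVRn in
#' (chromosome, start) order.
#'
#' @param calls A \linkS4class{CnvCalls} object.
#' @param q Boundary trim fraction per side (default 0.025).
#' @param minIndividuals Minimum distinct supporting samples (default 2).
#' @return A \linkS4class{CnvrSet}.
#' @export
buildCnvrs <- function(calls, q = 0.025, minIndividuals = 2L) {
    empty <- function() {
        gr <- GRanges()
        mcols(gr) <- DataFrame(cnvr_id = character(0), event = character(0),
                               n_individuals = integer(0),
                               n_calls = integer(0), raw_start = integer(0),
                               raw_end = integer(0))
        new("CnvrSet", gr)
    }
    if (!length(calls)) return(empty())
    cl <- mergeCalls(calls)
    recs <- lapply(seq_along(cl$regions), function(k) {
        mem <- which(cl$membership == k)
        nInd <- length(unique(mcols(calls)$sample[mem]))
        if (nInd < minIndividuals) return(NULL)
        tr <- trimBoundaries(start(calls)[mem], end(calls)[mem], q = q)
        data.frame(chrom = as.character(seqnames(cl$regions))[k],
                   start = tr[1], end = tr[2],
                   raw_start = start(cl$regions)[k],
                   raw_end = end(cl$regions)[k],
                   event = classifyEvent(mcols(calls)$copy_number[mem]),
                   n_individuals = nInd, n_calls = length(mem))
    })
    recs <- recs[!vapply(recs, is.null, logical(1))]
    if (!length(recs)) return(empty())
    df <- do.call(rbind, recs)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), event = df$event,
                  n_individuals = as.integer(df$n_individuals),
                  n_calls = as.integer(df$n_calls),
                  raw_start = as.integer(df$raw_start),
                  raw_end = as.integer(df$raw_end))
    gr <- .sortNatural(gr)
    mcols(gr)$cnvr_id <- paste0("CNVR", seq_along(gr))
    mcols(gr) <- mcols(gr)[, c("cnvr_id", "event", "n_individuals",
                               "n_calls", "raw_start", "raw_end")]
    new("CnvrSet", gr)
}

#' Drop CNVRs supported by a single individual
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param minIndividuals Minimum distinct supporting samples (default 2).
#' @return The filtered \linkS4class{CnvrSet}.
#' @export
filterSingletons <- function(cnvrs, minIndividuals = 2L) {
    keep <- mcols(cnvrs)$n_individuals >= minIndividuals
    cnvrs[keep]
}

#' Summarise a CNVR set
#'
#' Computes the genome summary reported for a CNVR catalogue: total count,
#' per-chromosome counts and percentages, length statistics, total length
#' and genome fraction, event-class breakdown, and the mean number of CNVRs
#' and CNV calls per individual when cohort sizes are supplied.  All
#' percentages and means use \code{\link{summaryPercent}} rounding (half
#' away from zero, 2 decimals).
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param chromLengths Named numeric vector of chromosome lengths in bp,
#'   covering every CNVR chromosome; its sum is the genome denominator.
#' @param nSamples Optional cohort size for the mean-CNVRs-per-individual
#'   figure.
#' @param nCnvCalls Optional total CNV call count for the
#'   mean-CNVs-per-individual figure.
#' @return A list of summary components; empty CNVR sets yield zero counts
#'   with the undefined means reported as \code{NA}.
#' @export
summarizeCnvrs <- function(cnvrs, chromLengths, nSamples = NULL,
                           nCnvCalls = NULL) {
    chroms <- unique(as.character(seqnames(cnvrs)))
    missing <- setdiff(chroms, names(chromLengths))
    if (length(missing))
        stop("missing chromosome length for: ",
             paste(missing, collapse = ", "))
    n <- length(cnvrs)
    if (n == 0) {
        return(list(n = 0L, perChromosome = data.frame(
            chrom = character(0), count = integer(0), pct = numeric(0)),
            lengthBp = c(min = NA_real_, mean = NA_real_, max = NA_real_,
                         total = 0),
            genomePct = 0,
            events = data.frame(event = c("gain", "loss", "both"),
                                count = c(0L, 0L, 0L), pct = c(0, 0, 0)),
            meanCnvrsPerIndividual = NA_real_,
            meanCnvsPerIndividual = NA_real_))
    }
    w <- width(cnvrs)
    perChr <- as.data.frame(table(
        chrom = factor(as.character(seqnames(cnvrs)),
                       levels = names(chromLengths))),
        responseName = "count")
    perChr$pct <- summaryPercent(perChr$count, n)
    ev <- table(factor(mcols(cnvrs)$event,
                       levels = c("gain", "loss", "both")))
    events <- data.frame(event = names(ev), count = as.integer(ev),
                         pct = summaryPercent(as.integer(ev), n))
    list(n = n,
         perChromosome = perChr,
         lengthBp = c(min = min(w), mean = mean(w), max = max(w),
                      total = sum(w)),
         genomePct = summaryPercent(sum(w), sum(chromLengths)),
         events = events,
         meanCnvrsPerIndividual = if (is.null(nSamples)) NA_real_
             else summaryPercent(n, nSamples, mean = TRUE),
         meanCnvsPerIndividual = if (is.null(nCnvCalls) ||
                                     is.null(nSamples)) NA_real_
             else summaryPercent(nCnvCalls, nSamples, mean = TRUE))
}

#' Export a CNVR table
#'
#' Tab-delimited table (id, chrom, start, end, length, event,
#' n_individuals), 1-based inclusive coordinates.
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeCnvrTable <- function(cnvrs, path) {
    df <- data.frame(id = mcols(cnvrs)$cnvr_id,
                     chrom = as.character(seqnames(cnvrs)),
                     start = start(cnvrs), end = end(cnvrs),
                     length = width(cnvrs), event = mcols(cnvrs)$event,
                     n_individuals = mcols(cnvrs)$n_individuals)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
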