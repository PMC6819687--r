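#' @import methods
#' @importFrom stats dnorm pnorm dbinom median sd cor rexp rnorm runif rbinom
#'   rpois phyper setNames aggregate quantile
#' @importFrom utils read.delim write.table head tail
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits metadata
#'   metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges findOverlaps countOverlaps reduce
#'   pintersect seqnames start end width start<- end<-
#' @importFrom GenomeInfoDb seqlevels seqlevels<- sortSeqlevels seqlengths
#'   seqlengths<- seqlevelsInUse keepSeqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   rowRanges<- colData
NULL

HMM_STATES <- c("CN0", "CN1", "CN2", "CN2-LOH", "CN3", "CN4")
HMM_COPY_NUMBER <- c(0L, 1L, 2L, 2L, 3L, 4L)
CN2_STATE <- 3L

#' Ordered autosomal marker map
#'
#' A \code{MarkerMap} is a \linkS4class{GRanges} of width-1 SNP positions,
#' sorted by chromosome and position, carrying the population B allele
#' frequency (PFB) of every marker in the metadata column \code{pfb}.  Marker
#' names are stored as range names and must be unique.  It is the coordinate
#' backbone all calling operates on.
#'
#' @slot .  Inherits every slot of \code{GRanges}.
#' @seealso \code{\link{markerMap}}, \code{\link{readMarkerMap}}
#' @export
setClass("MarkerMap", contains = "GRanges", validity = function(object) {
    msg <- character()
    if (length(object)) {
        if (is.null(names(object)) || anyNA(names(object)) ||
            any(names(object) == ""))
            msg <- c(msg, "all markers must be named")
        else if (anyDuplicated(names(object)))
            msg <- c(msg, paste0("duplicated marker name: ",
                names(object)[anyDuplicated(names(object))]))
        if (!"pfb" %in% colnames(mcols(object)))
            msg <- c(msg, "metadata column 'pfb' is required")
        else {
            p <- mcols(object)$pfb
            if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
                msg <- c(msg, "'pfb' must be numeric in [0, 1]")
        }
        if (any(width(object) != 1L))
            msg <- c(msg, "markers must be width-1 positions")
        bychr <- split(start(object), as.character(seqnames(object)))
        if (any(vapply(bychr, function(p) is.unsorted(p, strictly = TRUE),
                       logical(1))))
            msg <- c(msg,
                "positions must be strictly increasing within chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a marker map
#'
#' Builds a \linkS4class{MarkerMap} from parallel vectors, sorting markers by
#' (chromosome, position) with natural chromosome ordering.
#'
#' @param name Character vector of unique marker names.
#' @param chrom Character vector of chromosome names (autosomes).
#' @param pos Integer vector of 1-based marker positions.
#' @param pfb Numeric vector of population B allele frequencies in [0, 1];
#'   defaults to 0.5 for every marker.
#' @return A \linkS4class{MarkerMap}.
#' @examples
#' markerMap(c("s1", "s2"), c("1", "1"), c(100L, 200L))
#' @export
markerMap <- function(name, chrom, pos, pfb = rep(0.5, length(name))) {
    stopifnot(length(name) == length(chrom), length(chrom) == length(pos),
              length(pfb) == length(name))
    gr <- GRanges(as.character(chrom), IRanges(as.integer(pos), width = 1L),
                  pfb = as.numeric(pfb))
    names(gr) <- as.character(name)
    gr <- sortSeqlevels(gr)
    gr <- sort(gr)
    new("MarkerMap", gr)
}

#' Population B allele frequencies of a marker map or signal set
#' @param x A \linkS4class{MarkerMap} or \linkS4class{SignalSet}.
#' @return Numeric vector of per-marker PFB values.
#' @export
setGeneric("pfb", function(x) standardGeneric("pfb"))

#' @describeIn pfb PFB column of the map.
#' @export
setMethod("pfb", "MarkerMap", function(x) setNames(mcols(x)$pfb, names(x)))

#' Replace PFB values
#' @param x A \linkS4class{MarkerMap} or \linkS4class{SignalSet}.
#' @param value Numeric vector in [0, 1], one value per marker.
#' @export
setGeneric("pfb<-", function(x, value) standardGeneric("pfb<-"))

#' @describeIn pfb Replace the PFB column.
#' @export
setReplaceMethod("pfb", "MarkerMap", function(x, value) {
    mcols(x)$pfb <- value
    validObject(x)
    x
})

setMethod("show", "MarkerMap", function(object) {
    cat("MarkerMap with", length(object), "markers on",
        length(seqlevelsInUse(object)), "chromosome(s)\n")
    callNextMethod()
})

#' Per-sample LRR/BAF signal container
#'
#' A \code{SignalSet} is a \linkS4class{RangedSummarizedExperiment} whose rows
#' are the markers of a \linkS4class{MarkerMap} and whose columns are samples,
#' with two assays: \code{lrr} (Log R Ratio, log2-scale total intensity) and
#' \code{baf} (B allele frequency in [0, 1]).  \code{NA} is the missing-value
#' sentinel; missing markers are skipped by the HMM rather than imputed.
#'
#' @seealso \code{\link{signalSet}}, \code{\link{callCnvs}}
#' @export
setClass("SignalSet", contains = "RangedSummarizedExperiment",
    validity = function(object) {
        msg <- character()
        if (!all(c("lrr", "baf") %in% names(assays(object))))
            msg <- c(msg, "assays 'lrr' and 'baf' are required")
        else {
            b <- assay(object, "baf")
            if (any(b < 0 | b > 1, na.rm = TRUE))
                msg <- c(msg, "'baf' values must lie in [0, 1] or be NA")
        }
        if (!"pfb" %in% colnames(mcols(rowRanges(object))))
            msg <- c(msg, "rowRanges must carry a 'pfb' column")
        if (length(msg)) msg else TRUE
    })

#' Construct a signal set
#'
#' @param map A \linkS4class{MarkerMap}.
#' @param lrr,baf Numeric matrices (markers x samples) aligned to \code{map};
#'   row names must match marker names when present.  \code{NA} marks missing
#'   entries.
#' @return A \linkS4class{SignalSet}.
#' @export
signalSet <- function(map, lrr, baf) {
    stopifnot(is(map, "MarkerMap"), nrow(lrr) == length(map),
              identical(dim(lrr), dim(baf)))
    if (!is.null(rownames(lrr)))
        stopifnot(identical(rownames(lrr), names(map)))
    rownames(lrr) <- rownames(baf) <- names(map)
    se <- SummarizedExperiment(assays = list(lrr = lrr, baf = baf),
                               rowRanges = as(map, "GRanges"))
    new("SignalSet", se)
}

#' Log R Ratio assay
#' @param x A \linkS4class{SignalSet}.
#' @return Numeric matrix (markers x samples).
#' @export
setGeneric("lrr", function(x) standardGeneric("lrr"))

#' @describeIn lrr LRR assay of a signal set.
#' @export
setMethod("lrr", "SignalSet", function(x) assay(x, "lrr"))

#' B allele frequency assay
#' @param x A \linkS4class{SignalSet}.
#' @return Numeric matrix (markers x samples) with values in [0, 1] or NA.
#' @export
setGeneric("baf", function(x) standardGeneric("baf"))

#' @describeIn baf BAF assay of a signal set.
#' @export
setMethod("baf", "SignalSet", function(x) assay(x, "baf"))

#' @describeIn pfb PFB values attached to the signal set's markers.
#' @export
setMethod("pfb", "SignalSet", function(x)
    setNames(mcols(rowRanges(x))$pfb, rownames(x)))

#' @describeIn pfb Replace PFB values on the signal set's markers.
#' @export
setReplaceMethod("pfb", "SignalSet", function(x, value) {
    mcols(rowRanges(x))$pfb <- value
    validObject(x)
    x
})

#' Marker map of a signal set
#' @param x A \linkS4class{SignalSet}.
#' @return The \linkS4class{MarkerMap} underlying the rows.
#' @export
setGeneric("markerMapOf", function(x) standardGeneric("markerMapOf"))

#' @describeIn markerMapOf Marker backbone of the signal set.
#' @export
setMethod("markerMapOf", "SignalSet", function(x)
    new("MarkerMap", rowRanges(x)))

#' Six-state copy-number HMM parameterisation
#'
#' Holds the emission and transition parameters of the hidden Markov model
#' used to segment LRR/BAF tracks.  States are, in order, CN0 (homozygous
#' deletion), CN1 (hemizygous deletion), CN2 (diploid), CN2-LOH (copy-neutral
#' loss of heterozygosity), CN3 and CN4 (duplications).
#'
#' @slot lrrMean Per-state LRR means; nondecreasing across CN0..CN4.
#' @slot lrrSd Per-state LRR standard deviations.
#' @slot bafClusterSd Standard deviation of each BAF genotype cluster.
#' @slot bafOutlierWeight Mixture weight of the uniform BAF outlier component.
#' @slot stayProb Per-state self-transition probability in the
#'   infinite-distance limit.
#' @slot baseWeights Unnormalised inter-state jump weights (favouring CN2).
#' @slot decayLength Distance constant D (bp) of the exponential transition
#'   decay \code{1 - exp(-d/D)}.
#' @slot minSnps Minimum consecutive markers for a reportable call.
#' @slot initProb Initial state distribution (strongly favouring CN2).
#' @seealso \code{\link{hmmModel}}, \code{\link{viterbiDecode}}
#' @export
setClass("HmmModel", representation(
    lrrMean = "numeric", lrrSd = "numeric", bafClusterSd = "numeric",
    bafOutlierWeight = "numeric", stayProb = "numeric",
    baseWeights = "numeric", decayLength = "numeric", minSnps = "integer",
    initProb = "numeric"),
    validity = function(object) {
        msg <- character()
        for (s in c("lrrMean", "lrrSd", "stayProb", "baseWeights", "initProb"))
            if (length(slot(object, s)) != 6L)
                msg <- c(msg, paste0("'", s, "' must have length 6"))
        if (!length(msg)) {
            cnIdx <- c(1L, 2L, 3L, 5L, 6L)  # CN0,CN1,CN2,CN3,CN4
            if (is.unsorted(object@lrrMean[cnIdx]))
                msg <- c(msg,
                    "lrrMean must be nondecreasing in copy number")
            if (any(object@lrrSd <= 0) || object@bafClusterSd <= 0)
                msg <- c(msg, "standard deviations must be positive")
            if (any(object@stayProb <= 0 | object@stayProb >= 1))
                msg <- c(msg, "stayProb must lie in (0, 1)")
            if (any(object@baseWeights <= 0))
                msg <- c(msg, "baseWeights must be positive")
            if (object@bafOutlierWeight < 0 || object@bafOutlierWeight >= 1)
                msg <- c(msg, "bafOutlierWeight must lie in [0, 1)")
            if (object@decayLength <= 0)
                msg <- c(msg, "decayLength must be positive")
            if (object@minSnps < 1L)
                msg <- c(msg, "minSnps must be >= 1")
            if (abs(sum(object@initProb) - 1) > 1e-8 ||
                any(object@initProb <= 0))
                msg <- c(msg, "initProb must be a positive distribution")
        }
        if (length(msg)) msg else TRUE
    })

#' Construct the copy-number HMM
#'
#' Default parameters place the per-state LRR means at the canonical shifts
#' observed on SNP arrays (deep negative for CN0, about -0.67 for one copy,
#' 0 for diploid, +0.40 and +0.68 for three and four copies) and make CN2
#' sticky so that isolated noisy markers do not open segments.
#'
#' @param lrrMean,lrrSd Per-state LRR Gaussian parameters (length 6, order
#'   CN0, CN1, CN2, CN2-LOH, CN3, CN4).
#' @param bafClusterSd Within-cluster BAF standard deviation.
#' @param bafOutlierWeight Weight of the uniform BAF outlier component.
#' @param stayProb Per-state long-distance self-transition probability.
#' @param baseWeights Jump destination weights; the CN2 entry dominates so
#'   segments close back to diploid.
#' @param decayLength Transition distance constant D in bp.
#' @param minSnps Minimum markers per reported call (3 by default).
#' @param initProb Initial state distribution; normalised internally.
#' @return An \linkS4class{HmmModel}.
#' @examples
#' m <- hmmModel()
#' transitionMatrix(m, 5000)
#' @export
hmmModel <- function(lrrMean = c(-3.5, -0.67, 0, 0, 0.40, 0.68),
                     lrrSd = c(0.3, 0.25, 0.2, 0.2, 0.25, 0.3),
                     bafClusterSd = 0.03,
                     bafOutlierWeight = 0.01,
                     stayProb = c(0.95, 0.95, 0.999, 0.95, 0.95, 0.95),
                     baseWeights = c(0.02, 0.10, 0.60, 0.03, 0.15, 0.10),
                     decayLength = 1e5,
                     minSnps = 3L,
                     initProb = c(0.001, 0.002, 0.994, 0.001, 0.001, 0.001)) {
    new("HmmModel", lrrMean = lrrMean, lrrSd = lrrSd,
        bafClusterSd = bafClusterSd, bafOutlierWeight = bafOutlierWeight,
        stayProb = stayProb, baseWeights = baseWeights,
        decayLength = decayLength, minSnps = as.integer(minSnps),
        initProb = initProb / sum(initProb))
}

setMethod("show", "HmmModel", function(object) {
    cat("HmmModel (6 states:", paste(HMM_STATES, collapse = " "), ")\n")
    cat("  lrrMean:", paste(format(object@lrrMean), collapse = " "), "\n")
    cat("  lrrSd:  ", paste(format(object@lrrSd), collapse = " "), "\n")
    cat("  bafClusterSd:", object@bafClusterSd,
        " outlierWeight:", object@bafOutlierWeight, "\n")
    cat("  decayLength:", object@decayLength, "bp  minSnps:",
        object@minSnps, "\n")
})

#' Per-sample CNV calls
#'
#' A \linkS4class{GRanges} subclass holding one range per called segment, with
#' metadata columns \code{sample}, \code{state}, \code{copy_number} (0, 1, 3
#' or 4 -- diploid and copy-neutral LOH segments are never reported),
#' \code{num_snps} and \code{confidence} (log-likelihood ratio of the called
#' state against CN2 over the segment's markers).
#'
#' @export
setClass("CnvCalls", contains = "GRanges", validity = function(object) {
    msg <- character()
    need <- c("sample", "state", "copy_number", "num_snps", "confidence")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing metadata column(s): ",
                             paste(miss, collapse = ", ")))
    else if (length(object)) {
        if (!all(mcols(object)$copy_number %in% c(0L, 1L, 3L, 4L)))
            msg <- c(msg, "copy_number must be one of 0, 1, 3, 4")
        if (any(mcols(object)$num_snps < 1L))
            msg <- c(msg, "num_snps must be >= 1")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CnvCalls", function(object) {
    cat("CnvCalls:", length(object), "call(s) in",
        length(unique(mcols(object)$sample)), "sample(s)\n")
    callNextMethod()
})

#' Population copy-number variation regions
#'
#' A \linkS4class{GRanges} subclass holding trimmed CNVR boundaries with
#' metadata columns \code{cnvr_id}, \code{event} (gain/loss/both),
#' \code{n_individuals} (distinct supporting samples), \code{n_calls}, and
#' the untrimmed union extent \code{raw_start}/\code{raw_end}.
#'
#' @seealso \code{\link{buildCnvrs}}
#' @export
setClass("CnvrSet", contains = "GRanges", validity = function(object) {
    msg <- character()
    need <- c("cnvr_id", "event", "n_individuals", "n_calls",
              "raw_start", "raw_end")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing metadata column(s): ",
                             paste(miss, collapse = ", ")))
    else if (length(object)) {
        mc <- mcols(object)
        if (!all(mc$event %in% c("gain", "loss", "both")))
            msg <- c(msg, "event must be gain, loss or both")
        if (any(mc$n_individuals < 1L))
            msg <- c(msg, "n_individuals must be >= 1")
        if (any(mc$raw_start > start(object)) ||
            any(mc$raw_end < end(object)))
            msg <- c(msg, "trimmed boundaries must lie within the raw extent")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "CnvrSet", function(object) {
    ev <- table(factor(mcols(object)$event,
                       levels = c("gain", "loss", "both")))
    cat("CnvrSet:", length(object), "CNVR(s) [",
        paste(names(ev), as.integer(ev), collapse = ", "), "]\n")
    callNextMethod()
})
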