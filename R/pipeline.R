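#' Pipeline threshold configuration
#'
#' Collects every stage threshold with its conventional default: genotype
#' call rate 0.90, MAF 0.05, sample missingness 0.1, LRR SD 0.3, BAF drift
#' 0.02, waviness 0.05, minimum 3 SNPs per call, 400 bp depth windows and
#' 2.5\% CNVR boundary trimming.
#'
#' @param callRateMin,mafMin,hwePMin Marker QC thresholds.
#' @param maxMissing Sample missingness threshold.
#' @param lrrSdMax,bafDriftMax,wavinessMax Signal QC thresholds.
#' @param minSnps Minimum markers per CNV call.
#' @param trimQ CNVR boundary trim fraction per side.
#' @param minIndividuals Minimum distinct samples per CNVR.
#' @param windowWidth Depth window width (bp).
#' @param minRun Minimum windows per depth region.
#' @return A list of thresholds (class \code{PipelineConfig}).
#' @export
pipelineConfig <- function(callRateMin = 0.90, mafMin = 0.05,
                           hwePMin = 1e-6, maxMissing = 0.1,
                           lrrSdMax = 0.3, bafDriftMax = 0.02,
                           wavinessMax = 0.05, minSnps = 3L,
                           trimQ = 0.025, minIndividuals = 2L,
                           windowWidth = 400L, minRun = 5L) {
    cfg <- list(callRateMin = callRateMin, mafMin = mafMin,
                hwePMin = hwePMin, maxMissing = maxMissing,
                lrrSdMax = lrrSdMax, bafDriftMax = bafDriftMax,
                wavinessMax = wavinessMax, minSnps = as.integer(minSnps),
                trimQ = trimQ, minIndividuals = as.integer(minIndividuals),
                windowWidth = as.integer(windowWidth),
                minRun = as.integer(minRun))
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the cohort CNV discovery pipeline
#'
#' Orchestrates the stages in their canonical order: sample genotype
#' missingness filtering, marker QC (call rate, MAF, HWE), PFB computation
#' from the QC-passing samples, sample signal QC, per-sample HMM calling,
#' CNVR construction, and the genome summary; then the optional analytics
#' stages -- read-depth validation, concordance with reference catalogues,
#' QTL overlap, and gene content with term enrichment -- each skipped with
#' an explicit placeholder when its input is absent.  Every percentage in
#' the report is recomputable through \code{\link{summaryPercent}} from the
#' printed numerator and denominator, and this self-consistency is asserted
#' on every run.
#'
#' @param signal A \linkS4class{SignalSet}.
#' @param genotypes Optional dosage matrix (markers x samples) for genotype
#'   QC; markers must match the signal's.
#' @param chromLengths Named chromosome length vector.
#' @param model An \linkS4class{HmmModel}.
#' @param config A \code{\link{pipelineConfig}}.
#' @param depthCnvrs Optional \linkS4class{GRanges} of read-depth regions
#'   (with \code{cn}) for validation.
#' @param referenceCnvrs Optional named list of \linkS4class{GRanges}
#'   reference catalogues for concordance.
#' @param qtl Optional QTL \linkS4class{GRanges} (with \code{qtl_id},
#'   \code{trait}).
#' @param genes Optional gene \linkS4class{GRanges} (with \code{gene_id}).
#' @param annotation Optional gene-to-term table for enrichment (see
#'   \code{\link{termEnrichment}}); used with \code{genes}.
#' @param gcTrack Optional GC \linkS4class{GRanges} for signing the
#'   waviness factor.
#' @return A \code{CohortCnvReport} list: per-stage removal records,
#'   \code{calls}, \code{cnvrs}, \code{summary}, the optional stage
#'   outputs, and \code{provenance}.
#' @export
runPipeline <- function(signal, genotypes = NULL, chromLengths,
                        model = hmmModel(), config = pipelineConfig(),
                        depthCnvrs = NULL, referenceCnvrs = NULL,
                        qtl = NULL, genes = NULL, annotation = NULL,
                        gcTrack = NULL) {
    stopifnot(is(signal, "SignalSet"))
    report <- list(stages = character(0))
    note <- function(st) report$stages <<- c(report$stages, st)

    samples <- colnames(signal)
    if (!is.null(genotypes)) {
        keep <- sampleMissingnessFilter(genotypes, config$maxMissing)
        report$sampleMissingness <- list(
            removed = setdiff(samples, keep), retained = keep)
        samples <- intersect(samples, keep)
        mq <- snpQc(genotypes[, samples, drop = FALSE],
                    callRateMin = config$callRateMin,
                    mafMin = config$mafMin, hwePMin = config$hwePMin)
        report$snpQc <- mq[c("removed", "removedExclusive")]
        report$snpQc$nRetained <- length(mq$retained)
        keepM <- rownames(signal) %in% mq$retained
        signal <- signal[keepM, ]
        note("genotype_qc")
    } else {
        report$sampleMissingness <- report$snpQc <- "skipped (no genotypes)"
    }

    pfb(signal) <- computePfb(signal[, samples], samples)
    note("pfb")

    qc <- sampleSignalQc(signal[, samples], gcTrack = gcTrack,
                         lrrSdMax = config$lrrSdMax,
                         bafDriftMax = config$bafDriftMax,
                         wavinessMax = config$wavinessMax)
    report$signalQc <- qc
    passing <- qc$sample[qc$pass]
    report$signalQcRemoved <- setdiff(samples, passing)
    note("signal_qc")
    if (!length(passing))
        stop("pipeline stage signal_qc: no samples passed")

    calls <- callCnvs(signal, model, samples = passing)
    report$calls <- calls
    note("cnv_calling")

    cnvrs <- buildCnvrs(calls, q = config$trimQ,
                        minIndividuals = config$minIndividuals)
    report$cnvrs <- cnvrs
    note("cnvr_building")

    report$summary <- summarizeCnvrs(cnvrs, chromLengths,
                                     nSamples = length(passing),
                                     nCnvCalls = length(calls))
    note("summary")

    report$validation <- if (!is.null(depthCnvrs) && length(cnvrs)) {
        note("depth_validation")
        validateCnvrs(cnvrs, depthCnvrs)
    } else "skipped (no depth data)"

    report$concordance <- if (!is.null(referenceCnvrs) && length(cnvrs)) {
        note("concordance")
        do.call(rbind, lapply(names(referenceCnvrs), function(lb)
            concordance(cnvrs, referenceCnvrs[[lb]], lb)))
    } else "skipped (no reference catalogues)"

    report$qtl <- if (!is.null(qtl) && length(cnvrs)) {
        note("qtl_overlap")
        qtlOverlap(cnvrs, qtl)
    } else "skipped (no QTL catalogue)"

    if (!is.null(genes) && length(cnvrs)) {
        note("gene_annotation")
        report$genes <- annotateGenes(cnvrs, genes)
        report$enrichment <- if (!is.null(annotation) &&
                                 length(report$genes$genes)) {
            note("enrichment")
            termEnrichment(report$genes$genes, annotation,
                           unique(mcols(genes)$gene_id))
        } else "skipped (no annotation table)"
    } else {
        report$genes <- report$enrichment <- "skipped (no gene catalogue)"
    }

    report$provenance <- list(
        nSamplesInput = ncol(signal), nSamplesCalled = length(passing),
        nMarkers = nrow(signal), config = config,
        packageVersion = as.character(utils::packageVersion("cohortCNV")))
    .assertReportConsistency(report)
    class(report) <- "CohortCnvReport"
    report
}

# every printed percentage must equal summaryPercent(num, den)
.assertReportConsistency <- function(report) {
    s <- report$summary
    if (s$n > 0) {
        stopifnot(all(s$perChromosome$pct ==
                      summaryPercent(s$perChromosome$count, s$n)))
        stopifnot(all(s$events$pct ==
                      summaryPercent(s$events$count, s$n)))
    }
    v <- report$validation
    if (is.list(v))
        stopifnot(v$rate == summaryPercent(sum(v$confirmed),
                                           length(v$confirmed)))
    invisible(TRUE)
}

#' @export
print.CohortCnvReport <- function(x, ...) {
    cat("Cohort CNV report\n")
    cat("  stages run:", paste(x$stages, collapse = " -> "), "\n")
    cat("  samples called:", x$provenance$nSamplesCalled,
        " markers:", x$provenance$nMarkers, "\n")
    cat("  CNV calls:", length(x$calls), "  CNVRs:", x$summary$n, "\n")
    if (x$summary$n > 0) {
        ev <- x$summary$events
        cat("  events:", paste0(ev$event, " ", ev$count, " (", ev$pct,
                                "%)", collapse = ", "), "\n")
        cat("  genome coverage:", x$summary$lengthBp[["total"]], "bp (",
            x$summary$genomePct, "% )\n")
    }
    if (is.list(x$validation))
        cat("  depth-confirmed:", sum(x$validation$confirmed), "of",
            length(x$validation$confirmed), "(", x$validation$rate, "%)\n")
    invisible(x)
}
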