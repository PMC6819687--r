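#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg genotype proportions.  With the
#' allele counts fixed, every attainable heterozygote count (same parity as
#' the minor-allele count) is assigned its exact probability; the p-value is
#' the sum of probabilities no larger than that of the observed table.
#' Probabilities are accumulated through the standard recurrence in log
#' space, so large cohorts remain numerically stable.
#'
#' @param nAA,nAB,nBB Genotype counts (nonnegative integers, total >= 1).
#' @return Exact p-value in (0, 1].
#' @examples
#' hweExactTest(5, 0, 0)   # monomorphic: p = 1
#' hweExactTest(3, 1, 3)
#' @export
hweExactTest <- function(nAA, nAB, nBB) {
    if (any(c(nAA, nAB, nBB) < 0))
        stop("genotype counts must be nonnegative")
    n <- nAA + nAB + nBB
    if (n < 1) stop("at least one genotype is required")
    nA <- 2 * nAA + nAB
    nB <- 2 * nBB + nAB
    hs <- seq(nA %% 2, min(nA, nB), by = 2)
    if (length(hs) == 1L) return(1)
    logp <- numeric(length(hs))
    for (k in seq_along(hs)[-1]) {
        h <- hs[k - 1L]
        nAAh <- (nA - h) / 2
        nBBh <- (nB - h) / 2
        logp[k] <- logp[k - 1L] +
            log(4 * nAAh * nBBh) - log((h + 1) * (h + 2))
    }
    logp <- logp - max(logp)
    p <- exp(logp)
    p <- p / sum(p)
    pObs <- p[match(nAB, hs)]
    min(1, sum(p[p <= pObs * (1 + 1e-9)]))
}

#' Marker-level genotype quality control
#'
#' Removes markers failing any of: genotype call rate below
#' \code{callRateMin}, minor allele frequency below \code{mafMin}, or
#' Hardy-Weinberg exact p-value below \code{hwePMin}.  Removal counts are
#' reported both non-exclusively (a marker counts against every filter it
#' fails) and exclusively (attributed to the first failed filter in the
#' order HWE, call rate, MAF).
#'
#' @param geno Integer matrix (markers x samples) coded 0/1/2 as the B-allele
#'   dosage, \code{NA} for missing calls.
#' @param callRateMin Minimum call rate (default 0.90).
#' @param mafMin Minimum minor allele frequency (default 0.05).
#' @param hwePMin Minimum HWE exact p-value (default 1e-6; the test itself
#'   does not fix a genome-wide cutoff, this is the common convention).
#' @return A list: \code{retained} (marker names), \code{stats} (per-marker
#'   data frame with call rate, MAF, HWE p and failure flags),
#'   \code{removed} (non-exclusive per-filter counts) and
#'   \code{removedExclusive}.
#' @export
snpQc <- function(geno, callRateMin = 0.90, mafMin = 0.05, hwePMin = 1e-6) {
    if (!length(geno)) stop("empty genotype matrix")
    if (is.null(rownames(geno)))
        rownames(geno) <- paste0("m", seq_len(nrow(geno)))
    ns <- ncol(geno)
    n0 <- rowSums(geno == 0L, na.rm = TRUE)
    n1 <- rowSums(geno == 1L, na.rm = TRUE)
    n2 <- rowSums(geno == 2L, na.rm = TRUE)
    nc <- n0 + n1 + n2
    callRate <- nc / ns
    pB <- ifelse(nc > 0, (2 * n2 + n1) / (2 * nc), NA_real_)
    maf <- pmin(pB, 1 - pB)
    hweP <- rep(NA_real_, nrow(geno))
    for (i in which(nc > 0))
        hweP[i] <- hweExactTest(n0[i], n1[i], n2[i])
    failCR <- callRate < callRateMin
    failMAF <- !is.na(maf) & maf < mafMin
    failHWE <- !is.na(hweP) & hweP < hwePMin
    failAny <- failCR | failMAF | failHWE
    excl <- ifelse(failHWE, "hwe",
            ifelse(failCR, "call_rate",
            ifelse(failMAF, "maf", NA_character_)))
    stats <- data.frame(marker = rownames(geno), call_rate = callRate,
                        maf = maf, hwe_p = hweP, fail_call_rate = failCR,
                        fail_maf = failMAF, fail_hwe = failHWE,
                        row.names = NULL)
    list(retained = rownames(geno)[!failAny],
         stats = stats,
         removed = c(hwe = sum(failHWE), call_rate = sum(failCR),
                     maf = sum(failMAF)),
         removedExclusive = c(hwe = sum(excl == "hwe", na.rm = TRUE),
                              call_rate = sum(excl == "call_rate",
                                              na.rm = TRUE),
                              maf = sum(excl == "maf", na.rm = TRUE)))
}

#' Sample-level genotype missingness filter
#'
#' Removes samples whose missing genotype fraction exceeds
#' \code{maxMissing} (strictly; a sample at exactly the threshold is kept).
#'
#' @param geno Integer matrix (markers x samples), \code{NA} missing.
#' @param maxMissing Maximum tolerated missing fraction (default 0.1).
#' @return Character vector of retained sample names.
#' @export
sampleMissingnessFilter <- function(geno, maxMissing = 0.1) {
    if (is.null(colnames(geno)))
        colnames(geno) <- paste0("s", seq_len(ncol(geno)))
    missFrac <- colMeans(is.na(geno))
    colnames(geno)[missFrac <= maxMissing]
}

#' Sample-level signal quality control
#'
#' Computes, per sample: the standard deviation of non-missing autosomal LRR
#' (\code{lrr_sd}); the BAF drift, defined here as the fraction of
#' non-missing markers whose BAF falls in the off-cluster zones
#' [0.2, 0.25] or [0.75, 0.8]; and the waviness factor, the standard
#' deviation of per-1-Mb-bin median LRR, signed by the correlation of bin
#' medians with bin GC content when a GC track is supplied.  A sample passes
#' when \code{lrr_sd <= 0.3}, \code{baf_drift <= 0.02} and
#' \code{|waviness_factor| <= 0.05}; samples with fewer than
#' \code{minMarkers} informative markers are flagged unreliable and fail.
#'
#' @param signal A \linkS4class{SignalSet}.
#' @param gcTrack Optional \linkS4class{GRanges} with a numeric \code{gc}
#'   metadata column, used only to sign the waviness factor.
#' @param binSize Waviness bin width in bp (default 1e6).
#' @param minMarkers Minimum informative markers per sample (default 100).
#' @param lrrSdMax,bafDriftMax,wavinessMax Pass thresholds (defaults 0.3,
#'   0.02, 0.05).
#' @return A data frame with one row per sample: \code{sample},
#'   \code{lrr_sd}, \code{baf_drift}, \code{waviness_factor},
#'   \code{missing_rate}, \code{n_markers}, \code{reliable}, \code{pass}.
#' @export
sampleSignalQc <- function(signal, gcTrack = NULL, binSize = 1e6,
                           minMarkers = 100, lrrSdMax = 0.3,
                           bafDriftMax = 0.02, wavinessMax = 0.05) {
    map <- rowRanges(signal)
    chrom <- as.character(seqnames(map))
    binStart <- (start(map) - 1) %/% binSize * binSize + 1
    binKey <- paste0(chrom, ":", binStart)
    binGc <- NULL
    if (!is.null(gcTrack)) {
        ub <- !duplicated(binKey)
        bins <- GRanges(chrom[ub],
                        IRanges(binStart[ub], binStart[ub] + binSize - 1))
        hit <- findOverlaps(bins, gcTrack)
        gcv <- tapply(mcols(gcTrack)$gc[subjectHits(hit)], queryHits(hit),
                      mean)
        binGc <- setNames(rep(NA_real_, sum(ub)), binKey[ub])
        binGc[as.integer(names(gcv))] <- as.numeric(gcv)
    }
    L <- lrr(signal)
    B <- baf(signal)
    res <- lapply(colnames(signal), function(s) {
        x <- L[, s]
        b <- B[, s]
        inform <- sum(!is.na(x))
        lrrSd <- if (inform > 1) sd(x, na.rm = TRUE) else NA_real_
        drift <- mean((b >= 0.2 & b <= 0.25) | (b >= 0.75 & b <= 0.8),
                      na.rm = TRUE)
        med <- tapply(x, binKey, median, na.rm = TRUE)
        wf <- sd(med, na.rm = TRUE)
        if (!is.null(binGc) && !is.na(wf)) {
            g <- binGc[names(med)]
            ok <- !is.na(med) & !is.na(g)
            if (sum(ok) > 2 && sd(g[ok]) > 0 && sd(med[ok]) > 0) {
                r <- cor(med[ok], g[ok])
                if (!is.na(r) && r < 0) wf <- -wf
            }
        }
        reliable <- inform >= minMarkers
        pass <- reliable && !is.na(lrrSd) && lrrSd <= lrrSdMax &&
            !is.na(drift) && drift <= bafDriftMax &&
            !is.na(wf) && abs(wf) <= wavinessMax
        data.frame(sample = s, lrr_sd = lrrSd, baf_drift = drift,
                   waviness_factor = wf,
                   missing_rate = mean(is.na(x) | is.na(b)),
                   n_markers = inform, reliable = reliable, pass = pass)
    })
    do.call(rbind, res)
}
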