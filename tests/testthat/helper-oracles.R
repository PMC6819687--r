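# Independent oracles used to cross-check the package's optimised
# implementations on small instances.

# HWE exact test by direct closed-form probability of every attainable
# heterozygote count (log-factorial form, no recurrence).
hweOracle <- function(nAA, nAB, nBB) {
    nA <- 2 * nAA + nAB
    nB <- 2 * nBB + nAB
    n <- nAA + nAB + nBB
    hs <- seq(nA %% 2, min(nA, nB), by = 2)
    lp <- vapply(hs, function(h) {
        a <- (nA - h) / 2
        b <- (nB - h) / 2
        lfactorial(n) + lfactorial(nA) + lfactorial(nB) + h * log(2) -
            lfactorial(a) - lfactorial(h) - lfactorial(b) -
            lfactorial(2 * n)
    }, numeric(1))
    p <- exp(lp - max(lp))
    p <- p / sum(p)
    sum(p[p <= p[match(nAB, hs)] * (1 + 1e-9)])
}

# boundary trimming by naive per-base accumulation (1-based closed)
trimOracle <- function(starts, ends, q = 0.025) {
    lo <- min(starts)
    hi <- max(ends)
    bases <- lo:hi
    cov <- numeric(hi - lo + 1)
    for (i in seq_along(starts)) {
        idx <- (starts[i] - lo + 1):(ends[i] - lo + 1)
        cov[idx] <- cov[idx] + 1
    }
    M <- sum(cov)
    qm <- q * M
    cum <- cumsum(cov)
    before <- c(0, cum[-length(cum)])
    after <- M - cum
    aIdx <- which(before >= qm & cov > 0)
    bIdx <- which(after >= qm & cov > 0)
    if (!length(aIdx) || !length(bIdx) ||
        bases[min(aIdx)] > bases[max(bIdx)])
        return(c(lo, hi))
    c(bases[min(aIdx)], bases[max(bIdx)])
}

# brute-force best path over all 6^n state sequences; shares the model's
# emission/transition definitions (checked separately) but not the
# dynamic-programming recursion
exhaustivePathOracle <- function(model, lrrv, bafv, pfbv, pos) {
    E <- cohortCNV:::.emissionMatrix(model, lrrv, bafv, pfbv)
    n <- length(pos)
    scores <- log(model@initProb) + E[1, ]
    lastState <- 1:6
    if (n > 1) {
        for (t in 2:n) {
            lT <- log(transitionMatrix(model, pos[t] - pos[t - 1]))
            scores <- unlist(lapply(1:6, function(j)
                scores + lT[cbind(lastState, j)] + E[t, j]))
            lastState <- rep(1:6, each = length(scores) / 6)
        }
    }
    best <- which.max(scores)
    idx <- best - 1
    path <- integer(n)
    for (t in 1:n) {
        path[t] <- as.integer(idx %% 6 + 1)
        idx <- idx %/% 6
    }
    list(path = path, logProb = scores[best])
}

# hypergeometric upper tail by explicit combinatorial sum
hyperOracle <- function(k, K, n, N) {
    i <- k:min(K, n)
    sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# concordant length by explicit base sets
concordantLengthOracle <- function(query, reference) {
    refBases <- unique(unlist(lapply(seq_along(reference), function(i)
        paste0(as.character(GenomicRanges::seqnames(reference))[i], ":",
               GenomicRanges::start(reference)[i]:
                   GenomicRanges::end(reference)[i]))))
    sum(vapply(seq_along(query), function(i) {
        qb <- paste0(as.character(GenomicRanges::seqnames(query))[i], ":",
                     GenomicRanges::start(query)[i]:
                         GenomicRanges::end(query)[i])
        sum(qb %in% refBases)
    }, numeric(1)))
}

# Small deterministic cohort shared by several tests.  Hemizygous rather
# than homozygous deletions: on a ~1300-marker fixture the LRR outliers of a
# CN0 event make up several percent of a carrier's markers and legitimately
# inflate its LRR SD past the sample-QC gate, a density that full-size
# marker maps never reach.  CN0 calling is exercised separately.
tinyCohort <- function(seed = 11, nSamples = 6) {
    simulateCohort(simConfig(
        nSamples = nSamples,
        chromLengths = c(`1` = 2e6, `2` = 2e6),
        nEvents = 4L, nSingletonEvents = 1L,
        eventSizeMarkers = c(6L, 15L),
        cnProbs = c(`1` = 0.45, `3` = 0.35, `4` = 0.20),
        seed = seed))
}
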