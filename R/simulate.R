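#' Synthetic cohort configuration
#'
#' Bundles every parameter of the synthetic SNP-array cohort generator.
#' Defaults emulate the kind of cohort this workflow targets: 90 samples on
#' a dense autosomal map with ~3.08 kb mean marker spacing, LRR noise of
#' 0.2, tight BAF clusters, and a modest number of implanted multi-carrier
#' events plus single-carrier events that exercise singleton filtering.
#'
#' @param nSamples Cohort size (default 90).
#' @param chromLengths Named vector of chromosome lengths in bp (default two
#'   10-Mb chromosomes, the desk-scale genome used throughout the tests).
#' @param markerSpacing Mean inter-marker distance in bp (default 3080);
#'   spacings are exponential, creating realistic gaps.
#' @param lrrNoiseSd LRR noise standard deviation (default 0.2).
#' @param bafClusterSd BAF cluster standard deviation (default 0.03).
#' @param lrrShift Per-copy-number LRR means for CN 0..4.
#' @param nEvents Number of implanted multi-carrier events (default 12).
#' @param nSingletonEvents Number of single-carrier events (default 2).
#' @param eventSizeMarkers Inclusive range of event sizes in markers
#'   (default 5..30).
#' @param carrierRange Inclusive range of carriers per multi-carrier event
#'   (default 2..8).
#' @param cnProbs Sampling weights of event copy numbers 0, 1, 3, 4.
#' @param genoMissingRate Genotype missingness rate (default 0.005).
#' @param qcFail List of injected sample-level failure modes, each a list
#'   with \code{mode} ("wave", "baf_noise" or "lrr_noise"),
#'   \code{magnitude}, and \code{fail} (whether the injection is expected
#'   to trip the QC thresholds).  Applied to the last samples of the
#'   cohort, which never carry events.
#' @param wavePeriod Period of injected LRR waves in bp (default 1e7).
#' @param depthCoverage Simulated sequencing depth (default 30).
#' @param readLength Read length for depth conversion (default 150).
#' @param windowWidth Depth window width in bp (default 400).
#' @param gcMean,gcAmp,gcPeriod Smooth GC profile parameters: per-window GC
#'   is \code{gcMean + gcAmp * sin(2 pi mid / gcPeriod)}.
#' @param gcBiasSlope Linear GC bias slope on coverage (0 = no bias;
#'   default 2).
#' @param seed Mandatory random seed.
#' @return A validated configuration (class \code{SimConfig}).
#' @export
simConfig <- function(nSamples = 90L,
                      chromLengths = c(`1` = 1e7, `2` = 1e7),
                      markerSpacing = 3080,
                      lrrNoiseSd = 0.2,
                      bafClusterSd = 0.03,
                      lrrShift = c(-3.5, -0.67, 0, 0.40, 0.68),
                      nEvents = 12L,
                      nSingletonEvents = 2L,
                      eventSizeMarkers = c(5L, 30L),
                      carrierRange = c(2L, 8L),
                      cnProbs = c(`0` = 0.10, `1` = 0.40, `3` = 0.35,
                                  `4` = 0.15),
                      genoMissingRate = 0.005,
                      qcFail = list(),
                      wavePeriod = 1e7,
                      depthCoverage = 30,
                      readLength = 150,
                      windowWidth = 400L,
                      gcMean = 0.42, gcAmp = 0.08, gcPeriod = 2e6,
                      gcBiasSlope = 2,
                      seed) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    cfg <- list(nSamples = as.integer(nSamples),
                chromLengths = chromLengths,
                markerSpacing = markerSpacing, lrrNoiseSd = lrrNoiseSd,
                bafClusterSd = bafClusterSd, lrrShift = lrrShift,
                nEvents = as.integer(nEvents),
                nSingletonEvents = as.integer(nSingletonEvents),
                eventSizeMarkers = as.integer(eventSizeMarkers),
                carrierRange = as.integer(carrierRange),
                cnProbs = cnProbs, genoMissingRate = genoMissingRate,
                qcFail = qcFail, wavePeriod = wavePeriod,
                depthCoverage = depthCoverage, readLength = readLength,
                windowWidth = as.integer(windowWidth), gcMean = gcMean,
                gcAmp = gcAmp, gcPeriod = gcPeriod,
                gcBiasSlope = gcBiasSlope, seed = as.integer(seed))
    stopifnot(cfg$nSamples >= 1, all(cfg$chromLengths > 0),
              cfg$markerSpacing > 0, cfg$lrrNoiseSd > 0,
              cfg$bafClusterSd > 0, length(cfg$lrrShift) == 5,
              all(names(cfg$cnProbs) %in% c("0", "1", "3", "4")),
              cfg$eventSizeMarkers[1] >= 1,
              cfg$eventSizeMarkers[2] >= cfg$eventSizeMarkers[1])
    class(cfg) <- "SimConfig"
    cfg
}

# CN value (0..4) -> HMM state index
.cnToState <- function(cn) c(1L, 2L, 3L, 5L, 6L)[cn + 1L]

#' Simulate a SNP-array cohort with known truth
#'
#' Places markers by exponential spacing, draws per-marker B allele
#' frequencies uniformly on [0.05, 0.95] (defining the true PFB and the
#' genotypes), implants the configured CNV events in randomly chosen
#' carriers, and generates LRR (state mean + Gaussian noise) and BAF
#' (genotype cluster center + Gaussian noise, clamped to [0, 1]; uniform
#' under CN0).  Designated failure samples receive sinusoidal LRR waves,
#' uniform BAF contamination, or inflated LRR noise; they never carry
#' events.  The generator is a pure function of its configuration,
#' including the seed.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A list: \code{map} (\linkS4class{MarkerMap} with the true PFB),
#'   \code{signal} (\linkS4class{SignalSet}), \code{genotypes} (markers x
#'   samples dosage matrix), and \code{truth} -- a list with \code{events}
#'   (data frame: chrom, start, end, copy_number, n_markers, carriers),
#'   \code{expectedCnvrs} (\linkS4class{GRanges} of events with >= 2
#'   carriers, with \code{polarity}), and \code{qcFailSamples} (samples
#'   whose injected mode is expected to fail QC).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    chroms <- names(config$chromLengths)
    posL <- lapply(chroms, function(ch) {
        len <- config$chromLengths[[ch]]
        nGap <- ceiling(len / config$markerSpacing * 1.4) + 50
        gaps <- pmax(1, round(rexp(nGap, 1 / config$markerSpacing)))
        p <- cumsum(gaps)
        p[p <= len]
    })
    names(posL) <- chroms
    m <- sum(lengths(posL))
    chromV <- rep(chroms, lengths(posL))
    posV <- unlist(posL, use.names = FALSE)
    mnames <- paste0("SNP_", chromV, "_", unlist(lapply(posL, seq_along)))
    alleleFreq <- runif(m, 0.05, 0.95)
    map <- markerMap(mnames, chromV, posV, alleleFreq)
    # map construction sorts; recover alignment
    ord <- match(names(map), mnames)
    chromV <- chromV[ord]
    posV <- posV[ord]
    alleleFreq <- alleleFreq[ord]
    ns <- config$nSamples
    samples <- sprintf("S%03d", seq_len(ns))
    nFail <- length(config$qcFail)
    failSamples <- if (nFail) tail(samples, nFail) else character(0)
    eligible <- setdiff(samples, failSamples)

    # genotypes: B-allele dosage under HWE at the marker's allele frequency
    geno <- matrix(rbinom(m * ns, 2L, rep(alleleFreq, ns)), m, ns,
                   dimnames = list(names(map), samples))
    if (config$genoMissingRate > 0)
        geno[runif(m * ns) < config$genoMissingRate] <- NA

    # implant events on non-overlapping marker runs (>= 2 marker gap)
    used <- logical(m)
    nEv <- config$nEvents + config$nSingletonEvents
    events <- list()
    cnChoices <- as.integer(names(config$cnProbs))
    tries <- 0L
    while (length(events) < nEv && tries < 1000L) {
        tries <- tries + 1L
        k <- sample(seq(config$eventSizeMarkers[1],
                        config$eventSizeMarkers[2]), 1L)
        ch <- sample(chroms, 1L, prob = lengths(posL)[chroms])
        onChr <- which(chromV == ch)
        if (length(onChr) < k + 4L) next
        i0 <- sample(seq_len(length(onChr) - k + 1L), 1L)
        run <- onChr[i0:(i0 + k - 1L)]
        guard <- unique(pmin(pmax(c(min(run) - 2L, max(run) + 2L), 1L), m))
        if (any(used[c(run, guard)])) next
        used[run] <- TRUE
        used[guard] <- TRUE
        isSingleton <- length(events) >= config$nEvents
        nCar <- if (isSingleton) 1L
                else sample(seq(config$carrierRange[1],
                                min(config$carrierRange[2],
                                    length(eligible))), 1L)
        events[[length(events) + 1L]] <- list(
            chrom = ch, firstIdx = run[1L], lastIdx = run[length(run)],
            cn = sample(cnChoices, 1L, prob = config$cnProbs),
            carriers = sample(eligible, nCar))
    }

    # per-sample copy-number template, then signals
    L <- matrix(NA_real_, m, ns, dimnames = list(names(map), samples))
    B <- matrix(NA_real_, m, ns, dimnames = list(names(map), samples))
    cnBySample <- matrix(2L, m, ns)
    for (ev in events)
        for (s in ev$carriers)
            cnBySample[ev$firstIdx:ev$lastIdx, match(s, samples)] <- ev$cn
    shift <- config$lrrShift
    for (j in seq_len(ns)) {
        cnv <- cnBySample[, j]
        L[, j] <- shift[cnv + 1L] + rnorm(m, 0, config$lrrNoiseSd)
        bCount <- rbinom(m, cnv, alleleFreq)
        center <- ifelse(cnv > 0, bCount / cnv, NA_real_)
        bafv <- .clamp(center + rnorm(m, 0, config$bafClusterSd), 0, 1)
        bafv[cnv == 0] <- runif(sum(cnv == 0))
        B[, j] <- bafv
    }
    # failure-mode injections
    failFlag <- character(0)
    for (i in seq_along(config$qcFail)) {
        fs <- config$qcFail[[i]]
        j <- match(failSamples[i], samples)
        if (fs$mode == "wave") {
            L[, j] <- L[, j] + fs$magnitude *
                sin(2 * pi * posV / config$wavePeriod)
        } else if (fs$mode == "baf_noise") {
            sel <- runif(m) < fs$magnitude
            B[sel, j] <- runif(sum(sel))
        } else if (fs$mode == "lrr_noise") {
            L[, j] <- shift[3L] + rnorm(m, 0, fs$magnitude)
        } else stop("unknown qcFail mode: ", fs$mode)
        if (isTRUE(fs$fail)) failFlag <- c(failFlag, failSamples[i])
    }

    evDf <- if (length(events)) {
        do.call(rbind, lapply(events, function(ev) data.frame(
            chrom = ev$chrom, start = posV[ev$firstIdx],
            end = posV[ev$lastIdx], copy_number = ev$cn,
            n_markers = ev$lastIdx - ev$firstIdx + 1L,
            carriers = I(list(ev$carriers)))))
    } else {
        data.frame(chrom = character(0), start = integer(0),
                   end = integer(0), copy_number = integer(0),
                   n_markers = integer(0),
                   carriers = I(list()))
    }
    multi <- evDf[vapply(evDf$carriers, length, integer(1)) >= 2L, ,
                  drop = FALSE]
    expected <- if (nrow(multi) > 0) {
        gr <- GRanges(multi$chrom, IRanges(multi$start, multi$end),
                      copy_number = multi$copy_number,
                      polarity = ifelse(multi$copy_number > 2,
                                        "gain", "loss"))
        .sortNatural(gr)
    } else GRanges()
    list(map = map,
         signal = signalSet(map, L, B),
         genotypes = geno,
         truth = list(events = evDf, expectedCnvrs = expected,
                      qcFailSamples = failFlag),
         config = config)
}

# smooth deterministic GC profile over window midpoints
.gcProfile <- function(mid, config) {
    .clamp(config$gcMean +
               config$gcAmp * sin(2 * pi * mid / config$gcPeriod), 0.2, 0.7)
}

#' Simulate a read-depth window track for one genome
#'
#' Expected window counts are \code{coverage * width / readLength}, scaled
#' by half the local copy number and by a linear GC bias; realised counts
#' are Poisson.  Used both directly (one genome) and by
#' \code{\link{simulatePoolDepth}} with fractional pool-average copy
#' numbers.
#'
#' @param config A \code{\link{simConfig}} object (depth, GC and window
#'   parameters; the seed is NOT set here so pools can share one stream --
#'   call \code{set.seed} first or go through
#'   \code{\link{simulatePoolDepth}}).
#' @param cnOfWindow Function mapping (chrom, window midpoints) to the local
#'   (possibly fractional) copy number.
#' @return A \linkS4class{GRanges} of windows with metadata \code{raw},
#'   \code{gc} and \code{true_cn}.
#' @export
simulateDepthTrack <- function(config, cnOfWindow) {
    width <- config$windowWidth
    base <- config$depthCoverage * width / config$readLength
    si <- GenomeInfoDb::Seqinfo(names(config$chromLengths),
                                unname(config$chromLengths))
    out <- lapply(names(config$chromLengths), function(ch) {
        len <- config$chromLengths[[ch]]
        nwin <- ceiling(len / width)
        ws <- (seq_len(nwin) - 1L) * width + 1L
        we <- pmin(ws + width - 1L, len)
        mid <- (ws + we) / 2
        gc <- .gcProfile(mid, config)
        bias <- 1 + config$gcBiasSlope * (gc - config$gcMean)
        cn <- cnOfWindow(ch, mid)
        mu <- base * (cn / 2) * pmax(bias, 0.05)
        GRanges(ch, IRanges(ws, we), raw = rpois(nwin, mu), gc = gc,
                true_cn = cn, seqinfo = si)
    })
    do.call(c, out)
}

#' Simulate pooled-sequencing depth tracks
#'
#' Represents each DNA pool as one depth track whose local copy number is
#' the mean copy number of the pool members (a population-average signal),
#' following the pooled re-sequencing design this workflow validates
#' against.
#'
#' @param config A \code{\link{simConfig}} object.
#' @param truth Truth set from \code{\link{simulateCohort}}.
#' @param pools List of character vectors of member samples; defaults to
#'   two pools of up to 12 taken from the start of the cohort.
#' @return A list of \linkS4class{GRanges} window tracks, one per pool.
#' @export
simulatePoolDepth <- function(config, truth, pools = NULL) {
    samples <- sprintf("S%03d", seq_len(config$nSamples))
    if (is.null(pools)) {
        k <- min(12L, config$nSamples %/% 2L)
        pools <- list(samples[seq_len(k)], samples[k + seq_len(k)])
    }
    set.seed(config$seed + 1L)
    ev <- truth$events
    lapply(pools, function(members) {
        cnFun <- function(ch, mid) {
            cn <- rep(2 * length(members), length(mid))
            onCh <- which(ev$chrom == ch)
            for (i in onCh) {
                nCar <- sum(ev$carriers[[i]] %in% members)
                if (nCar == 0) next
                hit <- mid >= ev$start[i] & mid <= ev$end[i]
                cn[hit] <- cn[hit] + nCar * (ev$copy_number[i] - 2)
            }
            cn / length(members)
        }
        simulateDepthTrack(config, cnFun)
    })
}

#' Compare called CNVRs with the simulation truth
#'
#' An expected (multi-carrier) region is recovered when a called CNVR of
#' matching polarity covers at least half of it; recall is the fraction
#' recovered.  A called CNVR is a true positive when it overlaps any
#' implanted event of compatible polarity; precision is the true-positive
#' fraction.  When per-sample calls and the marker map are supplied,
#' per-event boundary errors are reported in marker units (how many map
#' positions the called segment's ends sit from the true ends).
#'
#' @param cnvrs A \linkS4class{CnvrSet} of called regions.
#' @param truth Truth set from \code{\link{simulateCohort}}.
#' @param calls Optional \linkS4class{CnvCalls} for boundary errors.
#' @param map Optional \linkS4class{MarkerMap} (required with
#'   \code{calls}).
#' @return A list: \code{recall}, \code{precision} (\code{NA} when nothing
#'   was called), \code{nExpected}, \code{nCalled}, and
#'   \code{boundaryErrorsMarkers} (integer vector over matched call ends).
#' @export
compareToTruth <- function(cnvrs, truth, calls = NULL, map = NULL) {
    expected <- truth$expectedCnvrs
    nExp <- length(expected)
    recall <- NA_real_
    if (nExp) {
        rec <- vapply(seq_len(nExp), function(i) {
            e <- expected[i]
            pol <- mcols(expected)$polarity[i]
            cand <- cnvrs[mcols(cnvrs)$event %in% c(pol, "both")]
            if (!length(cand)) return(FALSE)
            hit <- findOverlaps(e, cand)
            if (!length(hit)) return(FALSE)
            ints <- pintersect(rep(granges(e), length(hit)),
                               granges(cand)[subjectHits(hit)])
            any(width(ints) >= 0.5 * width(e))
        }, logical(1))
        recall <- mean(rec)
    }
    precision <- NA_real_
    if (length(cnvrs)) {
        ev <- truth$events
        evGr <- GRanges(ev$chrom, IRanges(ev$start, ev$end),
                        polarity = ifelse(ev$copy_number > 2,
                                          "gain", "loss"))
        hit <- findOverlaps(cnvrs, evGr)
        okPol <- mcols(cnvrs)$event[queryHits(hit)] == "both" |
            mcols(cnvrs)$event[queryHits(hit)] ==
                mcols(evGr)$polarity[subjectHits(hit)]
        tp <- unique(queryHits(hit)[okPol])
        precision <- length(tp) / length(cnvrs)
    }
    boundary <- integer(0)
    if (!is.null(calls) && !is.null(map) && length(calls)) {
        key <- paste0(as.character(seqnames(map)), ":", start(map))
        idxOf <- function(chrom, pos) match(paste0(chrom, ":", pos), key)
        ev <- truth$events
        for (i in seq_len(nrow(ev))) {
            if (length(ev$carriers[[i]]) < 2L) next
            pol <- if (ev$copy_number[i] > 2) "gain" else "loss"
            iTrueS <- idxOf(ev$chrom[i], ev$start[i])
            iTrueE <- idxOf(ev$chrom[i], ev$end[i])
            for (s in ev$carriers[[i]]) {
                cs <- calls[mcols(calls)$sample == s &
                    (mcols(calls)$copy_number > 2) == (pol == "gain")]
                if (!length(cs)) next
                hit <- findOverlaps(GRanges(ev$chrom[i],
                    IRanges(ev$start[i], ev$end[i])), cs)
                if (!length(hit)) next
                best <- subjectHits(hit)[1L]
                iCallS <- idxOf(ev$chrom[i], start(cs)[best])
                iCallE <- idxOf(ev$chrom[i], end(cs)[best])
                if (!is.na(iCallS) && !is.na(iTrueS))
                    boundary <- c(boundary, abs(iCallS - iTrueS))
                if (!is.na(iCallE) && !is.na(iTrueE))
                    boundary <- c(boundary, abs(iCallE - iTrueE))
            }
        }
    }
    list(recall = recall, precision = precision, nExpected = nExp,
         nCalled = length(cnvrs), boundaryErrorsMarkers = boundary)
}
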