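# BAF genotype-cluster centers per state; weights depend on PFB p.
# CN0 has no clusters (uniform BAF), handled separately.
.bafClusters <- function(stateIdx, p) {
    switch(stateIdx,
        NULL,                                              # CN0
        list(centers = c(0, 1), w = cbind(1 - p, p)),      # CN1
        list(centers = c(0, 0.5, 1),                       # CN2
             w = cbind((1 - p)^2, 2 * p * (1 - p), p^2)),
        list(centers = c(0, 1), w = cbind(1 - p, p)),      # CN2-LOH
        list(centers = c(0, 1/3, 2/3, 1),                  # CN3
             w = matrix(vapply(0:3, function(k) dbinom(k, 3, p),
                               numeric(length(p))), nrow = length(p))),
        list(centers = c(0, 0.25, 0.5, 0.75, 1),           # CN4
             w = matrix(vapply(0:4, function(k) dbinom(k, 4, p),
                               numeric(length(p))), nrow = length(p))))
}

# density of a Gaussian truncated to [0, 1]
.dtrunc01 <- function(x, mu, sd) {
    dnorm(x, mu, sd) / (pnorm(1, mu, sd) - pnorm(0, mu, sd))
}

# markers x 6 matrix of per-state emission log-likelihoods
.emissionMatrix <- function(model, lrrv, bafv, pfbv) {
    m <- length(lrrv)
    E <- matrix(0, m, 6L)
    p <- matrix(pfbv, ncol = 1)  # ensure vector ops below recycle safely
    hasL <- !is.na(lrrv)
    hasB <- !is.na(bafv)
    for (s in 1:6) {
        lt <- numeric(m)
        lt[hasL] <- dnorm(lrrv[hasL], model@lrrMean[s], model@lrrSd[s],
                          log = TRUE)
        bt <- numeric(m)
        if (any(hasB)) {
            if (s == 1L) {
                dens <- rep(1, sum(hasB))  # uniform BAF under CN0
            } else {
                cl <- .bafClusters(s, pfbv[hasB])
                dens <- rep(0, sum(hasB))
                for (k in seq_along(cl$centers))
                    dens <- dens + cl$w[, k] *
                        .dtrunc01(bafv[hasB], cl$centers[k],
                                  model@bafClusterSd)
            }
            w <- model@bafOutlierWeight
            bt[hasB] <- log((1 - w) * dens + w)
        }
        E[, s] <- lt + bt
    }
    E
}

#' Per-state BAF/LRR emission log-likelihood
#'
#' The emission density of one marker is the product of a state-specific
#' Gaussian on LRR and a PFB-weighted mixture of boundary-truncated Gaussian
#' BAF genotype clusters (uniform under CN0), plus a uniform outlier
#' component.  Missing LRR or BAF contributes zero to the log-likelihood, so
#' markers with no signal are effectively skipped.
#'
#' @param model An \linkS4class{HmmModel}.
#' @param state State name (one of \code{"CN0"}, \code{"CN1"}, \code{"CN2"},
#'   \code{"CN2-LOH"}, \code{"CN3"}, \code{"CN4"}) or index 1..6.
#' @param lrr,baf Numeric vectors (possibly \code{NA}).
#' @param pfb Population B allele frequencies in [0.01, 0.99].
#' @return Numeric vector of log-densities.
#' @export
emissionLoglik <- function(model, state, lrr, baf, pfb) {
    sIdx <- if (is.character(state)) match(state, HMM_STATES)
            else as.integer(state)
    if (is.na(sIdx) || sIdx < 1L || sIdx > 6L) stop("unknown state")
    .emissionMatrix(model, lrr, baf, pfb)[, sIdx]
}

#' Distance-dependent transition matrix
#'
#' The self-transition probability after an inter-marker gap of \code{d} bp
#' is \code{1 - (1 - stayProb) * (1 - exp(-d / D))}: markers at zero distance
#' cannot switch state, and the switch probability saturates at
#' \code{1 - stayProb} for distant markers.  Off-diagonal mass is split among
#' the other states proportionally to the model's fixed base weights, which
#' favour returning to CN2.
#'
#' @param model An \linkS4class{HmmModel}.
#' @param d Inter-marker distance in bp (scalar, >= 0).
#' @return A 6x6 row-stochastic matrix.
#' @export
transitionMatrix <- function(model, d) {
    stopifnot(d >= 0)
    f <- 1 - exp(-d / model@decayLength)
    P <- matrix(0, 6L, 6L, dimnames = list(HMM_STATES, HMM_STATES))
    for (i in 1:6) {
        diagI <- 1 - (1 - model@stayProb[i]) * f
        off <- 1 - diagI
        w <- model@baseWeights
        w[i] <- 0
        P[i, ] <- off * w / sum(w)
        P[i, i] <- diagI
    }
    P
}

#' Viterbi decoding of one chromosome's signal track
#'
#' Finds the most probable state path through the six-state model given
#' aligned LRR, BAF, PFB and position vectors, in log-domain arithmetic.
#' The initial distribution strongly favours CN2; ties are broken toward the
#' lower state index.
#'
#' @param model An \linkS4class{HmmModel}.
#' @param lrr,baf Numeric signal vectors (NA = missing).
#' @param pfb PFB vector.
#' @param pos Integer marker positions (strictly increasing).
#' @return A list: \code{path} (integer state indices 1..6), \code{states}
#'   (state names) and \code{logProb} (joint log-probability of the path).
#' @export
viterbiDecode <- function(model, lrr, baf, pfb, pos) {
    n <- length(pos)
    if (n == 0L)
        return(list(path = integer(0), states = character(0),
                    logProb = -Inf))
    stopifnot(length(lrr) == n, length(baf) == n, length(pfb) == n)
    E <- .emissionMatrix(model, lrr, baf, pfb)
    delta <- log(model@initProb) + E[1L, ]
    psi <- matrix(0L, n, 6L)
    if (n > 1L) {
        for (t in 2:n) {
            lT <- log(transitionMatrix(model, pos[t] - pos[t - 1L]))
            cand <- delta + lT   # cand[i, j] = delta[i] + log P(i -> j)
            best <- max.col(t(cand), ties.method = "first")
            psi[t, ] <- best
            delta <- cand[cbind(best, 1:6)] + E[t, ]
        }
    }
    path <- integer(n)
    path[n] <- which.max(delta)
    if (n > 1L)
        for (t in (n - 1L):1L)
            path[t] <- psi[t + 1L, path[t + 1L]]
    list(path = path, states = HMM_STATES[path], logProb = max(delta))
}

#' Call CNVs for cohort samples
#'
#' Runs the Viterbi decoder per sample and chromosome, then turns maximal
#' runs of a single non-diploid state into calls.  Runs shorter than
#' \code{minSnps(model)} markers are dropped, and copy-neutral LOH runs are
#' never reported (only losses and gains are CNVs).  Each call's confidence
#' is the summed per-marker emission log-likelihood advantage of the called
#' state over CN2.
#'
#' @param signal A \linkS4class{SignalSet} whose markers carry PFB values.
#' @param model An \linkS4class{HmmModel}.
#' @param samples Samples to call (default: all columns).
#' @return A \linkS4class{CnvCalls} object, sorted, with calls spanning the
#'   first through last marker of each run.
#' @examples
#' \donttest{
#' sim <- simulateCohort(simConfig(nSamples = 4, seed = 1))
#' calls <- callCnvs(sim$signal, hmmModel())
#' }
#' @export
callCnvs <- function(signal, model = hmmModel(),
                     samples = colnames(signal)) {
    stopifnot(is(signal, "SignalSet"), all(samples %in% colnames(signal)))
    map <- rowRanges(signal)
    chrom <- as.character(seqnames(map))
    pfbv <- .clamp(mcols(map)$pfb, 0.01, 0.99)
    L <- lrr(signal)
    B <- baf(signal)
    out <- list()
    for (s in samples) {
        for (ch in unique(chrom)) {
            idx <- which(chrom == ch)
            vit <- viterbiDecode(model, L[idx, s], B[idx, s], pfbv[idx],
                                 start(map)[idx])
            if (!length(vit$path)) next
            E <- .emissionMatrix(model, L[idx, s], B[idx, s], pfbv[idx])
            r <- rle(vit$path)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in seq_along(r$values)) {
                st <- r$values[k]
                if (st == CN2_STATE || st == 4L) next  # diploid or LOH
                if (r$lengths[k] < model@minSnps) next
                mi <- idx[starts[k]:ends[k]]
                conf <- sum(E[starts[k]:ends[k], st] -
                            E[starts[k]:ends[k], CN2_STATE])
                out[[length(out) + 1L]] <- data.frame(
                    chrom = ch, start = start(map)[mi[1L]],
                    end = start(map)[mi[length(mi)]], sample = s,
                    state = HMM_STATES[st],
                    copy_number = HMM_COPY_NUMBER[st],
                    num_snps = length(mi), confidence = conf)
            }
        }
    }
    if (!length(out)) {
        gr <- GRanges()
        mcols(gr) <- DataFrame(sample = character(0), state = character(0),
                               copy_number = integer(0),
                               num_snps = integer(0),
                               confidence = numeric(0))
        return(new("CnvCalls", gr))
    }
    df <- do.call(rbind, out)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end), sample = df$sample,
                  state = df$state, copy_number = as.integer(df$copy_number),
                  num_snps = as.integer(df$num_snps),
                  confidence = df$confidence)
    new("CnvCalls", .sortNatural(gr))
}

#' Export calls as PennCNV-style text lines
#'
#' One line per call: \code{chr:start-end  numsnp=N  length=L
#' state,cn=C  sample  conf=X}, in 1-based inclusive coordinates.
#'
#' @param calls A \linkS4class{CnvCalls} object.
#' @param path Optional file to write to.
#' @return Character vector of formatted lines (invisibly when writing).
#' @export
formatCalls <- function(calls, path = NULL) {
    mc <- mcols(calls)
    lines <- sprintf("%s:%d-%d\tnumsnp=%d\tlength=%d\t%s,cn=%d\t%s\tconf=%.3f",
                     as.character(seqnames(calls)), start(calls), end(calls),
                     mc$num_snps, width(calls), mc$state, mc$copy_number,
                     mc$sample, mc$confidence)
    if (!is.null(path)) {
        writeLines(lines, path)
        return(invisible(lines))
    }
    lines
}
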