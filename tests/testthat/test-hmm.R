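test_that("transition matrix is identity at d = 0 and stochastic everywhere", {
    m <- hmmModel()
    expect_equal(transitionMatrix(m, 0), diag(6),
                 ignore_attr = TRUE, tolerance = 1e-12)
    set.seed(1)
    for (d in c(runif(20, 1, 1e7), 1e9)) {
        P <- transitionMatrix(m, d)
        expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-12)
        expect_true(all(P >= 0))
    }
    # long-distance limit: diagonal converges to stayProb
    expect_equal(unname(diag(transitionMatrix(m, 1e9))), m@stayProb,
                 tolerance = 1e-9)
})

test_that("emission model ranks states as the signal dictates", {
    m <- hmmModel()
    # heterozygous BAF at 0.5 supports CN2 over copy-neutral LOH
    expect_gt(emissionLoglik(m, "CN2", 0, 0.5, 0.5),
              emissionLoglik(m, "CN2-LOH", 0, 0.5, 0.5))
    # three-copy signal (LRR at CN3 mean, BAF at 1/3) maximal for CN3
    e <- vapply(1:6, function(s) emissionLoglik(m, s, 0.40, 1/3, 0.5),
                numeric(1))
    expect_identical(which.max(e), 5L)
    # missing BAF leaves the LRR Gaussian term alone
    expect_equal(emissionLoglik(m, "CN2", 0.1, NA, 0.5),
                 dnorm(0.1, 0, m@lrrSd[3], log = TRUE))
    # fully missing marker emits log-probability 0 in every state
    expect_equal(vapply(1:6, function(s)
        emissionLoglik(m, s, NA, NA, 0.5), numeric(1)), rep(0, 6))
})

test_that("Viterbi matches the exhaustive-path oracle on small instances", {
    m <- hmmModel()
    set.seed(123)
    for (rep in 1:15) {
        n <- sample(2:6, 1)
        pos <- sort(sample(1:5e5, n))
        cn <- sample(c(1L, 2L, 3L), n, replace = TRUE)
        lrrv <- m@lrrMean[c(2L, 3L, 5L)[cn]] + rnorm(n, 0, 0.25)
        bafv <- runif(n)
        pfbv <- runif(n, 0.05, 0.95)
        vit <- viterbiDecode(m, lrrv, bafv, pfbv, pos)
        ora <- exhaustivePathOracle(m, lrrv, bafv, pfbv, pos)
        expect_equal(vit$logProb, ora$logProb, tolerance = 1e-9)
        expect_identical(vit$path, ora$path)
    }
})

test_that("diploid signal yields an all-CN2 path and no calls", {
    m <- hmmModel()
    set.seed(21)
    n <- 200
    pos <- sort(sample(1:6e5, n))
    pfbv <- runif(n, 0.2, 0.8)
    geno <- rbinom(n, 2, pfbv)
    lrrv <- rnorm(n, 0, 0.15)
    bafv <- pmin(pmax(geno / 2 + rnorm(n, 0, 0.03), 0), 1)
    vit <- viterbiDecode(m, lrrv, bafv, pfbv, pos)
    expect_true(all(vit$states == "CN2"))
    expect_identical(viterbiDecode(m, numeric(0), numeric(0), numeric(0),
                                   integer(0))$path, integer(0))
})

test_that("an implanted deletion block is recovered as a CN1 run", {
    m <- hmmModel()
    set.seed(31)
    n <- 60
    pos <- seq(5000L, by = 3000L, length.out = n)
    pfbv <- runif(n, 0.2, 0.8)
    geno <- rbinom(n, 2, pfbv)
    lrrv <- rnorm(n, 0, 0.2)
    bafv <- pmin(pmax(geno / 2 + rnorm(n, 0, 0.03), 0), 1)
    del <- 25:34
    lrrv[del] <- rnorm(10, m@lrrMean[2], 0.2)
    bafv[del] <- pmin(pmax(rbinom(10, 1, pfbv[del]) +
                           rnorm(10, 0, 0.03), 0), 1)
    vit <- viterbiDecode(m, lrrv, bafv, pfbv, pos)
    expect_true(all(vit$states[del] == "CN1"))
})

test_that("call extraction enforces the three-SNP rule and run boundaries", {
    m <- hmmModel()
    map <- markerMap(paste0("m", 1:30), rep("1", 30),
                     seq(10000L, by = 10000L, length.out = 30))
    pfb(map) <- rep(0.5, 30)
    set.seed(41)
    mkSignal <- function(states) {
        cn <- c(0L, 1L, 2L, 2L, 3L, 4L)[states]
        lrrv <- m@lrrMean[states] + rnorm(30, 0, 0.05)
        bafv <- ifelse(cn == 0, runif(30),
                       pmin(pmax(rbinom(30, cn, 0.5) / pmax(cn, 1) +
                                 rnorm(30, 0, 0.02), 0), 1))
        list(l = matrix(lrrv, 30, 1, dimnames = list(names(map), "s1")),
             b = matrix(bafv, 30, 1, dimnames = list(names(map), "s1")))
    }
    # 5-marker CN1 run at markers 10..14
    st <- rep(3L, 30); st[10:14] <- 2L
    sg <- mkSignal(st)
    calls <- callCnvs(signalSet(map, sg$l, sg$b), m)
    expect_identical(length(calls), 1L)
    expect_identical(start(calls), 100000L)
    expect_identical(end(calls), 140000L)
    expect_identical(mcols(calls)$num_snps, 5L)
    expect_identical(mcols(calls)$copy_number, 1L)
    expect_gt(mcols(calls)$confidence, 0)
    # 2-marker CN3 run is dropped by the minimum-SNP rule
    st2 <- rep(3L, 30); st2[20:21] <- 5L
    sg2 <- mkSignal(st2)
    expect_identical(length(callCnvs(signalSet(map, sg2$l, sg2$b), m)), 0L)
})

test_that("two implanted events give exactly two polarity-correct calls", {
    cfg <- simConfig(nSamples = 1L, chromLengths = c(`1` = 1e6),
                     nEvents = 0L, nSingletonEvents = 0L, seed = 5)
    sim <- simulateCohort(cfg)
    m <- hmmModel()
    n <- length(sim$map)
    L <- lrr(sim$signal)
    B <- baf(sim$signal)
    set.seed(6)
    i1 <- 40:45                           # CN1 x 6 markers
    i2 <- 120:127                         # CN3 x 8 markers
    af <- unname(pfb(sim$map))
    L[i1, 1] <- rnorm(6, m@lrrMean[2], 0.2)
    B[i1, 1] <- pmin(pmax(rbinom(6, 1, af[i1]) + rnorm(6, 0, 0.03), 0), 1)
    L[i2, 1] <- rnorm(8, m@lrrMean[5], 0.2)
    B[i2, 1] <- pmin(pmax(rbinom(8, 3, af[i2]) / 3 +
                          rnorm(8, 0, 0.03), 0), 1)
    calls <- callCnvs(signalSet(sim$map, L, B), m)
    expect_identical(length(calls), 2L)
    expect_identical(sort(mcols(calls)$copy_number), c(1L, 3L))
})

test_that("calls within a sample are ordered and non-overlapping", {
    sim <- tinyCohort(seed = 13)
    calls <- callCnvs(sim$signal, hmmModel())
    for (s in unique(mcols(calls)$sample)) {
        cs <- calls[mcols(calls)$sample == s]
        if (length(cs) < 2) next
        for (ch in unique(as.character(seqnames(cs)))) {
            cc <- cs[seqnames(cs) == ch]
            if (length(cc) < 2) next
            expect_true(all(start(cc)[-1] > end(cc)[-length(cc)]))
        }
    }
    expect_true(all(mcols(calls)$confidence > 0))
    expect_true(all(mcols(calls)$num_snps >= 3L))
})
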