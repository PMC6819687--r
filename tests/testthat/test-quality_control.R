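test_that("HWE exact test handles degenerate, derived and symmetric cases", {
    expect_identical(hweExactTest(5, 0, 0), 1)
    # full-enumeration oracle value for (3,1,3): hets {1,3,5,7}
    expect_equal(hweExactTest(3, 1, 3), 0.1188811189, tolerance = 1e-9)
    expect_equal(hweExactTest(2, 4, 8), hweExactTest(8, 4, 2),
                 tolerance = 1e-12)
    expect_error(hweExactTest(-1, 0, 2), "nonnegative")
    expect_error(hweExactTest(0, 0, 0), "at least one")
})

test_that("HWE exact test agrees with the closed-form oracle", {
    set.seed(5)
    for (rep in 1:200) {
        n <- sample(1:50, 1)
        nAB <- sample(0:n, 1)
        nAA <- if (n > nAB) sample(0:(n - nAB), 1) else 0L
        nBB <- n - nAB - nAA
        expect_equal(hweExactTest(nAA, nAB, nBB),
                     hweOracle(nAA, nAB, nBB), tolerance = 1e-9)
    }
})

test_that("marker QC removes by call rate, MAF and HWE and is idempotent", {
    set.seed(42)
    ns <- 40
    p <- 0.4
    good <- t(replicate(20, rbinom(ns, 2, p)))
    mono <- matrix(0L, 1, ns)                       # MAF 0
    lowcr <- matrix(rbinom(ns, 2, p), 1, ns)
    lowcr[1, 1:6] <- NA                             # 15% missing
    # gross heterozygote excess: all AB
    hweBad <- matrix(1L, 1, ns)
    g <- rbind(good, mono, lowcr, hweBad)
    rownames(g) <- paste0("m", seq_len(nrow(g)))
    res <- snpQc(g, hwePMin = 1e-4)
    expect_true(!"m21" %in% res$retained)   # monomorphic
    expect_true(!"m22" %in% res$retained)   # call rate 0.85
    expect_true(!"m23" %in% res$retained)   # HWE
    expect_true(res$stats$fail_maf[21])
    expect_true(res$stats$fail_call_rate[22])
    expect_true(res$stats$fail_hwe[23])
    # idempotence: re-filtering retained markers removes nothing
    res2 <- snpQc(g[res$retained, , drop = FALSE], hwePMin = 1e-4)
    expect_identical(res2$retained, res$retained)
})

test_that("marker at exact Hardy-Weinberg expectation is retained", {
    # counts 4/12/9 give allele freq 0.4/0.6 with AB at the modal value
    ns <- 25
    g <- matrix(rep(c(0L, 1L, 2L), c(4, 12, 9)), 1, ns)
    rownames(g) <- "hw"
    expect_true(hweExactTest(4, 12, 9) > 0.5)
    expect_identical(snpQc(g, hwePMin = 0.5)$retained, "hw")
})

test_that("sample missingness filter uses a strict threshold", {
    g <- matrix(0L, 100, 3, dimnames = list(NULL, c("a", "b", "c")))
    g[1:11, "a"] <- NA   # 11% -> removed
    g[1:10, "b"] <- NA   # exactly 10% -> retained
    expect_identical(sampleMissingnessFilter(g), c("b", "c"))
    expect_identical(sampleMissingnessFilter(matrix(0L, 10, 2,
        dimnames = list(NULL, c("x", "y")))), c("x", "y"))
})

test_that("clean signal passes and injected failure modes fail", {
    set.seed(9)
    m <- 4000
    pos <- sort(sample(1:2e7, m))
    map <- markerMap(paste0("m", 1:m), rep("1", m), pos)
    centers <- sample(c(0, 0.5, 1), m, replace = TRUE)
    clean_l <- rnorm(m, 0, 0.1)
    clean_b <- pmin(pmax(centers + rnorm(m, 0, 0.02), 0), 1)
    wavy_l <- clean_l + 0.2 * sin(2 * pi * pos / 1e7)
    unif_b <- runif(m)
    L <- cbind(clean = clean_l, wavy = clean_l, drift = clean_l)
    B <- cbind(clean = clean_b, wavy = clean_b, drift = unif_b)
    rownames(L) <- rownames(B) <- names(map)
    qc <- sampleSignalQc(signalSet(map, L + cbind(0, wavy_l - clean_l, 0),
                                   B))
    expect_identical(qc$pass, c(TRUE, FALSE, FALSE))
    # sinusoid of amplitude 0.2: bin-median SD near 0.2/sqrt(2)
    expect_gt(abs(qc$waviness_factor[2]), 0.05)
    # uniform BAF: off-cluster zones have measure 0.10
    expect_equal(qc$baf_drift[3], 0.10, tolerance = 0.02)
    expect_gt(qc$baf_drift[3], 0.02)
})

test_that("waviness factor is signed by GC correlation when a track is given", {
    set.seed(10)
    m <- 2000
    pos <- sort(sample(1:1e7, m))
    map <- markerMap(paste0("m", 1:m), rep("1", m), pos)
    wave <- 0.2 * sin(2 * pi * pos / 1e7)
    L <- matrix(wave + rnorm(m, 0, 0.05), m, 1,
                dimnames = list(names(map), "s1"))
    B <- matrix(pmin(pmax(sample(c(0, 0.5, 1), m, TRUE) +
                          rnorm(m, 0, 0.02), 0), 1), m, 1,
                dimnames = list(names(map), "s1"))
    bins <- GRanges("1", IRanges(seq(1, 1e7, by = 1e6), width = 1e6))
    gcUp <- bins; mcols(gcUp)$gc <- 0.4 +
        0.1 * sin(2 * pi * (start(bins) + 5e5) / 1e7)
    gcDown <- bins; mcols(gcDown)$gc <- 0.4 -
        0.1 * sin(2 * pi * (start(bins) + 5e5) / 1e7)
    sig <- signalSet(map, L, B)
    wPos <- sampleSignalQc(sig, gcTrack = gcUp)$waviness_factor
    wNeg <- sampleSignalQc(sig, gcTrack = gcDown)$waviness_factor
    expect_gt(wPos, 0.05)
    expect_lt(wNeg, -0.05)
    expect_equal(abs(wPos), abs(wNeg))
})

test_that("samples with too few informative markers are unreliable", {
    map <- markerMap(paste0("m", 1:120), rep("1", 120),
                     seq(1000L, by = 1000L, length.out = 120))
    L <- matrix(NA_real_, 120, 1, dimnames = list(names(map), "s1"))
    L[1:50, 1] <- rnorm(50, 0, 0.1)
    B <- matrix(0.5, 120, 1, dimnames = list(names(map), "s1"))
    qc <- sampleSignalQc(signalSet(map, L, B))
    expect_false(qc$reliable)
    expect_false(qc$pass)
})
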