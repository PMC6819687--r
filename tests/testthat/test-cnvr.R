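mkCalls <- function(chrom, start, end, sample, cn = 3L) {
    n <- length(start)
    gr <- GRanges(rep(chrom, length.out = n), IRanges(start, end),
                  sample = sample,
                  state = ifelse(rep(cn, length.out = n) > 2, "CN3", "CN1"),
                  copy_number = as.integer(rep(cn, length.out = n)),
                  num_snps = 5L, confidence = 10)
    new("CnvCalls", gr)
}

test_that("overlapping calls merge transitively; abutting calls do not", {
    # [100,200] and [150,250] overlap -> one cluster spanning the union
    cl <- mergeCalls(mkCalls("1", c(100, 150), c(200, 250), c("A", "B")))
    expect_identical(length(cl$regions), 1L)
    expect_identical(start(cl$regions), 100L)
    expect_identical(end(cl$regions), 250L)
    # closed [100,200] and [201,300] are abutting half-open intervals
    cl2 <- mergeCalls(mkCalls("1", c(100, 201), c(200, 300), c("A", "B")))
    expect_identical(length(cl2$regions), 2L)
    # chain A-B, B-C with A,C disjoint -> one cluster
    cl3 <- mergeCalls(mkCalls("1", c(100, 180, 260), c(200, 280, 360),
                              c("A", "B", "C")))
    expect_identical(length(cl3$regions), 1L)
    expect_identical(unique(cl3$membership), 1L)
})

test_that("boundary trimming matches the derived per-base profiles", {
    # two identical calls: uniform coverage, 2.5% shaved per side
    expect_identical(trimBoundaries(c(1001, 1001), c(2000, 2000)),
                     c(1026L, 1975L))
    # staggered pair: coverage 1/2/1 over three 50-bp segments
    expect_identical(trimBoundaries(c(1, 51), c(100, 150)), c(6L, 145L))
    # single call: closed form s + ceil(qL), e - ceil(qL)
    expect_identical(trimBoundaries(5001, 9000), c(5101L, 8900L))
})

test_that("sweep-based trimming equals the per-base oracle", {
    set.seed(77)
    for (rep in 1:60) {
        k <- sample(1:6, 1)
        s <- sample(1:5e4, k, replace = TRUE)
        e <- s + sample(50:2e4, k, replace = TRUE)
        # connected extent not required by the function contract
        expect_identical(trimBoundaries(s, e), trimOracle(s, e),
                         info = paste(s, e, collapse = ";"))
    }
})

test_that("trimming never inverts and stays inside the raw extent", {
    set.seed(78)
    for (rep in 1:50) {
        k <- sample(1:5, 1)
        s <- sample(1:1e5, k, replace = TRUE)
        e <- s + sample(100:5e4, k, replace = TRUE)
        tr <- trimBoundaries(s, e)
        expect_lt(tr[1], tr[2])
        expect_gte(tr[1], min(s))
        expect_lte(tr[2], max(e))
    }
})

test_that("event classification follows supporting copy numbers", {
    expect_identical(classifyEvent(c(3, 3, 4)), "gain")
    expect_identical(classifyEvent(c(1, 0)), "loss")
    expect_identical(classifyEvent(c(1, 3)), "both")
})

test_that("singleton clusters are removed, including same-sample pairs", {
    calls <- mkCalls("1",
        c(1000, 1500, 50000, 90000, 90500),
        c(2000, 2500, 60000, 91000, 91500),
        c("A", "B", "A", "A", "A"))
    cnvrs <- buildCnvrs(calls)
    # cluster 2 is one sample; cluster 3 is two calls from the same sample
    expect_identical(length(cnvrs), 1L)
    expect_identical(mcols(cnvrs)$n_individuals, 2L)
    # filterSingletons on a built set is a no-op here
    expect_identical(length(filterSingletons(cnvrs)), 1L)
})

test_that("CNVR ids follow genome order and results ignore input order", {
    calls <- mkCalls(c("2", "1", "1", "2", "1", "1"),
                     c(5000, 9000, 9100, 5100, 100, 150),
                     c(6000, 9900, 9950, 6100, 600, 650),
                     c("A", "A", "B", "B", "A", "B"),
                     cn = c(3L, 1L, 1L, 3L, 3L, 3L))
    c1 <- buildCnvrs(calls)
    set.seed(3)
    c2 <- buildCnvrs(calls[sample(length(calls))])
    expect_identical(mcols(c1)$cnvr_id, paste0("CNVR", 1:3))
    expect_identical(as.character(seqnames(c1)), c("1", "1", "2"))
    expect_identical(start(c1), start(c2))
    expect_identical(mcols(c1)$event, mcols(c2)$event)
    expect_identical(mcols(c1)$event, c("gain", "loss", "gain"))
})

test_that("CNVR summary reproduces the reference-cohort arithmetic", {
    # the printed worked example: 166 CNVRs, 111/46/9 gain/loss/both
    expect_equal(summaryPercent(c(111, 46, 9), 166),
                 c(66.87, 27.71, 5.42))
    expect_equal(summaryPercent(3871, 90, mean = TRUE), 43.01)
    s <- summarizeCnvrs(
        buildCnvrs(mkCalls("1", c(1000, 1500), c(11000, 11500),
                           c("A", "B"))),
        chromLengths = c(`1` = 2e6), nSamples = 2, nCnvCalls = 2)
    expect_identical(s$n, 1L)
    expect_equal(s$events$count, c(1L, 0L, 0L))
    expect_equal(s$events$pct, c(100, 0, 0))
    expect_equal(s$meanCnvsPerIndividual, 1)
    expect_error(summarizeCnvrs(buildCnvrs(mkCalls("7", c(1, 100),
        c(1000, 1100), c("A", "B"))), chromLengths = c(`1` = 2e6)), "7")
})

test_that("empty CNVR sets summarise to zeros with absent means", {
    calls <- mkCalls("1", 100, 200, "A")[0]
    s <- summarizeCnvrs(buildCnvrs(calls), chromLengths = c(`1` = 1e6))
    expect_identical(s$n, 0L)
    expect_true(is.na(s$meanCnvrsPerIndividual))
    expect_identical(s$lengthBp[["total"]], 0)
})
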