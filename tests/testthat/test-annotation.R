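mkCnvrs <- function(chrom, start, end, event = "gain") {
    n <- length(start)
    gr <- GRanges(rep(chrom, length.out = n), IRanges(start, end),
                  cnvr_id = paste0("CNVR", seq_len(n)),
                  event = rep(event, length.out = n),
                  n_individuals = 2L, n_calls = 2L,
                  raw_start = as.integer(start), raw_end = as.integer(end))
    new("CnvrSet", gr)
}

test_that("concordance counts overlaps and merged intersection length", {
    q <- mkCnvrs("1", 100, 200)
    r <- GRanges("1", IRanges(150, 250))
    cc <- concordance(q, r, "ref")
    expect_identical(cc$n_overlapping, 1L)
    expect_identical(cc$concordant_length, 51)   # closed [150,200]
    # reference covering the query entirely -> 100% length
    cc2 <- concordance(q, GRanges("1", IRanges(1, 1000)))
    expect_equal(cc2$pct_length, 100)
    # the printed worked example: 61 of 166 CNVRs, 1.48 of 15.55 Mb
    expect_equal(summaryPercent(61, 166), 36.75)
    expect_equal(summaryPercent(1.48, 15.55), 9.52)
    expect_error(concordance(mkCnvrs("1", 1, 2)[0], r), "empty")
})

test_that("concordance is monotone in the reference set", {
    set.seed(15)
    q <- mkCnvrs("1", seq(1000, 90000, by = 10000),
                 seq(1000, 90000, by = 10000) + 3000)
    refA <- GRanges("1", IRanges(sample(1:9e4, 5), width = 2000))
    refB <- c(refA, GRanges("1", IRanges(sample(1:9e4, 5), width = 2000)))
    ca <- concordance(q, refA)
    cb <- concordance(q, refB)
    expect_gte(cb$n_overlapping, ca$n_overlapping)
    expect_gte(cb$concordant_length, ca$concordant_length)
})

test_that("concordant length matches the base-set oracle", {
    set.seed(16)
    for (rep in 1:10) {
        q <- mkCnvrs("1", s <- sample(1:5e4, 6), s + sample(100:3000, 6))
        r <- GRanges("1", IRanges(sample(1:5e4, 8),
                                  width = sample(100:3000, 8)))
        expect_equal(concordance(q, r)$concordant_length,
                     concordantLengthOracle(q, r))
    }
})

test_that("QTL overlap counts CNVRs, QTLs and traits distinctly", {
    cn <- mkCnvrs("1", c(1000, 50000), c(2000, 60000))
    qtl <- GRanges("1", IRanges(c(500, 1500, 1800, 90000),
                                c(1200, 2500, 5000, 95000)),
                   qtl_id = paste0("Q", 1:4),
                   trait = c("growth", "growth", "meat", "litter"))
    ov <- qtlOverlap(cn, qtl)
    expect_identical(ov$n_cnvrs_overlapping, 1L)
    expect_identical(ov$n_qtls, 3L)
    expect_identical(ov$n_traits, 2L)
    expect_identical(sort(ov$perCnvr$CNVR1), c("Q1", "Q2", "Q3"))
    # no QTLs -> zeros
    ov0 <- qtlOverlap(cn, qtl[0])
    expect_identical(ov0$n_cnvrs_overlapping, 0L)
    expect_identical(ov0$n_qtls, 0L)
    # the printed worked example: 162 of 166
    expect_equal(summaryPercent(162, 166), 97.59)
})

test_that("gene annotation assigns on partial overlap and bins CNVRs", {
    cn <- mkCnvrs("1", c(150, 5000, 9000), c(300, 6000, 9500))
    genes <- GRanges("1", IRanges(c(100, 5100, 5500), c(200, 5300, 5600)),
                     gene_id = c("G1", "G2", "G3"))
    ann <- annotateGenes(cn, genes)
    expect_identical(ann$perCnvr$CNVR1, "G1")   # partial overlap counts
    expect_identical(sort(ann$perCnvr$CNVR2), c("G2", "G3"))
    expect_identical(unname(ann$histogram), c(1L, 1L, 1L))
    expect_identical(ann$nCnvrsWithGenes, 2L)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
    # k=5, K=10, n=10, N=100 against the explicit sum
    sel <- paste0("g", 1:10)
    bg <- paste0("g", 1:100)
    annot <- data.frame(gene = paste0("g", c(1:5, 51:55)),
                        term = rep("T1", 10))
    res <- termEnrichment(sel, annot, bg)
    expect_equal(res$p_raw, hyperOracle(5, 10, 10, 100))
    expect_equal(res$associated_gene_pct, 50)
    # forced selection gives p = 1
    resAll <- termEnrichment(bg, data.frame(gene = bg, term = "T"), bg)
    expect_equal(resAll$p_raw, 1)
})

test_that("Bonferroni factor counts tested terms only", {
    sel <- paste0("g", 1:5)
    bg <- paste0("g", 1:50)
    base <- data.frame(gene = paste0("g", c(1:3, 20:26)), term = "T1")
    extra <- data.frame(gene = paste0("g", c(2:4, 30:36)), term = "T2")
    r1 <- termEnrichment(sel, base, bg)
    r2 <- termEnrichment(sel, rbind(base, extra), bg)
    expect_equal(r2$p_raw[r2$term == "T1"], r1$p_raw)
    expect_equal(r2$p_bonferroni[r2$term == "T1"],
                 pmin(1, r1$p_raw * 2))
    # terms with no selected genes are not tested
    none <- data.frame(gene = paste0("g", 40:45), term = "T3")
    r3 <- termEnrichment(sel, rbind(base, none), bg)
    expect_false("T3" %in% r3$term)
    expect_equal(r3$p_bonferroni, pmin(1, r3$p_raw * 1))
    # a term entirely outside the background is skipped with a warning
    alien <- data.frame(gene = "zz9", term = "T4")
    expect_warning(termEnrichment(sel, rbind(base, alien), bg), "T4")
})

test_that("enrichment agrees with the oracle across small instances", {
    set.seed(17)
    for (rep in 1:40) {
        N <- sample(5:60, 1)
        K <- sample(1:N, 1)
        n <- sample(1:N, 1)
        bg <- paste0("g", 1:N)
        sel <- sample(bg, n)
        annot <- data.frame(gene = sample(bg, K), term = "T")
        k <- length(intersect(annot$gene, sel))
        if (k < 1) next
        res <- termEnrichment(sel, annot, bg)
        expect_equal(res$p_raw, hyperOracle(k, K, n, N), tolerance = 1e-12)
    }
})
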