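#' Concordance of a CNVR set with a reference catalogue
#'
#' Counts query CNVRs touched (>= 1 bp) by any reference interval and sums,
#' over query CNVRs, the merged intersection length with the reference set.
#' Percentages are reported against the query count and total query length,
#' rounded half away from zero to 2 decimals.
#'
#' @param query A \linkS4class{CnvrSet} or \linkS4class{GRanges}.
#' @param reference A \linkS4class{GRanges} of reference intervals.
#' @param studyLabel Label recorded in the output row.
#' @return A one-row data frame: \code{study}, \code{n_overlapping},
#'   \code{concordant_length} (bp), \code{pct_count}, \code{pct_length}.
#' @export
concordance <- function(query, reference, studyLabel = "reference") {
    if (!length(query)) stop("empty query CNVR set")
    refm <- reduce(granges(reference))
    hit <- findOverlaps(query, refm)
    nOv <- length(unique(queryHits(hit)))
    concLen <- 0
    if (length(hit)) {
        ints <- pintersect(granges(query)[queryHits(hit)],
                           refm[subjectHits(hit)])
        concLen <- sum(as.numeric(width(ints)))
    }
    totLen <- sum(as.numeric(width(query)))
    data.frame(study = studyLabel, n_overlapping = nOv,
               concordant_length = concLen,
               pct_count = summaryPercent(nOv, length(query)),
               pct_length = summaryPercent(concLen, totLen))
}

#' Overlap CNVRs with a QTL catalogue
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param qtl A \linkS4class{GRanges} with metadata columns \code{qtl_id}
#'   and \code{trait}.
#' @return A list: \code{n_cnvrs_overlapping}, \code{pct_cnvrs},
#'   \code{n_qtls} (distinct overlapped QTL ids), \code{n_traits} (distinct
#'   trait names), and \code{perCnvr}, a list of overlapped QTL ids per
#'   CNVR.
#' @export
qtlOverlap <- function(cnvrs, qtl) {
    hit <- findOverlaps(cnvrs, qtl)
    qids <- mcols(qtl)$qtl_id[subjectHits(hit)]
    perCnvr <- split(qids, factor(queryHits(hit),
                                  levels = seq_along(cnvrs)))
    names(perCnvr) <- mcols(cnvrs)$cnvr_id
    nOv <- length(unique(queryHits(hit)))
    list(n_cnvrs_overlapping = nOv,
         pct_cnvrs = if (length(cnvrs)) summaryPercent(nOv, length(cnvrs))
                     else NA_real_,
         n_qtls = length(unique(qids)),
         n_traits = length(unique(mcols(qtl)$trait[subjectHits(hit)])),
         perCnvr = perCnvr)
}

#' Retrieve gene content of CNVRs
#'
#' A gene is assigned to a CNVR when the two overlap by at least 1 bp
#' (genes partially or entirely spanning the region).
#'
#' @param cnvrs A \linkS4class{CnvrSet}.
#' @param genes A \linkS4class{GRanges} with metadata column \code{gene_id}
#'   (e.g. from \code{\link{readGff3Genes}}).
#' @return A list: \code{perCnvr} (gene ids per CNVR), \code{genes}
#'   (distinct gene ids hit), \code{nCnvrsWithGenes}, and
#'   \code{histogram} -- counts of CNVRs containing 0, 1, and >= 2 genes.
#' @export
annotateGenes <- function(cnvrs, genes) {
    hit <- findOverlaps(cnvrs, genes)
    gids <- mcols(genes)$gene_id[subjectHits(hit)]
    perCnvr <- split(gids, factor(queryHits(hit),
                                  levels = seq_along(cnvrs)))
    names(perCnvr) <- mcols(cnvrs)$cnvr_id
    nGenes <- lengths(lapply(perCnvr, unique))
    list(perCnvr = perCnvr,
         genes = unique(gids),
         nCnvrsWithGenes = sum(nGenes > 0),
         histogram = c(`0` = sum(nGenes == 0), `1` = sum(nGenes == 1),
                       `2+` = sum(nGenes >= 2)))
}

#' Hypergeometric term enrichment with Bonferroni correction
#'
#' For every annotation term with at least one selected gene, computes the
#' one-sided hypergeometric upper-tail probability of observing at least
#' \code{k} term-annotated genes in a selection of \code{n} genes from a
#' background of \code{N} genes of which \code{K} carry the term.  The
#' Bonferroni factor is the number of tested terms.  The associated-gene
#' percentage is \code{100 * k / K}.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   \code{background}).
#' @param annotation Data frame with columns \code{gene} and \code{term}
#'   (optionally \code{term_name}), or a named list of gene-id vectors.
#' @param background Character vector of background gene ids.
#' @return A data frame sorted by \code{p_bonferroni}: \code{term},
#'   \code{term_name}, \code{k}, \code{K}, \code{n}, \code{N},
#'   \code{p_raw}, \code{p_bonferroni}, \code{associated_gene_pct}.
#' @export
termEnrichment <- function(selected, annotation, background) {
    stopifnot(all(selected %in% background))
    if (is.list(annotation) && !is.data.frame(annotation)) {
        annotation <- data.frame(
            gene = unlist(annotation, use.names = FALSE),
            term = rep(names(annotation), lengths(annotation)))
    }
    hasName <- "term_name" %in% colnames(annotation)
    N <- length(unique(background))
    n <- length(unique(selected))
    terms <- unique(annotation$term)
    rows <- lapply(terms, function(tm) {
        g <- unique(annotation$gene[annotation$term == tm])
        gBg <- intersect(g, background)
        if (!length(gBg)) {
            warning("term '", tm, "' has no background genes; skipped")
            return(NULL)
        }
        k <- length(intersect(gBg, selected))
        if (k < 1) return(NULL)
        K <- length(gBg)
        data.frame(term = tm,
                   term_name = if (hasName)
                       annotation$term_name[match(tm, annotation$term)]
                       else tm,
                   k = k, K = K, n = n, N = N,
                   p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                   associated_gene_pct = summaryPercent(k, K))
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (!length(rows))
        return(data.frame(term = character(0), term_name = character(0),
                          k = integer(0), K = integer(0), n = integer(0),
                          N = integer(0), p_raw = numeric(0),
                          p_bonferroni = numeric(0),
                          associated_gene_pct = numeric(0)))
    df <- do.call(rbind, rows)
    df$p_bonferroni <- pmin(1, df$p_raw * nrow(df))
    df <- df[order(df$p_bonferroni, df$p_raw), ]
    rownames(df) <- NULL
    df[, c("term", "term_name", "k", "K", "n", "N", "p_raw",
           "p_bonferroni", "associated_gene_pct")]
}
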