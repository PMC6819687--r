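#' Read a marker map / PFB file
#'
#' Reads a tab-delimited table with header columns \code{Name}, \code{Chr},
#' \code{Position} and optionally \code{PFB} (defaulting to 0.5 when absent).
#' Markers on sex chromosomes are dropped with a message (calling is
#' autosome-only), and the result is sorted by (chromosome, position).
#' Transparently reads gzip-compressed files.
#'
#' @param path Path to the file.
#' @return A \linkS4class{MarkerMap}.
#' @seealso \code{\link{writeMarkerMap}}, \code{\link{computePfb}}
#' @export
readMarkerMap <- function(path) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
    need <- c("Name", "Chr", "Position")
    if (!all(need %in% colnames(tab)))
        stop("marker map must have columns Name, Chr, Position")
    pos <- suppressWarnings(as.numeric(tab$Position))
    if (anyNA(pos))
        stop("non-numeric position at line ",
             which(is.na(pos))[1] + 1L, " of ", path)
    dup <- tab$Name[duplicated(tab$Name)]
    if (length(dup))
        stop("duplicate marker name: ", dup[1])
    pfbv <- if ("PFB" %in% colnames(tab)) {
        v <- suppressWarnings(as.numeric(tab$PFB))
        if (anyNA(v)) stop("non-numeric PFB at line ",
                           which(is.na(v))[1] + 1L, " of ", path)
        v
    } else rep(0.5, nrow(tab))
    sex <- tab$Chr %in% SEX_CHROMS
    if (any(sex)) {
        message("dropping ", sum(sex), " marker(s) on sex chromosomes")
        tab <- tab[!sex, , drop = FALSE]
        pos <- pos[!sex]
        pfbv <- pfbv[!sex]
    }
    markerMap(tab$Name, tab$Chr, as.integer(pos), pfbv)
}

#' Write a marker map / PFB file
#'
#' @param map A \linkS4class{MarkerMap}.
#' @param path Output path (tab-delimited \code{Name Chr Position PFB}).
#' @return Invisibly, \code{path}.
#' @export
writeMarkerMap <- function(map, path) {
    df <- data.frame(Name = names(map),
                     Chr = as.character(seqnames(map)),
                     Position = start(map),
                     PFB = sprintf("%.6f", mcols(map)$pfb),
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a split per-sample signal file
#'
#' Reads the per-individual signal dialect: a tab-delimited file with columns
#' \code{Name}, \code{<sample>.Log R Ratio} and \code{<sample>.B Allele Freq},
#' one row per marker in any order.  Values are aligned to the marker map;
#' markers absent from the file become \code{NA}.  BAF values outside [0, 1]
#' are clamped with a warning (the clamp count is returned).
#'
#' @param path Path to the signal file.
#' @param sampleId Sample identifier matching the column prefix.
#' @param map A \linkS4class{MarkerMap} defining marker order.
#' @return A list with numeric vectors \code{lrr} and \code{baf} (aligned to
#'   \code{map}, named by marker) and \code{nClamped}.
#' @seealso \code{\link{writeSignalFile}}
#' @export
readSignalFile <- function(path, sampleId, map) {
    tab <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character")
    lcol <- paste0(sampleId, ".Log R Ratio")
    bcol <- paste0(sampleId, ".B Allele Freq")
    if (!all(c("Name", lcol, bcol) %in% colnames(tab)))
        stop("signal file lacks columns for sample '", sampleId, "'")
    lv <- suppressWarnings(as.numeric(tab[[lcol]]))
    bv <- suppressWarnings(as.numeric(tab[[bcol]]))
    missTok <- function(x) is.na(x) | x %in% c("NA", "", "NaN")
    badl <- is.na(lv) & !missTok(tab[[lcol]])
    badb <- is.na(bv) & !missTok(tab[[bcol]])
    if (any(badl | badb))
        stop("unreadable value at line ", which(badl | badb)[1] + 1L,
             " of ", path)
    nClamped <- sum(bv < 0 | bv > 1, na.rm = TRUE)
    if (nClamped > 0)
        warning(nClamped, " BAF value(s) outside [0,1] clamped")
    bv <- .clamp(bv, 0, 1)
    idx <- match(names(map), tab$Name)
    list(lrr = setNames(lv[idx], names(map)),
         baf = setNames(bv[idx], names(map)),
         nClamped = nClamped)
}

#' Write a split per-sample signal file
#'
#' @param lrr,baf Numeric vectors aligned to \code{map}.
#' @param sampleId Sample identifier used in the column headers.
#' @param map A \linkS4class{MarkerMap}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeSignalFile <- function(lrr, baf, sampleId, map, path) {
    stopifnot(length(lrr) == length(map), length(baf) == length(map))
    fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.6f", x))
    df <- data.frame(Name = names(map), l = fmt(lrr), b = fmt(baf),
                     check.names = FALSE)
    colnames(df) <- c("Name", paste0(sampleId, ".Log R Ratio"),
                      paste0(sampleId, ".B Allele Freq"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Compute population B allele frequencies from cohort signals
#'
#' The PFB of a marker is the mean BAF over the chosen samples' non-missing
#' entries, clamped into [0.01, 0.99] so every genotype-cluster weight in the
#' HMM emission model stays nonzero; markers with no data default to 0.5.
#'
#' @param signal A \linkS4class{SignalSet}.
#' @param samples Character vector of samples to use (typically the
#'   QC-passing subset); defaults to all samples.
#' @return Named numeric PFB vector aligned to the markers.
#' @export
computePfb <- function(signal, samples = colnames(signal)) {
    if (length(samples) == 0)
        stop("at least one sample is required to compute PFB")
    stopifnot(all(samples %in% colnames(signal)))
    b <- baf(signal)[, samples, drop = FALSE]
    p <- rowMeans(b, na.rm = TRUE)
    p[is.nan(p)] <- 0.5
    setNames(.clamp(p, 0.01, 0.99), rownames(signal))
}

#' Read BED-like intervals
#'
#' Reads 3+ column interval files in either the standard BED dialect (0-based
#' half-open) or a 1-based inclusive dialect, converting to the package's
#' internal 1-based closed coordinates.  A fourth column becomes the range
#' names, further columns are kept as metadata.  Rows whose interval is empty
#' or inverted are rejected with their line number.
#'
#' @param path Path to the file (gz-transparent).
#' @param dialect \code{"bed"} (0-based half-open, default) or
#'   \code{"one_based"} (1-based inclusive).
#' @param extraNames Optional names for columns beyond the fourth.
#' @return A sorted \linkS4class{GRanges}; \code{metadata(x)$dialect} records
#'   the input dialect.
#' @export
readBedIntervals <- function(path, dialect = c("bed", "one_based"),
                             extraNames = NULL) {
    dialect <- match.arg(dialect)
    tab <- read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(tab) < 3)
        stop("interval file needs at least 3 columns")
    s <- suppressWarnings(as.numeric(tab[[2]]))
    e <- suppressWarnings(as.numeric(tab[[3]]))
    if (anyNA(s) || anyNA(e))
        stop("non-numeric coordinate at line ", which(is.na(s) | is.na(e))[1],
             " of ", path)
    bad <- if (dialect == "bed") s >= e else s > e
    if (any(bad))
        stop("inverted or empty interval at line ", which(bad)[1],
             " of ", path)
    startc <- if (dialect == "bed") s + 1 else s
    gr <- GRanges(as.character(tab[[1]]), IRanges(startc, e))
    if (ncol(tab) >= 4) names(gr) <- as.character(tab[[4]])
    if (ncol(tab) > 4) {
        extra <- tab[, -(1:4), drop = FALSE]
        if (!is.null(extraNames) && length(extraNames) == ncol(extra))
            colnames(extra) <- extraNames
        mcols(gr) <- DataFrame(extra)
    }
    gr <- .sortNatural(gr)
    metadata(gr)$dialect <- dialect
    gr
}

#' Write intervals as BED (0-based half-open)
#'
#' @param gr A \linkS4class{GRanges}; names become the fourth column.
#' @param path Output path.
#' @param extraCols Optional metadata column names to append.
#' @return Invisibly, \code{path}.
#' @export
writeBedIntervals <- function(gr, path, extraCols = NULL) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = if (is.null(names(gr)))
                         paste0("iv", seq_along(gr)) else names(gr))
    for (cn in extraCols) df[[cn]] <- mcols(gr)[[cn]]
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Extracts \code{gene}-type features (column 3) from a GFF3 file, keeping
#' the gene identifier (\code{ID}, with any \code{gene:} prefix stripped) and
#' \code{biotype} attribute.  Features whose attribute column cannot be
#' parsed are skipped and counted rather than failing the whole file.
#' GFF3 coordinates are 1-based inclusive, matching the internal convention.
#'
#' @param path Path to the GFF3 file (gz-transparent).
#' @return A sorted \linkS4class{GRanges} with metadata columns
#'   \code{gene_id} and \code{biotype}; the number of skipped gene features
#'   is recorded in \code{metadata(x)$nSkipped}.
#' @export
readGff3Genes <- function(path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok9 <- lengths(fields) == 9L
    fields <- fields[ok9]
    type <- vapply(fields, `[[`, character(1), 3L)
    genes <- fields[type == "gene"]
    nSkipped <- 0L
    recs <- lapply(genes, function(f) {
        attrs <- strsplit(f[[9]], ";", fixed = TRUE)[[1]]
        kv <- strsplit(attrs, "=", fixed = TRUE)
        if (any(lengths(kv) != 2L)) return(NULL)
        keys <- vapply(kv, `[[`, character(1), 1L)
        vals <- vapply(kv, `[[`, character(1), 2L)
        id <- vals[match("ID", keys)]
        if (is.na(id)) return(NULL)
        id <- sub("^gene:", "", id)
        bt <- vals[match("biotype", keys)]
        s <- suppressWarnings(as.integer(f[[4]]))
        e <- suppressWarnings(as.integer(f[[5]]))
        if (is.na(s) || is.na(e) || s > e) return(NULL)
        list(chrom = f[[1]], start = s, end = e, id = id,
             biotype = if (is.na(bt)) "unknown" else bt)
    })
    keep <- !vapply(recs, is.null, logical(1))
    nSkipped <- sum(!keep)
    recs <- recs[keep]
    if (!length(recs)) {
        gr <- GRanges()
        mcols(gr)$gene_id <- character(0)
        mcols(gr)$biotype <- character(0)
    } else {
        gr <- GRanges(vapply(recs, `[[`, character(1), "chrom"),
                      IRanges(vapply(recs, `[[`, integer(1), "start"),
                              vapply(recs, `[[`, integer(1), "end")),
                      gene_id = vapply(recs, `[[`, character(1), "id"),
                      biotype = vapply(recs, `[[`, character(1), "biotype"))
        gr <- .sortNatural(gr)
    }
    metadata(gr)$nSkipped <- nSkipped
    gr
}
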