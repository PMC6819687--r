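#' Round half away from zero
#'
#' Commercial rounding used for every reported percentage: exact halves move
#' away from zero (base \code{round} rounds halves to even).  A tiny epsilon
#' absorbs binary representation error in quotients such as 100*111/166.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(2.675, 2)  # 2.68
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage or mean with report rounding
#'
#' Computes \code{100 * num / den} (or \code{num / den} for means) rounded
#' half away from zero to \code{digits} decimals -- the arithmetic every
#' summary table in this package uses, exposed so that any printed percentage
#' can be recomputed from its numerator and denominator.
#'
#' @param num,den Numeric vectors (recycled).
#' @param mean If \code{TRUE} return the plain ratio instead of a percentage.
#' @param digits Decimal places (default 2).
#' @return Numeric vector.
#' @examples
#' summaryPercent(26, 166)            # 15.66
#' summaryPercent(3871, 90, mean = TRUE)  # 43.01
#' @export
summaryPercent <- function(num, den, mean = FALSE, digits = 2) {
    if (any(den == 0))
        stop("zero denominator in summary computation")
    r <- num / den
    if (!mean) r <- 100 * r
    roundHalfUp(r, digits)
}

# clamp a numeric vector into [lo, hi]
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# natural-order chromosome sorting for bare GRanges built from files
.sortNatural <- function(gr) {
    gr <- sortSeqlevels(gr)
    sort(gr)
}

SEX_CHROMS <- c("X", "Y", "W", "Z", "MT", "M",
                "chrX", "chrY", "chrW", "chrZ", "chrMT", "chrM")
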