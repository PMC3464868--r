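#' Bland-Altman agreement between two paired measurement series
#'
#' Differences are taken as a - b; the bias is their mean and the limits
#' of agreement are bias +/- 2 standard deviations of the differences
#' (factor 2 exactly, sample n-1 SD). The coefficient of variability is
#' filled in alongside (NA when the grand mean is zero).
#'
#' @param a,b equal-length numeric vectors of paired measurements
#'   (same quantity by two methods or two observers)
#' @return an [AgreementReport-class]
#' @examples
#' rep <- blandAltman(c(10, 14, 18), c(12, 14, 17))
#' bias(rep)              # -1/3
#' limitsOfAgreement(rep)
#' @export
blandAltman <- function(a, b) {
    a <- as.numeric(a)
    b <- as.numeric(b)
    if (length(a) != length(b))
        stop("paired series must have equal length")
    if (length(a) < 2L)
        stop("need at least 2 pairs")
    d <- a - b
    m <- mean(d)
    s <- stats::sd(d)
    grand <- mean(c(a, b))
    cv <- if (abs(grand) < 1e-12) NA_real_ else 100 * s / abs(grand)
    new("AgreementReport", nPairs = length(a), bias = m, sdDiff = s,
        loaLow = m - 2 * s, loaHigh = m + 2 * s, covPercent = cv,
        pairMeans = (a + b) / 2, pairDiffs = d)
}

#' Coefficient of variability between two paired series
#'
#' 100 * SD(differences) / |grand mean of all 2n values|, with the sample
#' (n-1) SD — the definition used in the CMR reproducibility literature.
#' Scale-invariant: multiplying all values by k > 0 leaves it unchanged.
#'
#' @param a,b equal-length numeric vectors of paired measurements
#' @return coefficient of variability, percent
#' @export
covVariability <- function(a, b) {
    a <- as.numeric(a)
    b <- as.numeric(b)
    if (length(a) != length(b))
        stop("paired series must have equal length")
    if (length(a) < 2L)
        stop("need at least 2 pairs")
    grand <- mean(c(a, b))
    if (abs(grand) < 1e-12)
        stop("grand mean is zero: coefficient of variability undefined")
    100 * stats::sd(a - b) / abs(grand)
}

#' Bland-Altman plot
#'
#' Pair means against pair differences with the bias (solid) and
#' bias +/- 2 SD limits (dashed).
#'
#' @param x an [AgreementReport-class]
#' @param y ignored
#' @param ... passed to [graphics::plot()]
#' @export
setMethod("plot", signature("AgreementReport", "missing"), function(x, y, ...) {
    graphics::plot(x@pairMeans, x@pairDiffs, xlab = "mean of pair",
        ylab = "difference (a - b)", ...)
    graphics::abline(h = x@bias, lty = 1)
    graphics::abline(h = c(x@loaLow, x@loaHigh), lty = 2)
    invisible(x)
})
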