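#' @include AllGenerics.R
NULL

#' Bin log2 expression values into a frequency distribution
#'
#' Half-open constant-width bins `[left, left + width)`, aligned so that
#' `anchor` is a bin edge (default anchor 0, i.e. bins
#' `[k * width, (k + 1) * width)`). Empty interior bins are retained
#' with count 0; the counts always sum to the number of values.
#'
#' @param values finite log2 values (at least 2).
#' @param binWidth bin width in log2 units (default 0.2).
#' @param anchor a log2 value that falls on a bin edge.
#' @return a [BinnedFrequency-class].
#' @examples
#' binValues(c(5.0, 5.05, 5.19, 5.2), binWidth = 0.2)
#' @export
binValues <- function(values, binWidth = 0.2, anchor = 0) {
    values <- as.numeric(values)
    if (length(values) < 2L) stop("need at least 2 values to bin")
    if (anyNA(values) || any(!is.finite(values)))
        stop("values must be finite")
    if (!is.numeric(binWidth) || binWidth <= 0)
        stop("binWidth must be positive")
    # small relative epsilon so that values sitting exactly on an edge
    # (up to floating-point representation) open the next bin
    idx <- floor((values - anchor) / binWidth + 1e-9)
    rng <- range(idx)
    counts <- tabulate(idx - rng[1L] + 1L, nbins = rng[2L] - rng[1L] + 1L)
    new("BinnedFrequency", binWidth = binWidth,
        leftEdges = anchor + (rng[1L]:rng[2L]) * binWidth,
        counts = as.integer(counts))
}

#' @rdname BinnedFrequency-class
#' @export
setMethod("binWidth", "BinnedFrequency", function(object) object@binWidth)

#' @rdname BinnedFrequency-class
#' @export
setMethod("leftEdges", "BinnedFrequency", function(object) object@leftEdges)

#' @rdname BinnedFrequency-class
#' @export
setMethod("binCounts", "BinnedFrequency", function(object) object@counts)

#' @rdname BinnedFrequency-class
#' @export
setMethod("binCenters", "BinnedFrequency",
          function(object) object@leftEdges + object@binWidth / 2)

#' @rdname BinnedFrequency-class
#' @export
setMethod("nTotal", "BinnedFrequency",
          function(object) sum(object@counts))

setMethod("show", "BinnedFrequency", function(object) {
    cat(sprintf(
        "BinnedFrequency: %d bins of width %g on [%g, %g), n = %d\n",
        length(object@counts), object@binWidth, min(object@leftEdges),
        max(object@leftEdges) + object@binWidth, sum(object@counts)))
})
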