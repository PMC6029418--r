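#' @include mixture.R
NULL

SUBPOP_LEVELS <- c("low", "intermediate", "high", "unassigned")

#' Construct a sub-population cut-off scheme
#'
#' @param low,intermediate,high numeric `(lo, hi)` windows, closed
#'   intervals on the log2 scale, pairwise disjoint and ascending.
#' @return a [SubpopulationScheme-class].
#' @export
SubpopulationScheme <- function(low, intermediate, high)
    new("SubpopulationScheme", low = as.numeric(low),
        intermediate = as.numeric(intermediate), high = as.numeric(high))

#' Default cut-off windows for the three sub-populations
#'
#' Low `[5, 6.5]`, intermediate `[7.25, 8.5]`, high `[10, 13]` on the
#' log2 scale, chosen to keep the windows large while limiting the
#' number of patients incorrectly allocated by the overlapping
#' Gaussians; values in the inter-window gaps stay unassigned.
#'
#' @return a [SubpopulationScheme-class].
#' @export
defaultScheme <- function()
    SubpopulationScheme(c(5, 6.5), c(7.25, 8.5), c(10, 13))

schemeWindows <- function(scheme)
    rbind(low = scheme@low, intermediate = scheme@intermediate,
          high = scheme@high)

setMethod("show", "SubpopulationScheme", function(object) {
    w <- schemeWindows(object)
    cat("SubpopulationScheme (closed log2 windows):\n")
    for (i in seq_len(nrow(w)))
        cat(sprintf("  %-12s [%g, %g]\n", rownames(w)[i], w[i, 1], w[i, 2]))
})

#' Assign patients to sub-population windows
#'
#' A value inside a window (closed interval, boundaries inclusive)
#' receives that window's label; values in the gaps or outside all
#' windows are `unassigned`.
#'
#' @param values log2 values.
#' @param scheme a [SubpopulationScheme-class].
#' @return factor with levels low/intermediate/high/unassigned.
#' @examples
#' assignSubpopulations(c(6.0, 7.0, 12.9), defaultScheme())
#' @export
assignSubpopulations <- function(values, scheme = defaultScheme()) {
    stopifnot(is(scheme, "SubpopulationScheme"))
    w <- schemeWindows(scheme)
    lab <- rep("unassigned", length(values))
    for (i in seq_len(nrow(w)))
        lab[values >= w[i, 1] & values <= w[i, 2]] <- rownames(w)[i]
    factor(lab, levels = SUBPOP_LEVELS)
}

misassignCore <- function(means, sds, sizes, scheme) {
    stopifnot(length(means) == 3L, length(sds) == 3L, length(sizes) == 3L)
    w <- schemeWindows(scheme)
    out <- numeric(3L); names(out) <- rownames(w)
    occupancy <- matrix(0, 3, 3, dimnames = list(rownames(w), NULL))
    for (k in 1:3) {          # window k is intended for component k
        occ <- sizes * (pnorm((w[k, 2] - means) / sds) -
                        pnorm((w[k, 1] - means) / sds))
        occupancy[k, ] <- occ
        tot <- sum(occ)
        if (tot <= 0)
            stop("window '", rownames(w)[k], "' has zero expected occupancy")
        out[k] <- 100 * sum(occ[-k]) / tot
    }
    attr(out, "occupancy") <- occupancy
    out
}

#' @describeIn misassignment expected misassignment from a converged
#'   3-component fit; component population sizes default to the
#'   AUC-derived weights times the total count.
#' @param scheme a [SubpopulationScheme-class].
#' @param sizes patients per component (lowest mean first); default
#'   `componentWeights(object) * nTotal(freq)`.
#' @return named percentages (low/intermediate/high) of window
#'   occupants expected to originate from the other components, with an
#'   `"occupancy"` attribute holding the expected per-component counts.
#' @export
setMethod("misassignment", "MixtureFit", function(object,
                                                  scheme = defaultScheme(),
                                                  sizes = NULL) {
    if (nrow(object@components) != 3L)
        stop("misassignment requires a 3-component fit")
    if (!isConverged(object))
        stop("misassignment requires a converged fit")
    if (is.null(sizes))
        sizes <- componentWeights(object) * nTotal(object@freq)
    misassignCore(object@components$mean, object@components$sd, sizes, scheme)
})

#' @describeIn misassignment closed-form estimate from a components
#'   data.frame (columns `mean`, `sd`) plus explicit `sizes` — e.g.
#'   published fit parameters.
#' @export
setMethod("misassignment", "data.frame", function(object,
                                                  scheme = defaultScheme(),
                                                  sizes) {
    misassignCore(object$mean, object$sd, sizes, scheme)
})
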