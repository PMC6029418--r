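#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats pnorm qnorm pchisq pt pf rnorm runif rexp sd cor
#'   cor.test lm coef quantile setNames
NULL

## Closed vocabularies for the clinical table ------------------------------

#' Closed vocabularies for clinical covariates
#'
#' Levels accepted in the canonical clinical table: estrogen-receptor
#' status, treatment arm and vital-status outcome. `"unknown"` outcomes
#' arise from unmapped source codes and are treated as censored
#' observations downstream.
#'
#' @format Character vectors of factor levels.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
ER_LEVELS <- c("positive", "negative", "unknown")

#' @rdname vocabularies
#' @export
TREATMENT_LEVELS <- c("none", "hormone_only", "chemo_only", "other")

#' @rdname vocabularies
#' @export
OUTCOME_LEVELS <- c("died_of_disease", "died_other_cause", "alive", "unknown")

REQUIRED_CLINICAL <- c("patient_id", "er_status", "treatment",
                       "survival_time", "outcome")

## TumorCohort --------------------------------------------------------------

#' TumorCohort: expression plus clinical covariates
#'
#' A [SummarizedExperiment::SummarizedExperiment] with one `log2expr`
#' assay (genes in rows, patients in columns, log2 arbitrary-intensity
#' units), the canonical clinical covariates in `colData`, and the name
#' of the index gene whose distribution is deconvolved.
#'
#' @slot indexGene single gene symbol, present in `rownames`.
#' @export
setClass("TumorCohort",
    contains = "SummarizedExperiment",
    representation(indexGene = "character"))

setValidity("TumorCohort", function(object) {
    msg <- character()
    m <- SummarizedExperiment::assay(object)
    if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)))
        msg <- c(msg, "expression values must all be finite (no NA/Inf)")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicated gene identifiers")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated patient identifiers")
    if (length(object@indexGene) != 1L ||
        !(object@indexGene %in% rownames(object)))
        msg <- c(msg, sprintf("index gene '%s' not in gene identifiers",
                              object@indexGene[1]))
    cd <- SummarizedExperiment::colData(object)
    miss <- setdiff(REQUIRED_CLINICAL, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste("missing clinical columns:",
                            paste(miss, collapse = ", ")))
    else {
        if (any(is.na(cd$survival_time)) || any(cd$survival_time < 0))
            msg <- c(msg, "survival_time must be non-negative and non-missing")
        if (!all(cd$er_status %in% ER_LEVELS))
            msg <- c(msg, "er_status outside closed vocabulary")
        if (!all(cd$treatment %in% TREATMENT_LEVELS))
            msg <- c(msg, "treatment outside closed vocabulary")
        if (!all(cd$outcome %in% OUTCOME_LEVELS))
            msg <- c(msg, "outcome outside closed vocabulary")
    }
    if (length(msg)) msg else TRUE
})

## BinnedFrequency ----------------------------------------------------------

#' Binned frequency distribution of log2 expression
#'
#' Histogram of a gene's log2 expression over a cohort: constant-width
#' half-open bins `[left, left + width)` with integer counts, including
#' empty interior bins.
#'
#' @slot binWidth bin width in log2 units.
#' @slot leftEdges ascending left bin edges, spacing equal to `binWidth`.
#' @slot counts non-negative integer count per bin.
#' @export
setClass("BinnedFrequency",
    representation(binWidth = "numeric", leftEdges = "numeric",
                   counts = "integer"))

setValidity("BinnedFrequency", function(object) {
    msg <- character()
    w <- object@binWidth
    if (length(w) != 1L || !is.finite(w) || w <= 0)
        msg <- c(msg, "binWidth must be a single positive number")
    e <- object@leftEdges
    if (length(e) != length(object@counts))
        msg <- c(msg, "leftEdges and counts lengths differ")
    if (length(e) > 1L) {
        d <- diff(e)
        if (any(d <= 0) || any(abs(d - w) > 1e-8 * w))
            msg <- c(msg, "edges must ascend with constant spacing binWidth")
    }
    if (any(object@counts < 0L)) msg <- c(msg, "negative counts")
    if (length(msg)) msg else TRUE
})

## MixtureFit ---------------------------------------------------------------

#' Fitted sum-of-Gaussians model for a binned frequency distribution
#'
#' Result of the multi-start nonlinear least-squares fit of
#' `y = sum_i A_i * exp(-0.5 * ((x - m_i) / s_i)^2)` to bin counts.
#' Components are sorted by mean; the per-component area
#' `AUC_i = A_i * s_i * sqrt(2*pi)` is proportional to the number of
#' patients in that sub-population.
#'
#' @slot components data.frame with columns `amplitude`, `mean`, `sd`
#'   (one row per Gaussian, ascending mean).
#' @slot predicted model value at each bin center.
#' @slot ssResidual residual sum of squares.
#' @slot syx residual standard deviation,
#'   `sqrt(ssResidual / (n_bins - 3 * n_components))`.
#' @slot rObsPred Pearson correlation of observed vs predicted counts.
#' @slot aucs per-component area in patients.
#' @slot weights `aucs` normalised to sum to one.
#' @slot converged whether at least two independent starts agreed and the
#'   solution has no collapsed component.
#' @slot nStarts number of independent starts used.
#' @slot seed seed that drove the multi-start jitter.
#' @slot freq the [BinnedFrequency-class] that was fitted.
#' @slot candidates for [selectModel()] results, the candidate fits at
#'   each component count (list keyed by `"1"`, `"2"`, ...).
#' @export
setClass("MixtureFit",
    representation(components = "data.frame", predicted = "numeric",
                   ssResidual = "numeric", syx = "numeric",
                   rObsPred = "numeric", aucs = "numeric",
                   weights = "numeric", converged = "logical",
                   nStarts = "integer", seed = "integer",
                   freq = "BinnedFrequency", candidates = "list"))

setValidity("MixtureFit", function(object) {
    msg <- character()
    cmp <- object@components
    if (!all(c("amplitude", "mean", "sd") %in% colnames(cmp)))
        msg <- c(msg, "components needs amplitude/mean/sd columns")
    else {
        if (is.unsorted(cmp$mean)) msg <- c(msg, "components not sorted by mean")
        if (any(cmp$amplitude <= 0) || any(cmp$sd <= 0))
            msg <- c(msg, "amplitudes and SDs must be positive")
    }
    if (any(object@aucs < 0)) msg <- c(msg, "negative AUC")
    if (isTRUE(object@converged) && length(object@weights) &&
        abs(sum(object@weights) - 1) > 1e-9)
        msg <- c(msg, "weights of a converged fit must sum to 1")
    if (length(msg)) msg else TRUE
})

## SubpopulationScheme ------------------------------------------------------

#' Cut-off windows defining expression sub-populations
#'
#' Three closed, pairwise-disjoint, ascending windows `[lo, hi]` on the
#' log2 scale for the low, intermediate and high sub-populations.
#' Values between windows are left unassigned.
#'
#' @slot low,intermediate,high numeric length-2 `(lo, hi)` with `lo < hi`.
#' @export
setClass("SubpopulationScheme",
    representation(low = "numeric", intermediate = "numeric",
                   high = "numeric"))

setValidity("SubpopulationScheme", function(object) {
    w <- rbind(object@low, object@intermediate, object@high)
    if (ncol(w) != 2L) return("each window must be length 2")
    if (any(w[, 1] >= w[, 2])) return("each window needs lo < hi")
    if (w[1, 2] >= w[2, 1] || w[2, 2] >= w[3, 1])
        return("windows must be disjoint and ascending (low < intermediate < high)")
    TRUE
})

## DecisionCurve ------------------------------------------------------------

#' Sensitivity/specificity decision curve for a low-expression cutoff
#'
#' For each cutoff c, sensitivity is the true-positive rate of
#' `value < c` for predicting chemo-resistance and specificity the
#' true-negative rate of `value >= c` for sensitivity to treatment.
#' The cross-over is where the two curves intersect (linear
#' interpolation between grid points).
#'
#' @slot cutoffs ascending log2 cutoff grid.
#' @slot sensitivity,specificity rates in `[0, 1]` per cutoff.
#' @slot crossoverCutoff log2 value at which the curves cross.
#' @slot crossoverValue common rate at the intersection.
#' @slot nResistant,nSensitive class sizes used.
#' @export
setClass("DecisionCurve",
    representation(cutoffs = "numeric", sensitivity = "numeric",
                   specificity = "numeric", crossoverCutoff = "numeric",
                   crossoverValue = "numeric", nResistant = "integer",
                   nSensitive = "integer"))

setValidity("DecisionCurve", function(object) {
    msg <- character()
    if (is.unsorted(object@cutoffs)) msg <- c(msg, "cutoffs must ascend")
    r <- c(object@sensitivity, object@specificity)
    if (any(r < 0 | r > 1)) msg <- c(msg, "rates must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})
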