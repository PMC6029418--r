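#' @include survival.R
NULL

EXCLUSION_REASONS <- c("none", "not_in_arm", "died_other_cause_lt5y",
                       "followup_lt5y")

#' Classify treatment response at the 5-year boundary
#'
#' Within the requested arm: death from disease before `threshold`
#' years is resistant; survival to `threshold` or beyond (any vital
#' status) is sensitive; death from another cause before the threshold,
#' or a last follow-up before the threshold while alive (or with
#' unknown outcome), is excluded. The boundary itself counts as
#' sensitive ("survival less than 5 years" is strict).
#'
#' @param clinical canonical clinical data.frame.
#' @param arm treatment arm analysed (default `"chemo_only"`).
#' @param threshold years separating resistant from sensitive
#'   (default 5).
#' @return data.frame with `patient_id`, `status`
#'   (resistant/sensitive/excluded) and `exclusion_reason`.
#' @export
classifyPatients <- function(clinical, arm = "chemo_only", threshold = 5) {
    stopifnot(arm %in% TREATMENT_LEVELS, threshold > 0)
    t <- clinical$survival_time
    inArm <- clinical$treatment == arm
    status <- rep("excluded", nrow(clinical))
    reason <- rep("not_in_arm", nrow(clinical))
    sens <- inArm & t >= threshold
    res <- inArm & t < threshold & clinical$outcome == "died_of_disease"
    exOther <- inArm & t < threshold & clinical$outcome == "died_other_cause"
    exFup <- inArm & t < threshold &
        clinical$outcome %in% c("alive", "unknown")
    status[sens] <- "sensitive"; reason[sens] <- "none"
    status[res] <- "resistant"; reason[res] <- "none"
    reason[exOther] <- "died_other_cause_lt5y"
    reason[exFup] <- "followup_lt5y"
    data.frame(patient_id = clinical$patient_id,
               status = factor(status, c("resistant", "sensitive",
                                         "excluded")),
               exclusion_reason = factor(reason, EXCLUSION_REASONS),
               stringsAsFactors = FALSE)
}

#' Index-gene expression by survival-time bin
#'
#' Disease deaths are grouped by completed survival year
#' (bin k = `[k-1, k)` years, k = 1..threshold); patients classified
#' sensitive (survived the threshold) form the final `> threshold` bin.
#' Excluded patients contribute to no bin.
#'
#' @param clinical canonical clinical data.frame.
#' @param values index-gene log2 values aligned with `clinical` rows.
#' @param classification output of [classifyPatients()] on the same
#'   rows.
#' @param threshold years (default 5).
#' @return data.frame with `bin` (labels `"1"`.. and `">5"`-style),
#'   `n`, `meanExpression` (NA when empty), plus the per-bin score used
#'   for trend tests.
#' @export
survivalBins <- function(clinical, values, classification, threshold = 5) {
    stopifnot(nrow(clinical) == length(values),
              nrow(clinical) == nrow(classification))
    nb <- as.integer(threshold)
    bins <- vector("list", nb + 1L)
    labels <- c(as.character(seq_len(nb)), paste0(">", threshold))
    isDeath <- clinical$outcome == "died_of_disease"
    for (k in seq_len(nb)) {
        sel <- classification$status == "resistant" & isDeath &
            clinical$survival_time >= k - 1 & clinical$survival_time < k
        bins[[k]] <- values[sel]
    }
    bins[[nb + 1L]] <- values[classification$status == "sensitive"]
    data.frame(bin = factor(labels, levels = labels),
               score = seq_len(nb + 1L),
               n = vapply(bins, length, integer(1)),
               meanExpression = vapply(bins, function(v)
                   if (length(v)) mean(v) else NA_real_, numeric(1)),
               row.names = NULL)
}

binMembership <- function(clinical, classification, threshold = 5) {
    nb <- as.integer(threshold)
    lab <- rep(NA_integer_, nrow(clinical))
    isDeath <- clinical$outcome == "died_of_disease"
    for (k in seq_len(nb)) {
        sel <- classification$status == "resistant" & isDeath &
            clinical$survival_time >= k - 1 & clinical$survival_time < k
        lab[sel] <- k
    }
    lab[classification$status == "sensitive"] <- nb + 1L
    lab
}

#' One-way ANOVA plus linear trend across ordered bins
#'
#' Fixed-effects F test of expression across survival-time bins and a
#' post-hoc linear-contrast trend test with equally spaced bin scores:
#' contrast estimate over its standard error, t-distributed on the
#' ANOVA residual degrees of freedom (reported two-sided).
#'
#' @param values per-patient expression.
#' @param bin per-patient ordered bin membership (factor or integer;
#'   NA = not in any bin).
#' @return list of two `htest` objects, `anova` (F) and `trend` (t).
#' @export
anovaTrend <- function(values, bin) {
    keep <- !is.na(bin) & !is.na(values)
    values <- values[keep]
    bin <- droplevels(factor(bin[keep]))
    k <- nlevels(bin)
    if (k < 2L) stop("need at least 2 non-empty bins")
    n <- tapply(values, bin, length)
    m <- tapply(values, bin, mean)
    grand <- mean(values)
    ssb <- sum(n * (m - grand)^2)
    ssw <- sum((values - m[bin])^2)
    dfb <- k - 1L; dfw <- length(values) - k
    if (dfw < 1L) stop("no residual degrees of freedom")
    msw <- ssw / dfw
    f <- if (ssb <= 0) 0 else if (msw > 0) (ssb / dfb) / msw else Inf
    pAnova <- if (is.infinite(f)) 0 else pf(f, dfb, dfw, lower.tail = FALSE)
    anova <- structure(list(statistic = c(F = f),
                            parameter = c(dfNum = dfb, dfDen = dfw),
                            p.value = pAnova,
                            method = "one-way fixed-effects ANOVA",
                            data.name = "expression by survival bin"),
                       class = "htest")
    s <- seq_len(k)
    cvec <- s - mean(s)
    est <- sum(cvec * m)
    se <- sqrt(msw * sum(cvec^2 / n))
    tstat <- if (se > 0) est / se else 0
    trend <- structure(list(statistic = c(t = tstat),
                            parameter = c(df = dfw),
                            p.value = 2 * pt(-abs(tstat), dfw),
                            estimate = c(contrast = est),
                            method = "linear-contrast trend test",
                            data.name = "expression by survival bin"),
                       class = "htest")
    list(anova = anova, trend = trend)
}

#' Sensitivity/specificity decision curve for a low-expression cutoff
#'
#' For each cutoff c: sensitivity `P(value < c | resistant)`,
#' specificity `P(value >= c | sensitive)`. The default grid is all
#' observed values plus midpoints between adjacent distinct values.
#' The cross-over is found by linear interpolation at the first sign
#' change of sensitivity minus specificity; multiple sign changes
#' (small-sample noise) report the first with a warning.
#'
#' @param values log2 expression of the classified patients.
#' @param status factor/character, `"resistant"` or `"sensitive"`.
#' @param grid optional cutoff grid.
#' @return a [DecisionCurve-class].
#' @export
decisionCurve <- function(values, status, grid = NULL) {
    status <- as.character(status)
    keep <- status %in% c("resistant", "sensitive")
    values <- values[keep]; status <- status[keep]
    nR <- sum(status == "resistant"); nS <- sum(status == "sensitive")
    if (nR == 0 || nS == 0)
        stop("both classes must be non-empty for a decision curve")
    if (is.null(grid)) {
        v <- sort(unique(values))
        grid <- sort(unique(c(v, (v[-1] + v[-length(v)]) / 2)))
    } else grid <- sort(unique(as.numeric(grid)))
    vr <- values[status == "resistant"]
    vs <- values[status == "sensitive"]
    sens <- vapply(grid, function(c) mean(vr < c), numeric(1))
    spec <- vapply(grid, function(c) mean(vs >= c), numeric(1))
    d <- sens - spec
    # indices i where the sign of d changes between grid[i] and grid[i+1]
    changes <- which(d[-length(d)] * d[-1] < 0 | d[-length(d)] == 0)
    if (!length(changes)) {
        cc <- NA_real_; cv <- NA_real_
    } else {
        if (length(changes) > 1L &&
            any(diff(changes) > 1L))
            warning("multiple sensitivity/specificity crossings; ",
                    "reporting the first (lowest cutoff)")
        i <- changes[1L]
        if (d[i] == 0) {
            cc <- grid[i]; cv <- sens[i]
        } else {
            frac <- d[i] / (d[i] - d[i + 1L])
            cc <- grid[i] + frac * (grid[i + 1L] - grid[i])
            cv <- sens[i] + frac * (sens[i + 1L] - sens[i])
        }
    }
    new("DecisionCurve", cutoffs = grid, sensitivity = sens,
        specificity = spec, crossoverCutoff = cc, crossoverValue = cv,
        nResistant = as.integer(nR), nSensitive = as.integer(nS))
}

#' @rdname DecisionCurve-class
#' @export
setMethod("crossover", "DecisionCurve", function(object)
    c(cutoff = object@crossoverCutoff, value = object@crossoverValue))

setMethod("show", "DecisionCurve", function(object) {
    cat(sprintf(
        "DecisionCurve: %d cutoffs, %d resistant / %d sensitive\n",
        length(object@cutoffs), object@nResistant, object@nSensitive))
    cat(sprintf("cross-over at log2 = %.3f, sensitivity = specificity = %.3f\n",
                object@crossoverCutoff, object@crossoverValue))
})

#' Years of survival gained per log2 unit of expression
#'
#' Reciprocal slope of the least-squares line through the points
#' (bin mean expression, bin midpoint year) for the within-threshold
#' bins; a methodological summary of how steeply expression buys
#' survival time in a responsive arm.
#'
#' @param binsSummary output of [survivalBins()].
#' @param threshold years (default 5).
#' @return years per log2 unit (NA when fewer than 2 populated bins).
#' @export
yearsPerLog2 <- function(binsSummary, threshold = 5) {
    within <- binsSummary[binsSummary$score <= threshold &
                          binsSummary$n > 0, ]
    if (nrow(within) < 2L) return(NA_real_)
    midpoints <- within$score - 0.5
    fit <- lm(within$meanExpression ~ midpoints)
    slope <- unname(coef(fit)[2L])
    if (slope == 0) NA_real_ else 1 / slope
}
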