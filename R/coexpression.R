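#' @include cohort.R assignment.R
NULL

#' Pearson correlation with t-distributed p-value
#'
#' Sample Pearson r; two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y equal-length numeric vectors (n >= 3), neither constant.
#' @return list with `r` and `p`.
#' @export
pearsonCorr <- function(x, y) {
    checkCorrInput(x, y)
    ct <- cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of rank-transformed data (average ranks for
#' ties); p-value from the same t transform as [pearsonCorr()].
#'
#' @inheritParams pearsonCorr
#' @return list with `rho` and `p`.
#' @export
spearmanCorr <- function(x, y) {
    checkCorrInput(x, y)
    res <- pearsonCorr(rank(x), rank(y))
    list(rho = res$r, p = res$p)
}

checkCorrInput <- function(x, y) {
    if (length(x) != length(y)) stop("x and y lengths differ")
    if (length(x) < 3L) stop("need at least 3 observations")
    if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
    invisible(TRUE)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param alphaGlobal family-wise significance level.
#' @param nTests number of tests in the family.
#' @return `alphaGlobal / nTests`.
#' @examples
#' bonferroniThreshold(0.01, 25000) # 4e-7
#' @export
bonferroniThreshold <- function(alphaGlobal, nTests) {
    stopifnot(alphaGlobal > 0, alphaGlobal <= 1, nTests >= 1)
    alphaGlobal / nTests
}

#' Screen genes for sub-population-specific co-expression
#'
#' For every non-index gene and every sub-population, the Pearson
#' correlation with the index gene restricted to that sub-population's
#' patients; a gene is significant when its p-value falls below the
#' Bonferroni gene-level threshold. Unassigned patients take part in no
#' screen; sub-populations with fewer than 3 patients are skipped with
#' a warning.
#'
#' @param cohort a [TumorCohort-class].
#' @param labels per-patient factor from [assignSubpopulations()]
#'   (aligned with the cohort columns).
#' @param alphaGlobal family-wise level (default 0.01).
#' @param alphaGene per-gene level override (e.g. the fixed `4e-7` used
#'   with a full array); default
#'   `bonferroniThreshold(alphaGlobal, n_genes_tested)`.
#' @return data.frame with columns `gene`, `subpopulation`, `r`, `p`,
#'   `significant`; the thresholds used are in
#'   `attr(, "alphaGene")` / `attr(, "nTests")`.
#' @export
screenCoexpression <- function(cohort, labels, alphaGlobal = 0.01,
                               alphaGene = NULL) {
    stopifnot(is(cohort, "TumorCohort"),
              length(labels) == ncol(cohort))
    m <- exprMatrix(cohort)
    genes <- setdiff(rownames(m), indexGene(cohort))
    nTests <- length(genes)
    if (is.null(alphaGene))
        alphaGene <- bonferroniThreshold(alphaGlobal, nTests)
    idx <- indexValues(cohort)

    res <- list()
    for (pop in c("low", "intermediate", "high")) {
        sel <- which(labels == pop)
        if (length(sel) < 3L) {
            warning("sub-population '", pop,
                    "' has fewer than 3 patients; skipped")
            next
        }
        xi <- idx[sel]
        if (sd(xi) == 0) {
            warning("index gene constant in sub-population '", pop,
                    "'; skipped")
            next
        }
        sub <- m[genes, sel, drop = FALSE]
        sds <- apply(sub, 1L, sd)
        r <- rep(NA_real_, nTests)
        ok <- sds > 0
        # vectorised Pearson r + t-transform p; equals cor.test per gene
        r[ok] <- as.numeric(cor(t(sub[ok, , drop = FALSE]), xi))
        df <- length(sel) - 2L
        tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
        p <- 2 * pt(-abs(tstat), df)
        res[[pop]] <- data.frame(gene = genes, subpopulation = pop,
                                 r = r, p = p,
                                 significant = !is.na(p) & p < alphaGene,
                                 stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, c(res, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- data.frame(gene = character(), subpopulation = character(),
                          r = numeric(), p = numeric(),
                          significant = logical())
    attr(out, "alphaGene") <- alphaGene
    attr(out, "nTests") <- nTests
    out
}

#' Significant gene sets per sub-population
#'
#' @param screenResult output of [screenCoexpression()].
#' @return named list of significant gene vectors
#'   (`low`/`intermediate`/`high`).
#' @export
significantSets <- function(screenResult) {
    lapply(setNames(nm = c("low", "intermediate", "high")), function(pop) {
        s <- screenResult[screenResult$subpopulation == pop &
                          screenResult$significant, "gene"]
        unique(s)
    })
}

#' Three-way Venn partition of gene sets
#'
#' Exact counts for the seven regions of three sets.
#'
#' @param low,intermediate,high character vectors (gene sets).
#' @return named integer vector: `low_only`, `intermediate_only`,
#'   `high_only`, `low_intermediate`, `low_high`, `intermediate_high`,
#'   `all_three`.
#' @export
vennPartition <- function(low, intermediate, high) {
    low <- unique(low); intermediate <- unique(intermediate)
    high <- unique(high)
    u <- union(union(low, intermediate), high)
    inL <- u %in% low; inI <- u %in% intermediate; inH <- u %in% high
    c(low_only = sum(inL & !inI & !inH),
      intermediate_only = sum(!inL & inI & !inH),
      high_only = sum(!inL & !inI & inH),
      low_intermediate = sum(inL & inI & !inH),
      low_high = sum(inL & !inI & inH),
      intermediate_high = sum(!inL & inI & inH),
      all_three = sum(inL & inI & inH))
}
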