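#' @include cohort.R
NULL

## All randomness flows from one root seed through named substreams so
## that stages can be regenerated independently and a fixed seed gives a
## bitwise-identical cohort.
substreamSeed <- function(seed, stream) {
    offset <- c(mixture = 1L, genes = 2L, clinical = 3L, er = 4L)[[stream]]
    as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate a METABRIC-scale breast-cancer cohort with the
#' statistical structure the deconvolution pipeline assumes: a trimodal
#' Gaussian log2 distribution of the index gene (component weights,
#' means and SDs default to the fitted whole-cohort values 26/38/36%,
#' 6.25/7.89/10.58 and 0.39/1.12/0.86); gene blocks correlated with the
#' index gene only inside the low or high sub-population; independent
#' null genes; a background "absent gene" (SRY analogue, mean 5.4); an
#' ESR1 analogue bimodal by ER status; ER-negative status enriched in
#' the true low component; treatment arms assigned independently of
#' expression; and exponential disease-death times whose log-hazard
#' depends on the index gene only in the chemotherapy arm, competing
#' with other-cause death and censoring.
#'
#' @param nPatients cohort size.
#' @param componentWeights,componentMeans,componentSDs the three mixture
#'   components (weights sum to 1; log2 units).
#' @param nCorrGenesLow,nCorrGenesHigh sizes of the gene blocks
#'   correlated with the index gene only within the low / high
#'   sub-population.
#' @param corrStrength target within-sub-population Pearson r of block
#'   genes with the index gene.
#' @param nNullGenes independent noise genes.
#' @param backgroundGeneMean,backgroundGeneSD log2 parameters of the
#'   absent-gene analogue.
#' @param erNegProbLow,erNegProbOther probability of ER-negative status
#'   given membership of the true low component vs otherwise.
#' @param esr1Means,esr1SDs log2 parameters of the ESR1 analogue for
#'   ER-negative and ER-positive patients (named `negative`, `positive`).
#' @param treatmentProbs arm probabilities, named by [TREATMENT_LEVELS].
#' @param baselineRates per-arm baseline disease-death rate per year.
#' @param logHazardSlopes per-arm log-hazard slope per log2 unit of the
#'   (cohort-mean-centred) index gene; negative means high expression
#'   protects. Default: effect in the chemotherapy arm only.
#' @param otherCauseRate other-cause death rate per year.
#' @param censorHorizon administrative censoring horizon in years
#'   (must exceed 5).
#' @param earlyCensorFrac fraction of patients with an additional
#'   uniform early-censoring time on (0, horizon).
#' @param seed root integer seed for the named substreams.
#' @return a validated `synthetic_config` list.
#' @export
syntheticConfig <- function(nPatients = 1980L,
                            componentWeights = c(0.26, 0.38, 0.36),
                            componentMeans = c(6.25, 7.89, 10.58),
                            componentSDs = c(0.39, 1.12, 0.86),
                            nCorrGenesLow = 50L, nCorrGenesHigh = 50L,
                            corrStrength = 0.6,
                            nNullGenes = 200L,
                            backgroundGeneMean = 5.4,
                            backgroundGeneSD = 0.3,
                            erNegProbLow = 0.7, erNegProbOther = 0.05,
                            esr1Means = c(negative = 6.0, positive = 9.5),
                            esr1SDs = c(negative = 0.7, positive = 0.8),
                            treatmentProbs = c(none = 0.26,
                                               hormone_only = 0.53,
                                               chemo_only = 0.20,
                                               other = 0.01),
                            baselineRates = c(none = 0.06,
                                              hormone_only = 0.06,
                                              chemo_only = 0.10,
                                              other = 0.06),
                            logHazardSlopes = c(none = 0,
                                                hormone_only = 0,
                                                chemo_only = -0.35,
                                                other = 0),
                            otherCauseRate = 0.01,
                            censorHorizon = 12,
                            earlyCensorFrac = 0.15,
                            seed = 1L) {
    cfg <- list(nPatients = as.integer(nPatients),
                componentWeights = componentWeights,
                componentMeans = componentMeans,
                componentSDs = componentSDs,
                nCorrGenesLow = as.integer(nCorrGenesLow),
                nCorrGenesHigh = as.integer(nCorrGenesHigh),
                corrStrength = corrStrength,
                nNullGenes = as.integer(nNullGenes),
                backgroundGeneMean = backgroundGeneMean,
                backgroundGeneSD = backgroundGeneSD,
                erNegProbLow = erNegProbLow,
                erNegProbOther = erNegProbOther,
                esr1Means = esr1Means, esr1SDs = esr1SDs,
                treatmentProbs = treatmentProbs,
                baselineRates = baselineRates,
                logHazardSlopes = logHazardSlopes,
                otherCauseRate = otherCauseRate,
                censorHorizon = censorHorizon,
                earlyCensorFrac = earlyCensorFrac,
                seed = as.integer(seed))
    k <- length(cfg$componentWeights)
    stopifnot(length(cfg$componentMeans) == k,
              length(cfg$componentSDs) == k)
    if (abs(sum(cfg$componentWeights) - 1) > 1e-9)
        stop("componentWeights must sum to 1")
    if (any(cfg$componentWeights < 0)) stop("negative component weight")
    if (any(cfg$componentSDs < 0)) stop("negative component SD")
    p <- c(cfg$erNegProbLow, cfg$erNegProbOther, cfg$treatmentProbs,
           cfg$earlyCensorFrac)
    if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
    if (abs(sum(cfg$treatmentProbs) - 1) > 1e-9)
        stop("treatmentProbs must sum to 1")
    if (!is.na(cfg$censorHorizon) && cfg$censorHorizon <= 5)
        stop("censorHorizon must exceed 5 years")
    stopifnot(setequal(names(cfg$treatmentProbs), TREATMENT_LEVELS),
              setequal(names(cfg$baselineRates), TREATMENT_LEVELS),
              setequal(names(cfg$logHazardSlopes), TREATMENT_LEVELS))
    class(cfg) <- "synthetic_config"
    cfg
}

#' Draw index-gene values from the Gaussian mixture
#'
#' Each patient's component is drawn from `componentWeights` and the
#' value from that component's normal distribution.
#'
#' @param config a [syntheticConfig()].
#' @return list with `values` (log2) and `trueLabels` (component index,
#'   1 = lowest mean).
#' @export
sampleMixture <- function(config) {
    stopifnot(inherits(config, "synthetic_config"))
    set.seed(substreamSeed(config$seed, "mixture"))
    n <- config$nPatients
    k <- length(config$componentWeights)
    labels <- sample.int(k, n, replace = TRUE, prob = config$componentWeights)
    values <- rnorm(n, mean = config$componentMeans[labels],
                    sd = config$componentSDs[labels])
    list(values = values, trueLabels = labels)
}

#' Generate the synthetic expression matrix
#'
#' The index gene row equals `values`. Low-block genes follow
#' `r * z + sqrt(1 - r^2) * noise` of the standardized index gene for
#' patients in the true low component and are independent noise
#' elsewhere; high-block genes analogously for the high component. Null
#' genes are i.i.d. normal, one background gene is
#' `N(backgroundGeneMean, backgroundGeneSD^2)`, and an ESR1 analogue is
#' drawn from the ER-status-specific normals.
#'
#' @param config a [syntheticConfig()].
#' @param values,trueLabels output of [sampleMixture()].
#' @param erStatus optional per-patient ER status; when `NULL` it is
#'   sampled from the configured ER model.
#' @param indexGene row name for the index gene.
#' @return genes-by-patients log2 matrix (index gene, `LOWCOR*`,
#'   `HIGHCOR*`, `NULLG*`, `SRY`, `ESR1`).
#' @export
generateExpression <- function(config, values, trueLabels, erStatus = NULL,
                               indexGene = "NAT1") {
    stopifnot(inherits(config, "synthetic_config"),
              length(values) == length(trueLabels))
    n <- length(values)
    if (is.null(erStatus)) {
        set.seed(substreamSeed(config$seed, "er"))
        pneg <- ifelse(trueLabels == 1L, config$erNegProbLow,
                       config$erNegProbOther)
        erStatus <- ifelse(runif(n) < pneg, "negative", "positive")
    }
    set.seed(substreamSeed(config$seed, "genes"))
    lowIdx <- which(trueLabels == 1L)
    highIdx <- which(trueLabels == max(trueLabels))

    blockGene <- function(groupIdx, r, mu, sigma) {
        g <- rnorm(n, mu, sigma)               # independent outside the group
        if (length(groupIdx) >= 2L && r != 0) {
            v <- values[groupIdx]
            z <- (v - mean(v)) / sd(v)
            g[groupIdx] <- mu + sigma * (r * z +
                sqrt(1 - r^2) * rnorm(length(groupIdx)))
        }
        g
    }

    nl <- config$nCorrGenesLow; nh <- config$nCorrGenesHigh
    nn <- config$nNullGenes
    rows <- vector("list", 1L + nl + nh + nn + 2L)
    nm <- character(length(rows))
    rows[[1L]] <- values; nm[1L] <- indexGene
    j <- 1L
    for (i in seq_len(nl)) {
        j <- j + 1L
        rows[[j]] <- blockGene(lowIdx, config$corrStrength, 8, 1)
        nm[j] <- sprintf("LOWCOR%03d", i)
    }
    for (i in seq_len(nh)) {
        j <- j + 1L
        rows[[j]] <- blockGene(highIdx, config$corrStrength, 8, 1)
        nm[j] <- sprintf("HIGHCOR%03d", i)
    }
    for (i in seq_len(nn)) {
        j <- j + 1L
        rows[[j]] <- rnorm(n, 8, 1)
        nm[j] <- sprintf("NULLG%03d", i)
    }
    rows[[j + 1L]] <- rnorm(n, config$backgroundGeneMean,
                            config$backgroundGeneSD)
    nm[j + 1L] <- "SRY"
    esr <- ifelse(erStatus == "negative",
                  rnorm(n, config$esr1Means[["negative"]],
                        config$esr1SDs[["negative"]]),
                  rnorm(n, config$esr1Means[["positive"]],
                        config$esr1SDs[["positive"]]))
    rows[[j + 2L]] <- esr
    nm[j + 2L] <- "ESR1"

    m <- do.call(rbind, rows)
    dimnames(m) <- list(nm, sprintf("P%05d", seq_len(n)))
    m
}

#' Generate the synthetic clinical table
#'
#' ER status is sampled from the component-conditional model; the
#' treatment arm is independent of expression; disease-death times are
#' exponential with rate
#' `baselineRates[arm] * exp(logHazardSlopes[arm] * (value - mean(values)))`,
#' competing with exponential other-cause death and with administrative
#' (plus optional uniform early) censoring. The outcome is the earliest
#' event; survival time is truncated at the horizon.
#'
#' @inheritParams generateExpression
#' @return canonical clinical data.frame with an extra `true_component`
#'   column.
#' @export
generateClinical <- function(config, values, trueLabels) {
    stopifnot(inherits(config, "synthetic_config"),
              length(values) == length(trueLabels))
    n <- length(values)
    set.seed(substreamSeed(config$seed, "er"))
    pneg <- ifelse(trueLabels == 1L, config$erNegProbLow,
                   config$erNegProbOther)
    er <- ifelse(runif(n) < pneg, "negative", "positive")

    set.seed(substreamSeed(config$seed, "clinical"))
    arms <- names(config$treatmentProbs)
    treatment <- arms[sample.int(length(arms), n, replace = TRUE,
                                 prob = config$treatmentProbs)]
    centred <- values - mean(values)
    rate <- unname(config$baselineRates[treatment] *
                   exp(unname(config$logHazardSlopes[treatment]) * centred))
    rexpSafe <- function(n, rate) {
        t <- rep(Inf, n)
        pos <- rate > 0
        t[pos] <- rexp(sum(pos), rate[pos])
        t
    }
    tDisease <- rexpSafe(n, rate)
    tOther <- rexpSafe(n, rep(config$otherCauseRate, n))
    tCensor <- rep(config$censorHorizon, n)
    early <- runif(n) < config$earlyCensorFrac
    u <- runif(n, 0, min(config$censorHorizon, 1e6))
    tCensor[early] <- pmin(tCensor[early], u[early])

    time <- pmin(tDisease, tOther, tCensor)
    # ties: events precede censoring at the same time
    outcome <- ifelse(tDisease <= time & tDisease <= tOther,
                      "died_of_disease",
                      ifelse(tOther <= time, "died_other_cause", "alive"))
    data.frame(patient_id = sprintf("P%05d", seq_len(n)),
               er_status = er, treatment = treatment,
               survival_time = pmin(time, config$censorHorizon),
               outcome = outcome,
               age_at_diagnosis = round(runif(n, 30, 85), 1),
               tumor_size = round(runif(n, 5, 60), 1),
               true_component = trueLabels,
               stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Composes [sampleMixture()], [generateClinical()] and
#' [generateExpression()] (ER status shared between the clinical table
#' and the ESR1 analogue) into a validated [TumorCohort-class]. A fixed
#' seed yields a bitwise-identical cohort.
#'
#' @param config a [syntheticConfig()].
#' @param indexGene index gene symbol.
#' @return a `TumorCohort`; the true component labels are in
#'   `clinicalData(x)$true_component` and in
#'   `S4Vectors::metadata(x)$trueLabels`.
#' @export
generateCohort <- function(config = syntheticConfig(), indexGene = "NAT1") {
    sm <- sampleMixture(config)
    clin <- generateClinical(config, sm$values, sm$trueLabels)
    expr <- generateExpression(config, sm$values, sm$trueLabels,
                               erStatus = clin$er_status,
                               indexGene = indexGene)
    coh <- TumorCohort(expr, clin, indexGene = indexGene)
    S4Vectors::metadata(coh)$trueLabels <- sm$trueLabels
    S4Vectors::metadata(coh)$syntheticConfig <- config
    coh
}
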