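#' @include synthetic.R mixture.R assignment.R coexpression.R survival.R response.R normality.R
NULL

#' Default pipeline configuration
#'
#' Returns the full stage-parameter list used by [runPipeline()]:
#' either a `synthetic` section (passed to [syntheticConfig()]) or an
#' `input` section (`expression`, `clinical` TSV paths and reader
#' options), plus the index gene, bin width, component selection,
#' sub-population windows, screening level, survival table settings and
#' the response-analysis arm and threshold. Values can be overridden by
#' a named list or by a YAML file with the same structure.
#'
#' @param overrides named list (possibly nested) of overrides.
#' @return validated config list.
#' @export
pipelineConfig <- function(overrides = list()) {
    cfg <- list(
        synthetic = list(),          # syntheticConfig() arguments
        input = NULL,                # or list(expression=, clinical=, ...)
        index_gene = "NAT1",
        bin_width = 0.2,
        bin_anchor = 0,
        components = "auto",         # "auto" or 1/2/3
        n_starts = 3,
        scheme = list(low = c(5, 6.5), intermediate = c(7.25, 8.5),
                      high = c(10, 13)),
        alpha_global = 0.01,
        alpha_gene = NULL,
        survival_interval = 2,
        survival_horizon = NULL,
        response_arm = "chemo_only",
        threshold_years = 5,
        seed = 1L)
    cfg <- utils::modifyList(cfg, overrides)
    if (!is.null(cfg$input) && length(cfg$synthetic) &&
        !identical(cfg$synthetic, list()))
        stop("exactly one of 'input' and 'synthetic' may be configured")
    stopifnot(cfg$bin_width > 0,
              cfg$alpha_global > 0, cfg$alpha_global <= 1,
              cfg$threshold_years > 0,
              cfg$response_arm %in% TREATMENT_LEVELS,
              identical(cfg$components, "auto") ||
                  cfg$components %in% 1:3)
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipelineConfig()].
#' @return validated config list.
#' @export
readPipelineConfig <- function(path) {
    raw <- yaml::read_yaml(path)
    for (s in intersect(names(raw$scheme), c("low", "intermediate", "high")))
        raw$scheme[[s]] <- as.numeric(raw$scheme[[s]])
    pipelineConfig(raw)
}

stageFile <- function(dir, name) file.path(dir, name)

writeStageTSV <- function(df, path, seed) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# trimix %s stage output; seed=%d",
                       as.character(utils::packageVersion("trimix")), seed),
               con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

htestRow <- function(name, h)
    data.frame(test = name, statistic = unname(h$statistic[1]),
               df = paste(unname(h$parameter), collapse = ","),
               p = h$p.value, stringsAsFactors = FALSE)

#' Run the full deconvolution-and-outcome pipeline
#'
#' Executes the stages in order — cohort acquisition (synthetic
#' generation or TSV input), binning and mixture fitting, window
#' assignment with misassignment estimates, per-sub-population
#' co-expression screening, survival comparison (Kaplan-Meier curves,
#' Mantel-Cox and trend and Gehan-Breslow-Wilcoxon tests, at-risk
#' table) and the treatment-response analysis (classification, survival
#' bins, ANOVA/trend, decision curve). Each stage's tabular output is
#' persisted under `outputDir` with a provenance header; an identical
#' config and seed yields byte-identical outputs. A stage failure
#' aborts with the stage name; outputs of earlier stages are retained.
#'
#' @param config a [pipelineConfig()] list or path to a YAML file.
#' @param outputDir directory for the report bundle (created).
#' @return invisibly, a list with every stage result.
#' @export
runPipeline <- function(config = pipelineConfig(), outputDir = tempfile()) {
    if (is.character(config)) config <- readPipelineConfig(config)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    yaml::write_yaml(config, stageFile(outputDir, "config.yaml"))
    seed <- as.integer(config$seed)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }

    ## --- cohort -------------------------------------------------------
    cohort <- stage("cohort", {
        if (!is.null(config$input)) {
            inp <- config$input
            expr <- readExpression(inp$expression,
                orientation = if (is.null(inp$orientation)) "genes_in_rows"
                              else inp$orientation)
            clin <- readClinical(inp$clinical)
            TumorCohort(expr, clin, indexGene = config$index_gene)
        } else {
            sc <- do.call(syntheticConfig,
                          utils::modifyList(config$synthetic,
                                            list(seed = seed), keep.null = TRUE))
            generateCohort(sc, indexGene = config$index_gene)
        }
    })
    values <- indexValues(cohort)
    clin <- clinicalData(cohort)

    ## --- mixture fit --------------------------------------------------
    fit <- stage("fit", {
        freq <- binValues(values, binWidth = config$bin_width,
                          anchor = config$bin_anchor)
        if (identical(config$components, "auto"))
            selectModel(freq, nStarts = config$n_starts, seed = seed)
        else fitMixture(freq, config$components,
                        nStarts = config$n_starts, seed = seed)
    })
    norm <- stage("fit", ksNormality(values))
    writeStageTSV(data.frame(center = binCenters(fit@freq),
                             observed = binCounts(fit@freq),
                             predicted = predictedCounts(fit)),
                  stageFile(outputDir, "bins.tsv"), seed)
    jsonlite::write_json(
        list(components = componentTable(fit),
             converged = isConverged(fit),
             rObsPred = fit@rObsPred, syx = fit@syx,
             ksDistance = unname(norm$statistic),
             ksP = norm$p.value, seed = seed),
        stageFile(outputDir, "mixture_fit.json"),
        auto_unbox = TRUE, digits = NA)

    ## --- assignment ---------------------------------------------------
    scheme <- SubpopulationScheme(config$scheme$low,
                                  config$scheme$intermediate,
                                  config$scheme$high)
    labels <- stage("assign", assignSubpopulations(values, scheme))
    if (all(labels == "unassigned"))
        warning("assignment stage: all patients unassigned ",
                "(windows may not match this cohort)")
    mis <- stage("assign", {
        if (nrow(fit@components) == 3L && isConverged(fit))
            misassignment(fit, scheme)
        else {
            warning("assignment stage: no converged 3-component fit; ",
                    "misassignment estimates unavailable")
            NULL
        }
    })
    writeStageTSV(data.frame(patient_id = colnames(cohort),
                             value = unname(values),
                             label = as.character(labels)),
                  stageFile(outputDir, "labels.tsv"), seed)
    if (!is.null(mis))
        writeStageTSV(data.frame(window = names(mis),
                                 misassignment_pct = as.numeric(mis)),
                      stageFile(outputDir, "misassignment.tsv"), seed)

    ## --- co-expression screen ----------------------------------------
    screen <- stage("coexpress",
        screenCoexpression(cohort, labels,
                           alphaGlobal = config$alpha_global,
                           alphaGene = config$alpha_gene))
    sets <- significantSets(screen)
    venn <- vennPartition(sets$low, sets$intermediate, sets$high)
    for (pop in unique(screen$subpopulation))
        writeStageTSV(screen[screen$subpopulation == pop, ],
                      stageFile(outputDir,
                                sprintf("coexpression_%s.tsv", pop)), seed)
    writeStageTSV(data.frame(region = names(venn), genes = as.integer(venn)),
                  stageFile(outputDir, "venn.tsv"), seed)

    ## --- survival -----------------------------------------------------
    surv <- stage("survival", {
        si <- survivalInputs(clin)
        grp <- droplevels(labels[labels != "unassigned"])
        keep <- labels != "unassigned"
        tests <- list()
        curves <- list()
        if (nlevels(grp) >= 2L && sum(si$events[keep]) > 0) {
            tests$mantel_cox <- logrank(si$times[keep], si$events[keep], grp)
            tests$gehan_breslow_wilcoxon <-
                logrank(si$times[keep], si$events[keep], grp,
                        weighting = "gehan_breslow_wilcoxon")
            if (nlevels(grp) >= 3L)
                tests$trend <- logrankTrend(si$times[keep], si$events[keep],
                                            grp)
            for (g in levels(grp)) {
                sel <- keep & labels == g
                curves[[g]] <- kmCurve(si$times[sel], si$events[sel])
            }
        }
        horizon <- if (is.null(config$survival_horizon)) max(si$times)
                   else config$survival_horizon
        atRisk <- if (nlevels(grp) >= 1L)
            atRiskTable(si$times[keep], grp,
                        interval = config$survival_interval,
                        horizon = horizon)
        else NULL
        list(tests = tests, curves = curves, atRisk = atRisk)
    })
    for (g in names(surv$curves))
        writeStageTSV(with(surv$curves[[g]],
                           data.frame(time = eventTimes, survival = survival,
                                      nAtRisk = nAtRisk, events = nEvents)),
                      stageFile(outputDir, sprintf("km_%s.tsv", g)), seed)
    if (length(surv$tests))
        writeStageTSV(do.call(rbind, Map(htestRow, names(surv$tests),
                                         surv$tests)),
                      stageFile(outputDir, "survival_tests.tsv"), seed)
    if (!is.null(surv$atRisk))
        writeStageTSV(data.frame(group = rownames(surv$atRisk),
                                 surv$atRisk, check.names = FALSE),
                      stageFile(outputDir, "at_risk.tsv"), seed)

    ## --- treatment response -------------------------------------------
    resp <- stage("response", {
        cls <- classifyPatients(clin, arm = config$response_arm,
                                threshold = config$threshold_years)
        bins <- survivalBins(clin, values, cls,
                             threshold = config$threshold_years)
        memb <- binMembership(clin, cls, threshold = config$threshold_years)
        tests <- if (sum(!is.na(memb)) >= 3 &&
                     length(unique(memb[!is.na(memb)])) >= 2)
            anovaTrend(values, memb) else NULL
        dc <- if (any(cls$status == "resistant") &&
                  any(cls$status == "sensitive"))
            decisionCurve(values, cls$status) else NULL
        list(classification = cls, bins = bins, tests = tests,
             decision = dc,
             yearsPerLog2 = yearsPerLog2(bins, config$threshold_years))
    })
    writeStageTSV(resp$classification,
                  stageFile(outputDir, "response_classification.tsv"), seed)
    writeStageTSV(resp$bins, stageFile(outputDir, "response_bins.tsv"), seed)
    if (!is.null(resp$tests))
        writeStageTSV(rbind(htestRow("anova", resp$tests$anova),
                            htestRow("trend", resp$tests$trend)),
                      stageFile(outputDir, "response_tests.tsv"), seed)
    if (!is.null(resp$decision)) {
        dc <- resp$decision
        writeStageTSV(data.frame(cutoff = dc@cutoffs,
                                 sensitivity = dc@sensitivity,
                                 specificity = dc@specificity),
                      stageFile(outputDir, "decision_curve.tsv"), seed)
        writeStageTSV(data.frame(crossover_cutoff = dc@crossoverCutoff,
                                 crossover_value = dc@crossoverValue,
                                 years_per_log2 = resp$yearsPerLog2),
                      stageFile(outputDir, "crossover.tsv"), seed)
    }

    writeSummary(outputDir, fit, norm, mis, venn, surv, resp, seed)
    invisible(list(cohort = cohort, fit = fit, normality = norm,
                   scheme = scheme, labels = labels, misassignment = mis,
                   screen = screen, venn = venn, survival = surv,
                   response = resp, outputDir = outputDir))
}

writeSummary <- function(dir, fit, norm, mis, venn, surv, resp, seed) {
    con <- file(stageFile(dir, "summary.txt"), "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("trimix pipeline summary (seed %d)", seed)
    w("")
    w("Mixture deconvolution (%d component(s), %s):",
      nrow(fit@components), if (isConverged(fit)) "converged"
                            else "not converged")
    tbl <- componentTable(fit)
    w("  %-10s %9s %7s %6s %9s %7s", "component", "amplitude", "mean",
      "sd", "patients", "pct")
    n <- nTotal(fit@freq)
    for (i in seq_len(nrow(tbl)))
        w("  %-10d %9.2f %7.2f %6.2f %9.0f %6.1f%%", i, tbl$amplitude[i],
          tbl$mean[i], tbl$sd[i], tbl$weight[i] * n, tbl$weight[i] * 100)
    w("  r(obs,pred) = %.4f, Sy.x = %.3f, K-S D = %.4f (p = %.3g)",
      fit@rObsPred, fit@syx, unname(norm$statistic), norm$p.value)
    if (!is.null(mis)) {
        w("")
        w("Expected misassignment: %s",
          paste(sprintf("%s %.1f%%", names(mis), mis), collapse = ", "))
    }
    w("")
    w("Venn partition of significant co-expressed genes:")
    for (r in names(venn)) w("  %-18s %d", r, venn[[r]])
    if (length(surv$tests)) {
        w("")
        w("Survival tests across sub-populations:")
        for (nm in names(surv$tests))
            w("  %-24s chi2 = %8.3f, p = %.3g", nm,
              unname(surv$tests[[nm]]$statistic),
              surv$tests[[nm]]$p.value)
    }
    w("")
    w("Treatment response (%d resistant, %d sensitive, %d excluded):",
      sum(resp$classification$status == "resistant"),
      sum(resp$classification$status == "sensitive"),
      sum(resp$classification$status == "excluded"))
    if (!is.null(resp$tests))
        w("  ANOVA p = %.3g, trend p = %.3g",
          resp$tests$anova$p.value, resp$tests$trend$p.value)
    if (!is.null(resp$decision))
        w("  decision-curve cross-over: cutoff %.2f, rate %.3f; %.2f years per log2 unit",
          resp$decision@crossoverCutoff, resp$decision@crossoverValue,
          resp$yearsPerLog2)
    invisible(NULL)
}
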