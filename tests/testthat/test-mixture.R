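test_that("gaussianSum matches closed-form evaluations", {
    one <- data.frame(amplitude = 1, mean = 0, sd = 1)
    expect_equal(gaussianSum(0, one), 1)
    expect_equal(gaussianSum(1, one), exp(-0.5))
    # whole-cohort components at the low mean: amplitude plus the
    # intermediate component's tail (hand-computed)
    expect_equal(gaussianSum(6.25, cohortFitAll),
                 104 + 54 * exp(-0.5 * ((6.25 - 7.89) / 1.12)^2) +
                 68 * exp(-0.5 * ((6.25 - 10.58) / 0.86)^2))
    expect_equal(gaussianSum(6.25, cohortFitAll), 122.484, tolerance = 1e-5)
})

test_that("component areas and normalised weights reproduce the printed percentage arithmetic", {
    expect_equal(componentAUC(1, 1), sqrt(2 * pi), tolerance = 1e-9)
    expect_equal(componentAUC(104, 0.39), 101.67, tolerance = 1e-3)
    auc <- componentAUC(cohortFitAll$amplitude, cohortFitAll$sd)
    w <- auc / sum(auc)
    expect_equal(w, c(0.2543, 0.3791, 0.3666), tolerance = 1e-3)
})

test_that("noiseless two-component data are recovered to high precision", {
    truth <- data.frame(amplitude = c(80, 50), mean = c(4, 9),
                        sd = c(0.5, 1.2))
    edges <- seq(2, 13, by = 0.2)
    centers <- edges[-length(edges)] + 0.1
    y <- gaussianSum(centers, truth)
    freq <- new("BinnedFrequency", binWidth = 0.2,
                leftEdges = edges[-length(edges)],
                counts = as.integer(round(y)))
    # counts are rounded to integers, so compare against the rounded target
    fit <- fitMixture(freq, 2, nStarts = 4, seed = 1)
    expect_true(isConverged(fit))
    refit <- fitMixture(freq, 2, nStarts = 4, seed = 99)
    expect_equal(fit@components, refit@components, tolerance = 1e-4)
    expect_equal(fit@components$mean, truth$mean, tolerance = 1e-2)
    expect_equal(fit@components$sd, truth$sd, tolerance = 1e-2)

    # with exact (unrounded) counts stored as doubles the recovery is
    # essentially exact
    freq2 <- new("BinnedFrequency", binWidth = 0.2,
                 leftEdges = edges[-length(edges)],
                 counts = as.integer(round(y * 1e6)))
    fit2 <- fitMixture(freq2, 2, nStarts = 4, seed = 1)
    expect_equal(fit2@components$mean, truth$mean, tolerance = 1e-6)
    expect_equal(fit2@components$sd, truth$sd, tolerance = 1e-6)
    expect_equal(fit2@components$amplitude, truth$amplitude * 1e6,
                 tolerance = 1e-4)
})

test_that("three-component fit on synthetic whole-cohort draws meets the quality bar", {
    cfg <- syntheticConfig(seed = 11)
    freq <- binValues(sampleMixture(cfg)$values)
    fit <- fitMixture(freq, 3, nStarts = 5, seed = 11)
    expect_true(isConverged(fit))
    expect_lt(abs(max(fit@components$mean) - 10.58), 0.4)
    expect_lt(abs(min(fit@components$mean) - 6.25), 0.1)
    expect_gte(fit@rObsPred, 0.96)
    # one component cannot describe trimodal data as well
    fit1 <- fitMixture(freq, 1, nStarts = 3, seed = 11)
    expect_lt(fit1@rObsPred, fit@rObsPred - 0.02)
    expect_gt(fit1@syx, fit@syx)
})

test_that("components are reported sorted by mean regardless of start order", {
    cfg <- syntheticConfig(seed = 13)
    freq <- binValues(sampleMixture(cfg)$values)
    for (s in c(1, 7, 123)) {
        fit <- fitMixture(freq, 3, nStarts = 4, seed = s)
        expect_false(is.unsorted(fit@components$mean))
    }
})

test_that("predicted mass equals the component areas for separated fits", {
    truth <- data.frame(amplitude = c(100, 60), mean = c(3, 10),
                        sd = c(0.6, 0.9))
    edges <- seq(0, 14, by = 0.2)
    centers <- edges[-length(edges)] + 0.1
    freq <- new("BinnedFrequency", binWidth = 0.2,
                leftEdges = edges[-length(edges)],
                counts = as.integer(round(gaussianSum(centers, truth))))
    fit <- fitMixture(freq, 2, nStarts = 3, seed = 2)
    riemann <- sum(predictedCounts(fit)) * binWidth(freq)
    expect_lt(abs(riemann - sum(fit@aucs)) / sum(fit@aucs), 0.02)
})

test_that("binned least squares agrees with a raw-value EM fit", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))   # Mclust needs its namespace attached
    set.seed(17)
    n <- 5000
    lab <- sample(1:2, n, TRUE, prob = c(0.4, 0.6))
    v <- rnorm(n, c(5, 9)[lab], c(0.7, 1.0)[lab])
    fit <- fitMixture(binValues(v, 0.2), 2, nStarts = 4, seed = 17)
    em <- mclust::Mclust(v, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(fit@weights), sort(unname(em$parameters$pro)),
                 tolerance = 0.05)
    expect_equal(sort(fit@components$mean),
                 sort(unname(em$parameters$mean)), tolerance = 0.1)
})

test_that("recovered means are unbiased at cohort scale over many seeds", {
    err <- t(vapply(1:20, function(s) {
        cfg <- syntheticConfig(seed = 900 + s)
        fit <- fitMixture(binValues(sampleMixture(cfg)$values), 3,
                          nStarts = 4, seed = s)
        abs(fit@components$mean - c(6.25, 7.89, 10.58))
    }, numeric(3)))
    med <- apply(err, 2, median)
    expect_lt(med[1], 0.1)
    expect_lt(med[3], 0.1)
    # the broad intermediate component has sampling SD ~0.15 at this n;
    # its median error is bounded accordingly
    expect_lt(med[2], 0.25)
})

test_that("model selection picks the generative component count", {
    # trimodal cohort -> 3
    cfg <- syntheticConfig(seed = 19)
    sel <- selectModel(binValues(sampleMixture(cfg)$values), seed = 19)
    expect_equal(nrow(sel@components), 3L)

    # single Gaussian -> 1
    cfg1 <- syntheticConfig(componentWeights = c(1, 0, 0),
                            componentMeans = c(8, 0, 0),
                            componentSDs = c(1, 1, 1), seed = 23)
    sel1 <- selectModel(binValues(sampleMixture(cfg1)$values), seed = 23)
    expect_equal(nrow(sel1@components), 1L)

    # two well-separated components -> 2
    cfg2 <- syntheticConfig(componentWeights = c(0.5, 0.5, 0),
                            componentMeans = c(5, 10, 0),
                            componentSDs = c(0.5, 0.5, 1), seed = 29)
    sel2 <- selectModel(binValues(sampleMixture(cfg2)$values), seed = 29)
    expect_equal(nrow(sel2@components), 2L)
    expect_named(sel2@candidates, c("1", "2", "3", "aicc"),
                 ignore.order = TRUE)
})

test_that("fitMixture guards its preconditions", {
    freq <- binValues(rnorm(100), 0.5)
    expect_error(fitMixture(freq, 4), "1, 2 or 3")
    tiny <- new("BinnedFrequency", binWidth = 1,
                leftEdges = c(0, 1, 2, 3), counts = c(1L, 5L, 5L, 1L))
    expect_error(fitMixture(tiny, 2), "too few bins")
})
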