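test_that("response classification applies the two exclusion rules exactly", {
    clin <- data.frame(
        patient_id = paste0("P", 1:6),
        er_status = "positive",
        treatment = c(rep("chemo_only", 5), "hormone_only"),
        survival_time = c(3, 3, 4, 5, 7, 2),
        outcome = c("died_of_disease", "died_other_cause", "alive",
                    "died_of_disease", "alive", "died_of_disease"),
        stringsAsFactors = FALSE)
    got <- classifyPatients(clin)
    expect_equal(as.character(got$status),
                 c("resistant",   # died of disease at 3y
                   "excluded",    # died of other cause before 5y
                   "excluded",    # alive, follow-up < 5y
                   "sensitive",   # death at exactly 5y: boundary to sensitive
                   "sensitive",   # survived past 5y
                   "excluded"))   # wrong arm
    expect_equal(as.character(got$exclusion_reason),
                 c("none", "died_other_cause_lt5y", "followup_lt5y",
                   "none", "none", "not_in_arm"))
    # excluded if and only if a reason is recorded
    expect_identical(got$status == "excluded",
                     got$exclusion_reason != "none")
})

test_that("survival bins use completed years and a final long-survivor bin", {
    clin <- data.frame(
        patient_id = paste0("P", 1:5),
        er_status = "positive", treatment = "chemo_only",
        survival_time = c(0.5, 1.2, 4.9, 6, 8),
        outcome = c("died_of_disease", "died_of_disease",
                    "died_of_disease", "alive", "died_of_disease"),
        stringsAsFactors = FALSE)
    v <- c(5, 6, 7, 9, 10)
    cls <- classifyPatients(clin)
    bins <- survivalBins(clin, v, cls)
    expect_equal(bins$n, c(1L, 1L, 0L, 0L, 1L, 2L))
    expect_equal(bins$meanExpression, c(5, 6, NA, NA, 7, 9.5))
    expect_equal(as.character(bins$bin), c("1", "2", "3", "4", "5", ">5"))

    # everyone surviving the threshold: one populated bin only
    clin$survival_time <- rep(9, 5); clin$outcome <- "alive"
    bins2 <- survivalBins(clin, v, classifyPatients(clin))
    expect_equal(bins2$n, c(0L, 0L, 0L, 0L, 0L, 5L))
})

test_that("one-way ANOVA and linear trend match hand calculations", {
    got <- anovaTrend(c(1, 2, 3, 4, 5, 6), rep(1:2, each = 3))
    expect_equal(unname(got$anova$statistic), 13.5, tolerance = 1e-12)
    expect_equal(unname(got$anova$parameter), c(1, 4))
    expect_equal(got$anova$p.value, pf(13.5, 1, 4, lower.tail = FALSE))
    expect_equal(got$anova$p.value, 0.0213, tolerance = 1e-3)

    # flat bins: F = 0, p = 1
    flat <- anovaTrend(rep(c(1, 2, 3), 3), rep(1:3, each = 3))
    expect_equal(unname(flat$anova$statistic), 0)
    expect_equal(flat$anova$p.value, 1)

    # cross-check against the built-in ANOVA machinery
    set.seed(9)
    v <- rnorm(60, rep(c(0, 0.4, 1.1), each = 20))
    b <- rep(1:3, each = 20)
    got2 <- anovaTrend(v, b)
    ref <- summary(stats::aov(v ~ factor(b)))[[1]]
    expect_equal(unname(got2$anova$statistic), ref[["F value"]][1],
                 tolerance = 1e-10)
    expect_equal(got2$anova$p.value, ref[["Pr(>F)"]][1], tolerance = 1e-10)

    # tight linear means: the focused trend test is far more sensitive
    set.seed(10)
    v3 <- rnorm(150, rep(seq(0, 0.4, length.out = 5), each = 30), 1)
    b3 <- rep(1:5, each = 30)
    got3 <- anovaTrend(v3, b3)
    expect_lt(got3$trend$p.value, got3$anova$p.value)

    expect_error(anovaTrend(1:5, rep(1, 5)), "at least 2")
})

test_that("chemo-arm bins rise with survival time; untreated arms stay flat", {
    rising <- vapply(1:20, function(s) {
        cfg <- syntheticConfig(nPatients = 2000, seed = 5000 + s)
        sm <- sampleMixture(cfg)
        clin <- generateClinical(cfg, sm$values, sm$trueLabels)
        cls <- classifyPatients(clin, arm = "chemo_only")
        bins <- survivalBins(clin, sm$values, cls)
        m <- bins$meanExpression[bins$n > 0]
        mean(diff(m) >= 0) >= 0.5 && m[length(m)] > m[1]
    }, logical(1))
    expect_gt(mean(rising), 0.5)

    # slope-free arm: trend p-values behave like a null
    ps <- vapply(1:20, function(s) {
        cfg <- syntheticConfig(nPatients = 1500, seed = 5100 + s)
        sm <- sampleMixture(cfg)
        clin <- generateClinical(cfg, sm$values, sm$trueLabels)
        cls <- classifyPatients(clin, arm = "none")
        memb <- trimix:::binMembership(clin, cls)
        anovaTrend(sm$values, memb)$trend$p.value
    }, numeric(1))
    expect_gt(mean(ps > 0.05), 0.5)
})

test_that("decision curve handles perfect, chance and overlapping classes", {
    # perfect separation
    v <- c(rnorm(50, 4, 0.3), rnorm(50, 9, 0.3))
    st <- rep(c("resistant", "sensitive"), each = 50)
    dc <- decisionCurve(v, st, grid = 6.5)
    expect_equal(dc@sensitivity, 1)
    expect_equal(dc@specificity, 1)

    # chance performance: crossover value near 0.5
    set.seed(12)
    v2 <- rnorm(4000, 7, 1)
    st2 <- rep(c("resistant", "sensitive"), 2000)
    dc2 <- decisionCurve(v2, st2)
    expect_lt(abs(crossover(dc2)[["value"]] - 0.5), 0.05)

    expect_error(decisionCurve(v, rep("resistant", 100)), "non-empty")
})

test_that("decision-curve endpoints, monotonicity and crossover consistency hold", {
    set.seed(13)
    v <- c(rnorm(300, 6, 0.5), rnorm(300, 7, 0.5))
    st <- rep(c("resistant", "sensitive"), each = 300)
    dc <- decisionCurve(v, st, grid = seq(3, 10, by = 0.05))
    expect_equal(dc@sensitivity[1], 0)
    expect_equal(dc@sensitivity[length(dc@cutoffs)], 1)
    expect_equal(dc@specificity[1], 1)
    expect_equal(dc@specificity[length(dc@cutoffs)], 0)
    expect_true(all(diff(dc@sensitivity) >= 0))
    expect_true(all(diff(dc@specificity) <= 0))

    # interpolated sensitivity and specificity agree at the crossover
    co <- crossover(dc)
    sAt <- stats::approx(dc@cutoffs, dc@sensitivity, co[["cutoff"]])$y
    pAt <- stats::approx(dc@cutoffs, dc@specificity, co[["cutoff"]])$y
    expect_lt(abs(sAt - pAt), 1e-9)
    expect_equal(co[["value"]], sAt, tolerance = 1e-9)
})

test_that("symmetric normal classes cross at the midpoint with rate Phi(1)", {
    set.seed(14)
    n <- 20000
    v <- c(rnorm(n, 6, 0.5), rnorm(n, 7, 0.5))
    st <- rep(c("resistant", "sensitive"), each = n)
    co <- crossover(decisionCurve(v, st))
    expect_lt(abs(co[["cutoff"]] - 6.5), 0.03)
    expect_lt(abs(co[["value"]] - pnorm(1)), 0.02)
})

test_that("years-per-log2 summarises the bin-mean gradient", {
    bins <- data.frame(bin = factor(c(as.character(1:5), ">5"),
                                    levels = c(as.character(1:5), ">5")),
                       score = 1:6,
                       n = c(10, 10, 10, 10, 10, 50),
                       meanExpression = c(6.0, 6.4, 6.8, 7.2, 7.6, 9))
    # bin means rise 0.4 log2 units per year -> 2.5 years per log2 unit
    expect_equal(yearsPerLog2(bins), 2.5, tolerance = 1e-12)
})
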