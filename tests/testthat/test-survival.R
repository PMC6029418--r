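# Frozen three-group dataset for the weighted log-rank oracles; the
# expected statistics were computed once with an independent reference
# implementation of the same weightings and are asserted to full
# reported precision.
oracleData <- function() {
    list(times = c(1, 2, 2, 3.5, 4, 5, 6.5, 7, 8, 9,
                   0.5, 1.5, 2, 2.5, 3, 3, 4.5, 5.5, 6, 10,
                   2, 3, 4, 6, 7.5, 8.5, 9.5, 10, 11, 12),
         events = c(1, 1, 0, 1, 1, 0, 1, 0, 1, 1,
                    1, 1, 1, 0, 1, 1, 1, 1, 0, 0,
                    1, 0, 1, 1, 0, 1, 0, 1, 0, 0),
         group = rep(c("A", "B", "C"), each = 10))
}

test_that("product-limit estimates match hand-computed step functions", {
    km <- kmCurve(c(1, 2, 3), c(1, 1, 0))
    expect_equal(km$eventTimes, c(1, 2))
    expect_equal(km$survival, c(2 / 3, 1 / 3))
    expect_equal(kmSurvivalAt(km, c(0.5, 1, 2.5, 3)),
                 c(1, 2 / 3, 1 / 3, 1 / 3))

    # all censored: survival stays at 1
    km2 <- kmCurve(c(1, 2, 3), c(0, 0, 0))
    expect_equal(kmSurvivalAt(km2, c(0, 5)), c(1, 1))

    # tied events share a risk set
    km3 <- kmCurve(c(1, 1, 2), c(1, 1, 1))
    expect_equal(km3$survival, c(1 / 3, 0))
})

test_that("Kaplan-Meier agrees with the reference implementation on random data", {
    skip_if_not_installed("survival")
    for (s in 1:50) {
        set.seed(s)
        n <- sample(10:80, 1)
        t <- round(rexp(n, 0.2), 2)
        e <- rbinom(n, 1, 0.7)
        if (sum(e) == 0) e[1] <- 1
        km <- kmCurve(t, e)
        sf <- survival::survfit(survival::Surv(t, e) ~ 1)
        ref <- summary(sf, times = km$eventTimes)
        expect_equal(km$survival, ref$surv, tolerance = 1e-10)
        expect_equal(km$nAtRisk, ref$n.risk, tolerance = 1e-10)
    }
})

test_that("log-rank statistics reproduce frozen reference values", {
    d <- oracleData()
    two <- d$group != "C"
    mc2 <- logrank(d$times[two], d$events[two], d$group[two])
    expect_equal(unname(mc2$statistic), 0.301214315244, tolerance = 1e-9)
    expect_equal(mc2$p.value, 0.583122153819, tolerance = 1e-9)
    mc3 <- logrank(d$times, d$events, d$group)
    expect_equal(unname(mc3$statistic), 4.013911824562, tolerance = 1e-9)
    expect_equal(mc3$p.value, 0.134397169379, tolerance = 1e-9)
    expect_equal(unname(mc3$parameter), 2)

    gw2 <- logrank(d$times[two], d$events[two], d$group[two],
                   weighting = "gehan_breslow_wilcoxon")
    expect_equal(unname(gw2$statistic), 0.921602787456, tolerance = 1e-9)
    expect_equal(gw2$p.value, 0.337054484260, tolerance = 1e-9)
    gw3 <- logrank(d$times, d$events, d$group,
                   weighting = "gehan_breslow_wilcoxon")
    expect_equal(unname(gw3$statistic), 4.495504088450, tolerance = 1e-9)
})

test_that("Mantel-Cox agrees with survdiff across random datasets", {
    skip_if_not_installed("survival")
    for (s in 1:25) {
        set.seed(200 + s)
        n <- 60
        g <- sample(c("x", "y", "z"), n, TRUE)
        t <- round(rexp(n, ifelse(g == "x", 0.3, 0.15)), 2)
        e <- rbinom(n, 1, 0.8)
        if (sum(e) == 0) next
        got <- logrank(t, e, g)
        ref <- survival::survdiff(survival::Surv(t, e) ~ g)
        expect_equal(unname(got$statistic), unname(ref$chisq),
                     tolerance = 1e-8)
    }
})

test_that("degenerate and symmetric log-rank cases behave as required", {
    # identical groups: statistic 0, p 1
    t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
    same <- logrank(c(t, t), c(e, e), rep(c("a", "b"), each = 4))
    expect_equal(unname(same$statistic), 0, tolerance = 1e-12)
    expect_equal(same$p.value, 1)
    # two groups: chi-square equals the squared standardised O-E
    d <- oracleData(); two <- d$group != "C"
    core <- trimix:::logrankCore(d$times[two], d$events[two],
                                 d$group[two], "mantel_cox")
    expect_equal(unname(core$U[1]^2 / core$V[1, 1]),
                 unname(logrank(d$times[two], d$events[two],
                                d$group[two])$statistic),
                 tolerance = 1e-12)
    expect_error(logrank(c(1, 2), c(0, 0), c("a", "b")), "no events")
})

test_that("log-rank has power against a rate ratio and is calibrated under the null", {
    set.seed(42)
    t1 <- rexp(200, 3); t2 <- rexp(200, 1)
    got <- logrank(c(t1, t2), rep(1, 400), rep(1:2, each = 200))
    expect_lt(got$p.value, 0.001)

    ps <- vapply(1:400, function(s) {
        set.seed(1000 + s)
        t <- rexp(60, 1); e <- rbinom(60, 1, 0.8)
        if (sum(e) == 0) return(NA_real_)
        logrank(t, e, rep(1:2, each = 30))$p.value
    }, numeric(1))
    expect_gt(stats::ks.test(ps[!is.na(ps)], "punif")$p.value, 0.01)
})

test_that("trend test is score-symmetric and matches a Cox score oracle", {
    d <- oracleData()
    tr <- logrankTrend(d$times, d$events, d$group)
    rev <- logrankTrend(d$times, d$events,
                        factor(d$group, levels = c("C", "B", "A")))
    expect_equal(unname(tr$statistic), unname(rev$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(tr$parameter), 1)

    # identical groups: statistic ~ 0
    t <- c(1, 2, 3, 4); e <- c(1, 1, 0, 1)
    same <- logrankTrend(rep(t, 3), rep(e, 3), rep(c("a", "b", "c"), each = 4))
    expect_lt(unname(same$statistic), 1e-10)

    expect_error(logrankTrend(d$times[d$group != "C"],
                              d$events[d$group != "C"],
                              d$group[d$group != "C"]), ">= 3")

    skip_if_not_installed("survival")
    # on tie-free data the trend statistic equals the Cox
    # partial-likelihood score test with the group scores as covariate
    set.seed(31)
    tt <- rexp(90, rep(c(3, 2, 1), each = 30))
    ee <- rbinom(90, 1, 0.8); ee[1:3] <- 1
    gg <- rep(c("g1", "g2", "g3"), each = 30)
    tr2 <- logrankTrend(tt, ee, gg)
    cox <- survival::coxph(survival::Surv(tt, ee) ~ as.numeric(factor(gg)),
                           ties = "breslow")
    expect_equal(unname(tr2$statistic),
                 unname(summary(cox)$sctest["test"]), tolerance = 1e-8)
})

test_that("monotone hazards favour the trend test over the unordered one", {
    better <- vapply(1:50, function(s) {
        set.seed(3000 + s)
        t <- c(rexp(150, 3), rexp(150, 2), rexp(150, 1))
        e <- rep(1, 450)
        g <- rep(c("g1", "g2", "g3"), each = 150)
        logrankTrend(t, e, g)$p.value <= logrank(t, e, g)$p.value
    }, logical(1))
    expect_gte(mean(better), 0.8)
})

test_that("at-risk tables count subjects still under observation", {
    tab <- atRiskTable(c(1, 3, 5), rep("g", 3), interval = 2, horizon = 4)
    expect_equal(unname(tab["g", ]), c(3, 2, 1))
    t <- c(0.5, 2, 7, 9); g <- c("a", "a", "b", "b")
    tab2 <- atRiskTable(t, g, interval = 2, horizon = 8)
    expect_equal(unname(tab2[, "0"]), c(2, 2))   # full group sizes at 0
    for (r in rownames(tab2))
        expect_true(all(diff(tab2[r, ]) <= 0))   # non-increasing
})

test_that("higher index expression means better chemo-arm survival at 5 years", {
    direction <- vapply(1:20, function(s) {
        cfg <- syntheticConfig(nPatients = 1500, seed = 4000 + s)
        sm <- sampleMixture(cfg)
        clin <- generateClinical(cfg, sm$values, sm$trueLabels)
        chemo <- clin$treatment == "chemo_only"
        lab <- assignSubpopulations(sm$values, defaultScheme())
        si <- survivalInputs(clin)
        sel <- function(p) chemo & lab == p
        s5 <- function(p) kmSurvivalAt(kmCurve(si$times[sel(p)],
                                               si$events[sel(p)]), 5)
        s5("high") > s5("low")
    }, logical(1))
    expect_gt(mean(direction), 0.5)
})
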