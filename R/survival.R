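#' @include cohort.R
NULL

## Risk-set bookkeeping shared by the product-limit estimator and the
## weighted log-rank family. Ties: events precede censoring at the same
## time, so a subject censored at an event time is still at risk there.

#' Kaplan-Meier product-limit curve
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times,
#' with censoring at an event time removing subjects only after the
#' events at that time.
#'
#' @param times non-negative follow-up times in years.
#' @param events 1 = event (death from disease), 0 = censored.
#' @return object of class `kmCurve`: `eventTimes`, `survival`
#'   (step values at the event times), `nAtRisk`, `nEvents`,
#'   `censorTimes`, `n`.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 1, 0))$survival # 2/3, 1/3
#' @export
kmCurve <- function(times, events) {
    stopifnot(length(times) == length(events), length(times) > 0,
              all(times >= 0), all(events %in% c(0, 1)))
    et <- sort(unique(times[events == 1]))
    nAtRisk <- vapply(et, function(t) sum(times >= t), numeric(1))
    d <- vapply(et, function(t) sum(times == t & events == 1), numeric(1))
    s <- cumprod(1 - d / nAtRisk)
    structure(list(eventTimes = et, survival = s, nAtRisk = nAtRisk,
                   nEvents = d, censorTimes = sort(times[events == 0]),
                   n = length(times)),
              class = "kmCurve")
}

#' Survival probability at given times
#'
#' Step-function evaluation of a [kmCurve()]; `S(t) = 1` before the
#' first event.
#'
#' @param curve a `kmCurve`.
#' @param t times in years.
#' @export
kmSurvivalAt <- function(curve, t) {
    vapply(t, function(tt) {
        i <- sum(curve$eventTimes <= tt)
        if (i == 0) 1 else curve$survival[i]
    }, numeric(1))
}

#' @export
print.kmCurve <- function(x, ...) {
    cat(sprintf("Kaplan-Meier curve: n = %d, %d events, %d censored\n",
                x$n, sum(x$nEvents), length(x$censorTimes)))
    invisible(x)
}

## O-E vector and covariance of the weighted log-rank family.
logrankCore <- function(times, events, group, weighting) {
    group <- factor(group)
    k <- nlevels(group)
    et <- sort(unique(times[events == 1]))
    U <- numeric(k)
    V <- matrix(0, k, k)
    for (t in et) {
        atRisk <- times >= t
        N <- sum(atRisk)
        d <- sum(times == t & events == 1)
        if (N < 1 || d < 1) next
        nj <- vapply(levels(group), function(g)
            sum(atRisk & group == g), numeric(1))
        dj <- vapply(levels(group), function(g)
            sum(times == t & events == 1 & group == g), numeric(1))
        w <- if (weighting == "gehan_breslow_wilcoxon") N else 1
        U <- U + w * (dj - d * nj / N)
        if (N > 1) {
            hyper <- d * (N - d) / (N - 1)
            V <- V + w^2 * hyper *
                (diag(nj / N, k) - tcrossprod(nj / N))
        }
    }
    list(U = U, V = V, k = k, levels = levels(group))
}

#' Weighted log-rank test across groups
#'
#' At each distinct event time, observed events per group are compared
#' with their hypergeometric expectation; the weighted `O - E` vector
#' and its covariance give a chi-square statistic on `k - 1` degrees of
#' freedom. Weights: 1 (Mantel-Cox) or the total number at risk
#' (Gehan-Breslow-Wilcoxon, emphasising early events).
#'
#' @param times,events follow-up times and event indicators.
#' @param group group membership (coerced to factor, k >= 2 levels).
#' @param weighting `"mantel_cox"` (default) or
#'   `"gehan_breslow_wilcoxon"`.
#' @return an `htest` with `statistic` (chi-square), `parameter` (df)
#'   and `p.value`.
#' @export
logrank <- function(times, events,
                    group, weighting = c("mantel_cox",
                                         "gehan_breslow_wilcoxon")) {
    weighting <- match.arg(weighting)
    stopifnot(length(times) == length(events),
              length(times) == length(group))
    if (sum(events == 1) == 0)
        stop("no events in any group: log-rank test undefined")
    core <- logrankCore(times, events, group, weighting)
    if (core$k < 2L) stop("need at least 2 groups")
    idx <- seq_len(core$k - 1L)
    Vsub <- core$V[idx, idx, drop = FALSE]
    stat <- tryCatch(
        as.numeric(crossprod(core$U[idx], solve(Vsub, core$U[idx]))),
        error = function(e) 0)
    stat <- max(stat, 0)
    structure(list(statistic = c("chi-square" = stat),
                   parameter = c(df = core$k - 1L),
                   p.value = pchisq(stat, core$k - 1L, lower.tail = FALSE),
                   method = paste("log-rank test,", weighting),
                   data.name = "times by group"),
              class = "htest")
}

#' Log-rank test for trend across ordered groups
#'
#' `(sum_m s_m (O_m - E_m))^2 / (s' V s)`, chi-square on 1 df, with
#' equally spaced integer scores by default. Requires at least 3
#' ordered groups (with 2 groups use [logrank()]).
#'
#' @inheritParams logrank
#' @param group ordered group membership; factor level order defines
#'   the trend direction (the statistic is invariant to reversal).
#' @param scores numeric scores per group (default `1..k`).
#' @return an `htest` (chi-square, 1 df).
#' @export
logrankTrend <- function(times, events, group, scores = NULL) {
    group <- factor(group)
    if (nlevels(group) < 3L)
        stop("trend test needs >= 3 ordered groups; use logrank()")
    if (sum(events == 1) == 0) stop("no events: trend test undefined")
    core <- logrankCore(times, events, group, "mantel_cox")
    s <- if (is.null(scores)) seq_len(core$k) else as.numeric(scores)
    stopifnot(length(s) == core$k)
    num <- sum(s * core$U)^2
    den <- as.numeric(crossprod(s, core$V %*% s))
    stat <- if (den > 0) num / den else 0
    structure(list(statistic = c("chi-square" = stat),
                   parameter = c(df = 1),
                   p.value = pchisq(stat, 1, lower.tail = FALSE),
                   method = "log-rank test for trend",
                   data.name = "times by ordered group"),
              class = "htest")
}

#' Numbers at risk at regular intervals
#'
#' @param times follow-up times in years.
#' @param group group membership.
#' @param interval tick spacing in years (default 2).
#' @param horizon last tick (default the largest time).
#' @return matrix of counts with `time >= tick`, groups in rows, ticks
#'   in columns.
#' @export
atRiskTable <- function(times, group, interval = 2, horizon = NULL) {
    stopifnot(interval > 0, length(times) == length(group))
    group <- factor(group)
    if (is.null(horizon)) horizon <- max(times)
    ticks <- seq(0, horizon, by = interval)
    out <- vapply(ticks, function(t)
        vapply(levels(group), function(g)
            sum(times >= t & group == g), numeric(1)),
        numeric(nlevels(group)))
    out <- matrix(out, nrow = nlevels(group),
                  dimnames = list(levels(group), format(ticks)))
    out
}

#' Overall-survival inputs from a clinical table
#'
#' Death from disease is the event; other-cause deaths, unknown
#' outcomes and administrative censoring are censored at their
#' follow-up time.
#'
#' @param clinical canonical clinical data.frame.
#' @return list with `times` and `events`.
#' @export
survivalInputs <- function(clinical) {
    list(times = clinical$survival_time,
         events = as.integer(clinical$outcome == "died_of_disease"))
}
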