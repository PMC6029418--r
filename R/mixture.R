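#' @include binning.R
NULL

## ----------------------------------------------------------------------
## Model function and component areas
## ----------------------------------------------------------------------

#' Sum-of-Gaussians model value
#'
#' Evaluates `y = sum_i A_i * exp(-0.5 * ((x - mean_i) / sd_i)^2)`,
#' the expected bin count at bin center `x`.
#'
#' @param x numeric vector of log2 values (bin centers).
#' @param components data.frame with columns `amplitude`, `mean`, `sd`.
#' @return predicted counts, same length as `x`.
#' @export
gaussianSum <- function(x, components) {
    stopifnot(all(c("amplitude", "mean", "sd") %in% colnames(components)))
    y <- numeric(length(x))
    for (i in seq_len(nrow(components)))
        y <- y + components$amplitude[i] *
            exp(-0.5 * ((x - components$mean[i]) / components$sd[i])^2)
    y
}

#' Area under a Gaussian component
#'
#' `AUC = A * SD * sqrt(2 * pi)`, in patients when the amplitude is a
#' peak bin count divided by the bin width (or, up to the common bin
#' width factor, proportional to patients for raw amplitudes —
#' normalised weights are identical either way).
#'
#' @param amplitude peak height(s) `A`.
#' @param sd standard deviation(s).
#' @return `A * SD * sqrt(2*pi)`, vectorised.
#' @export
componentAUC <- function(amplitude, sd) {
    stopifnot(length(amplitude) == length(sd))
    amplitude * sd * sqrt(2 * pi)
}

paramsToComponents <- function(p) {
    k <- length(p) / 3L
    cmp <- data.frame(amplitude = p[3 * seq_len(k) - 2],
                      mean = p[3 * seq_len(k) - 1],
                      sd = p[3 * seq_len(k)])
    cmp[order(cmp$mean), , drop = FALSE]
}

## weighted quantiles of bin centers; the un-binned values are not
## available to the fitter, so starting means come from the histogram
weightedQuantile <- function(centers, counts, probs) {
    o <- order(centers)
    centers <- centers[o]; counts <- counts[o]
    cw <- cumsum(counts) / sum(counts)
    vapply(probs, function(p) centers[which(cw >= p)[1L]], numeric(1))
}

## ----------------------------------------------------------------------
## Multi-start nonlinear least squares
## ----------------------------------------------------------------------

#' Fit a sum of 1-3 Gaussians to a binned frequency distribution
#'
#' Least-squares minimisation of the squared difference between
#' observed bin counts and [gaussianSum()] at the bin centers
#' (unweighted, Levenberg-Marquardt with box constraints `A > 0`,
#' `sd > 0`). Convergence is confirmed with `nStarts` independent
#' initialisations: starting means sit at the `(2j - 1) / (2k)`
#' quantiles of the binned values plus seed-driven uniform jitter, SDs
#' at the sample SD divided by the component count, amplitudes at the
#' maximum count divided by the component count. A fit is reported as
#' converged when at least two starts reach parameter vectors agreeing
#' within a relative tolerance of 1e-3 and no component is collapsed
#' (weight below 1%, SD below half the bin width, or adjacent means
#' closer than the smaller of the two SDs — a duplicated, unresolvable
#' mode); the reported solution is the lowest-SSE converged one.
#'
#' @param freq a [BinnedFrequency-class].
#' @param nComponents number of Gaussians, 1 to 3.
#' @param nStarts independent starts (at least 3; default 5).
#' @param seed integer seed driving the start jitter.
#' @return a [MixtureFit-class] (check [isConverged()]).
#' @examples
#' cfg <- syntheticConfig(seed = 7)
#' freq <- binValues(sampleMixture(cfg)$values)
#' fit <- fitMixture(freq, nComponents = 3, seed = 7)
#' componentTable(fit)
#' @export
fitMixture <- function(freq, nComponents, nStarts = 5L, seed = 1L) {
    stopifnot(is(freq, "BinnedFrequency"))
    k <- as.integer(nComponents)
    if (k < 1L || k > 3L) stop("nComponents must be 1, 2 or 3")
    nStarts <- max(3L, as.integer(nStarts))
    x <- binCenters(freq)
    y <- as.numeric(binCounts(freq))
    nb <- length(x)
    if (nb <= 3L * k)
        stop("too few bins: need more than 3 * nComponents")

    ## start construction
    probs <- (2 * seq_len(k) - 1) / (2 * k)
    mu0 <- weightedQuantile(x, y, probs)
    n <- sum(y)
    mAll <- sum(x * y) / n
    sAll <- sqrt(max(sum(y * (x - mAll)^2) / max(n - 1, 1),
                     (binWidth(freq) / 2)^2))
    sd0 <- rep(sAll / k, k)
    amp0 <- rep(max(y) / k, k)

    set.seed(as.integer(seed))
    lower <- rep(c(1e-8, min(x) - 2 * sAll, binWidth(freq) / 10), k)
    upper <- rep(c(2 * max(y) * k + 1, max(x) + 2 * sAll, diff(range(x)) + 1), k)
    resid <- function(p) y - gaussianSum(x, paramsToComponents(p))

    sols <- vector("list", nStarts)
    for (s in seq_len(nStarts)) {
        mu <- mu0; sdv <- sd0; am <- amp0
        if (s > 1L) {              # first start is the plain quantile seed
            mu <- mu + runif(k, -1, 1) * sAll / 2
            sdv <- sdv * exp(runif(k, -0.7, 0.7))
            am <- am * exp(runif(k, -0.7, 0.7))
        }
        p0 <- pmin(pmax(as.vector(rbind(am, mu, sdv)), lower), upper)
        ans <- tryCatch(
            minpack.lm::nls.lm(par = p0, fn = resid, lower = lower,
                               upper = upper,
                               control = minpack.lm::nls.lm.control(
                                   maxiter = 500, maxfev = 5000)),
            error = function(e) NULL)
        if (is.null(ans) || !(ans$info %in% 1:4)) next
        cmp <- paramsToComponents(ans$par)
        sols[[s]] <- list(cmp = cmp, sse = sum(resid(ans$par)^2),
                          par = as.vector(rbind(cmp$amplitude, cmp$mean,
                                                cmp$sd)))
    }
    sols <- Filter(Negate(is.null), sols)
    if (!length(sols))
        return(makeFit(freq, data.frame(amplitude = amp0, mean = mu0,
                                        sd = sd0),
                       FALSE, nStarts, seed))

    valid <- vapply(sols, function(s) {
        auc <- componentAUC(s$cmp$amplitude, s$cmp$sd)
        gaps <- diff(s$cmp$mean)
        minSd <- pmin(s$cmp$sd[-1], s$cmp$sd[-nrow(s$cmp)])
        all(auc / sum(auc) >= 0.01) &&
            all(s$cmp$sd >= binWidth(freq) / 2) &&
            all(gaps >= minSd)   # duplicated modes are not resolvable
    }, logical(1))

    relAgree <- function(a, b)
        max(abs(a - b) / pmax(abs(b), 1e-6)) < 1e-3
    agreeing <- rep(FALSE, length(sols))
    for (i in seq_along(sols))
        for (j in seq_along(sols))
            if (i != j && relAgree(sols[[i]]$par, sols[[j]]$par))
                agreeing[i] <- TRUE

    ok <- valid & agreeing
    pick <- if (any(ok)) which(ok) else which(valid)
    converged <- any(ok)
    if (!length(pick)) { pick <- seq_along(sols); converged <- FALSE }
    best <- sols[[pick[which.min(vapply(sols[pick], `[[`, numeric(1),
                                        "sse"))]]]
    makeFit(freq, best$cmp, converged, nStarts, seed)
}

makeFit <- function(freq, cmp, converged, nStarts, seed,
                    candidates = list()) {
    x <- binCenters(freq)
    y <- as.numeric(binCounts(freq))
    pred <- gaussianSum(x, cmp)
    sse <- sum((y - pred)^2)
    dfree <- length(x) - 3L * nrow(cmp)
    aucs <- componentAUC(cmp$amplitude, cmp$sd)
    r <- if (sd(pred) > 0) cor(y, pred) else NA_real_
    new("MixtureFit", components = cmp, predicted = pred,
        ssResidual = sse,
        syx = if (dfree > 0) sqrt(sse / dfree) else NA_real_,
        rObsPred = r, aucs = aucs, weights = aucs / sum(aucs),
        converged = converged, nStarts = as.integer(nStarts),
        seed = as.integer(seed), freq = freq, candidates = candidates)
}

## ----------------------------------------------------------------------
## Model selection over 1..max components
## ----------------------------------------------------------------------

#' Select the number of Gaussian components
#'
#' Fits 1 to `maxComponents` Gaussians and, among converged fits (no
#' collapsed component, multi-start agreement), selects the one
#' minimising the small-sample information criterion AICc computed from
#' the Gaussian residual likelihood on the bins,
#' `n*log(SSE/n) + 2p + 2p(p+1)/(n-p-1)` with `p = 3*k + 1`.
#'
#' @inheritParams fitMixture
#' @param maxComponents largest model considered (default 3).
#' @return the selected [MixtureFit-class]; all candidate fits are kept
#'   in its `candidates` slot and the AICc values in
#'   `attr(, "aicc")`-style element `candidates[["aicc"]]`.
#' @export
selectModel <- function(freq, maxComponents = 3L, nStarts = 5L, seed = 1L) {
    stopifnot(is(freq, "BinnedFrequency"))
    nb <- length(binCounts(freq))
    fits <- list(); aicc <- c()
    for (k in seq_len(maxComponents)) {
        if (nb <= 3L * k) break
        f <- fitMixture(freq, k, nStarts = nStarts, seed = seed)
        fits[[as.character(k)]] <- f
        p <- 3 * k + 1
        a <- if (isConverged(f) && nb - p - 1 > 0)
            nb * log(max(f@ssResidual, 1e-12) / nb) + 2 * p +
                2 * p * (p + 1) / (nb - p - 1)
        else NA_real_
        aicc[as.character(k)] <- a
    }
    if (all(is.na(aicc)))
        stop("no converged candidate fit with 1..", maxComponents,
             " components")
    bestK <- names(aicc)[which.min(aicc)]
    best <- fits[[bestK]]
    best@candidates <- c(fits, list(aicc = aicc))
    best
}

## ----------------------------------------------------------------------
## Accessors and show
## ----------------------------------------------------------------------

#' @rdname MixtureFit-class
#' @export
setMethod("componentTable", "MixtureFit", function(object) {
    cbind(object@components, auc = object@aucs, weight = object@weights)
})

#' @rdname MixtureFit-class
#' @export
setMethod("componentWeights", "MixtureFit", function(object) object@weights)

#' @rdname MixtureFit-class
#' @export
setMethod("fitQuality", "MixtureFit", function(object)
    list(rObsPred = object@rObsPred, syx = object@syx,
         ssResidual = object@ssResidual))

#' @rdname MixtureFit-class
#' @export
setMethod("isConverged", "MixtureFit", function(object) object@converged)

#' @rdname MixtureFit-class
#' @export
setMethod("predictedCounts", "MixtureFit", function(object) object@predicted)

setMethod("show", "MixtureFit", function(object) {
    cat(sprintf("MixtureFit: %d component(s), %s\n",
                nrow(object@components),
                if (object@converged) "converged" else "NOT converged"))
    print(round(componentTable(object), 4))
    cat(sprintf("r(obs, pred) = %.4f, Sy.x = %.3f\n",
                object@rObsPred, object@syx))
})
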