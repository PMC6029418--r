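#' @include AllGenerics.R
NULL

## Lilliefors D: sup distance between the empirical CDF and the normal
## CDF with mean/sd estimated from the sample.
lillieforsD <- function(values) {
    n <- length(values)
    z <- (sort(values) - mean(values)) / sd(values)
    p <- pnorm(z)
    max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Kolmogorov-Smirnov normality test with estimated parameters
#'
#' Computes the Lilliefors statistic
#' `D = sup |F_n(x) - Phi((x - m) / s)|` with `m`, `s` estimated from
#' the sample. For `n >= 30` the p-value uses the Dallal-Wilkinson
#' approximation (via `nortest::lillie.test`); for smaller samples a
#' parametric bootstrap (10 000 replicates) is used, since the
#' approximation degrades at small `n`.
#'
#' @param values numeric sample, `n >= 5`, non-degenerate.
#' @param bootstrapReps bootstrap replicates for small samples.
#' @return an object of class `htest` with the `D` statistic and
#'   p-value.
#' @export
ksNormality <- function(values, bootstrapReps = 10000L) {
    values <- as.numeric(values)
    if (length(values) < 5L) stop("need at least 5 values")
    if (sd(values) == 0) stop("degenerate sample: zero variance")
    n <- length(values)
    d <- lillieforsD(values)
    if (n >= 30L) {
        p <- nortest::lillie.test(values)$p.value
    } else {
        boot <- vapply(seq_len(bootstrapReps),
                       function(i) lillieforsD(rnorm(n)), numeric(1))
        p <- (sum(boot >= d) + 1) / (bootstrapReps + 1)
    }
    structure(list(statistic = c(D = d),
                   p.value = min(max(p, 0), 1),
                   method = "Kolmogorov-Smirnov normality test (Lilliefors)",
                   data.name = deparse(substitute(values))),
              class = "htest")
}

#' Probit plot coordinates
#'
#' Pairs the sorted sample with standard-normal quantiles at plotting
#' positions `(i - 0.5) / n`; a sample from a single normal yields
#' near-linear pairs.
#'
#' @param values numeric sample, `n >= 2`.
#' @return list with `sorted` (ascending values) and `quantiles`
#'   (`qnorm((i - 0.5) / n)`).
#' @export
probitCoordinates <- function(values) {
    values <- as.numeric(values)
    n <- length(values)
    if (n < 2L) stop("need at least 2 values")
    list(sorted = sort(values),
         quantiles = qnorm((seq_len(n) - 0.5) / n))
}
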