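# Shared fixtures, built in code at test time.

# Published whole-cohort fit parameters (amplitude, mean, sd) and the
# printed component sizes, reused across mixture/assignment tests.
cohortFitAll <- data.frame(amplitude = c(104, 54, 68),
                        mean = c(6.25, 7.89, 10.58),
                        sd = c(0.39, 1.12, 0.86))
cohortFitSizes <- c(515, 752, 713)
cohortFitErPos <- data.frame(amplitude = c(35, 49, 67),
                          mean = c(6.47, 8.07, 10.61),
                          sd = c(0.37, 1.10, 0.84))

# Small synthetic config for fast end-to-end tests.
smallConfig <- function(seed = 1L, ...)
    syntheticConfig(nPatients = 400L, nCorrGenesLow = 10L,
                    nCorrGenesHigh = 10L, nNullGenes = 30L,
                    seed = seed, ...)

# Minimal hand-built clinical table.
makeClinical <- function(n = 6L) {
    data.frame(patient_id = sprintf("P%02d", seq_len(n)),
               er_status = rep("positive", n),
               treatment = rep("chemo_only", n),
               survival_time = seq_len(n),
               outcome = rep("alive", n),
               stringsAsFactors = FALSE)
}

# Expected bin counts under a Gaussian mixture, for noise-free fits.
expectedFreq <- function(weights, means, sds, n, lo, hi, width = 0.2) {
    edges <- seq(lo, hi, by = width)
    counts <- vapply(seq_len(length(edges) - 1L), function(i)
        sum(weights * (pnorm(edges[i + 1L], means, sds) -
                       pnorm(edges[i], means, sds))) * n,
        numeric(1))
    new("BinnedFrequency", binWidth = width,
        leftEdges = edges[-length(edges)],
        counts = as.integer(round(counts)))
}
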