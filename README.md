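# trimix

Deconvolution of tumor expression sub-populations from a single gene's
log2 distribution, with survival and treatment-response analysis.

Some genes are regulated by several distinct mechanisms across a tumor
cohort, so their marginal log2 mRNA distribution is a mixture of
sub-populations rather than one Gaussian — arylamine
N-acetyltransferase 1 (NAT1) in breast cancer, which separates into
low, intermediate and high expressers, is the motivating case. trimix
is for analysts who want to resolve such sub-populations from bulk
expression plus clinical tables and ask whether they differ in
co-expression partners, overall survival and response to chemotherapy.

## The model

The binned frequency distribution (bin width 0.2 log2 units) of the
index gene is fitted by multi-start nonlinear least squares to a sum
of Gaussians,

    y = Σᵢ Aᵢ · exp(−½ ((x − x̄ᵢ)/SDᵢ)²),   i = 1..n,  n ≤ 3,

where `y` is the observed count at bin center `x`. The area under
component i, `AUCᵢ = Aᵢ·SDᵢ·√(2π)`, is proportional to the number of
patients in sub-population i; AICc over converged fits selects `n`.
Patients are then assigned through cut-off windows (defaults
[5, 6.5], [7.25, 8.5], [10, 13]) with closed-form estimates of the
expected misassignment from the overlapping components. Downstream:
per-sub-population Pearson co-expression screens under Bonferroni
control, Kaplan-Meier curves with Mantel-Cox / trend /
Gehan-Breslow-Wilcoxon log-rank statistics (implemented from first
principles), resistant/sensitive classification at the 5-year
boundary, and a sensitivity/specificity decision curve with cross-over
estimation. A synthetic-cohort generator reproduces the statistical
structure the analysis assumes, so the whole chain is testable without
patient data.

## Worked example

```r
library(trimix)
res <- runPipeline(pipelineConfig(list(seed = 1)), outputDir = "demo")
cat(readLines("demo/summary.txt"), sep = "\n")
```

```
trimix pipeline summary (seed 1)

Mixture deconvolution (3 component(s), converged):
  component  amplitude    mean     sd  patients     pct
  1             118.03    6.29   0.41       613   30.9%
  2              51.70    7.86   0.71       463   23.4%
  3              69.23   10.32   1.04       904   45.7%
  r(obs,pred) = 0.9814, Sy.x = 6.799, K-S D = 0.1050 (p = 4.08e-59)

Expected misassignment: low 3.0%, intermediate 12.6%, high 0.1%

Venn partition of significant co-expressed genes:
  low_only           50
  intermediate_only  0
  high_only          50
  ...

Survival tests across sub-populations:
  mantel_cox               chi2 =    9.914, p = 0.00703
  gehan_breslow_wilcoxon   chi2 =   11.762, p = 0.00279
  trend                    chi2 =    7.763, p = 0.00533

Treatment response (161 resistant, 180 sensitive, 1639 excluded):
  ANOVA p = 7.8e-14, trend p = 7.53e-07
  decision-curve cross-over: cutoff 8.37, rate 0.678; 5.64 years per log2 unit
```

Reading it: the generated cohort (n = 1980) is deconvolved into three
Gaussian components whose areas translate into patient counts; the
observed-vs-predicted correlation 0.98 and the failed normality test
(K-S p ≪ 0.0001) say a single Gaussian cannot describe the data. The
co-expression screen recovers exactly the two 50-gene blocks built
into the generator, in the correct sub-populations, with zero false
positives among 200 null genes. Survival differs across the three
windows, and in the chemotherapy arm expression climbs with survival
time (trend p ≈ 8e-7), with the decision curve's cross-over marking
the cutoff where sensitivity equals specificity for predicting
resistance. All numbers above are the actual seed-1 output;
`misassignment.tsv`, `decision_curve.tsv` and the other per-stage TSVs
land in the output directory.

The per-stage functions — `binValues()`, `fitMixture()`,
`selectModel()`, `assignSubpopulations()`, `misassignment()`,
`screenCoexpression()`, `kmCurve()`, `logrank()`,
`classifyPatients()`, `decisionCurve()` — run standalone; a shell
wrapper lives at `inst/scripts/pipeline.R`. Real data enter as two
TSVs (genes × patients log2 matrix; clinical table mapped by
`clinicalMapping()`). See the methods vignette
(`vignettes/trimix-methods.Rmd`) for the model details, conventions
and limitations.

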