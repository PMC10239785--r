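# glaucodose

Dose–response, gene–environment interaction and Mendelian randomization
analyses of habitual alcohol consumption and glaucoma-related traits.

## The problem

Whether, how strongly, and at what intake levels alcohol consumption
affects glaucoma and its structural biomarkers — intraocular pressure
(IOP), macular retinal nerve fiber layer (mRNFL) and macular ganglion
cell–inner plexiform layer (mGCIPL) thickness — is a question that large
population cohorts can address through a combination of observational
regression, gene–environment interaction and genetic (instrumental
variable) analyses. The individual-level cohort data those studies run on
are access-restricted. glaucodose implements the full analytic pipeline as
a reusable, tested R package, together with a synthetic-data module that
emulates the statistical structure of such a cohort and of consortium GWAS
summary statistics, so every stage can be exercised, validated and
stress-tested at the desk.

It is aimed at epidemiologists and statistical geneticists who want the
individual analysis components (exposure quantification, ICD-based
phenotype ascertainment, restricted-cubic-spline dose–response models,
polygenic-score interaction tests, a from-scratch two-sample MR suite) or
a calibrated simulation environment for methods work.

## The models

**Exposure.** Weekly ethanol intake is quantified from a six-beverage
frequency questionnaire as

    grams/week = sum_i portions_i × volume_i (mL) × concentration_i (g/mL) × k

with *k* = 1 for weekly reporters and *k* = 12×7/365 ≈ 0.23 for monthly
reporters; drinkers are classified never / infrequent / regular / former,
regular drinkers' estimates are trimmed at the top and bottom percentiles,
and the retained intake is standardized (mean 0, SD 1).

**Association.** Maximally adjusted (13 covariates) linear and logistic
models contrast drinking categories against infrequent drinkers, then test
dose–response in regular drinkers: per-SD coefficients, quintile contrasts
with a median-based trend test, and restricted cubic splines on log intake
— Harrell's truncated-power basis, knots at fixed heuristic percentiles,
3–7 knots selected by AIC — which are linear beyond the boundary knots.

**Gene–environment.** A weighted-sum glaucoma polygenic score
Σ β̂ᵢ·SNPᵢ (standardized) enters the adjusted IOP model through a
multiplicative intake × PRS product term, with descriptive per-SD effects
in PRS quintiles.

**Mendelian randomization.** Harmonized two-sample summary statistics
(allele alignment, palindrome removal, full vs rs1229984-restricted
instruments) feed a complete estimator battery implemented from first
principles: per-SNP Wald ratios, inverse-variance weighted regression
through the origin (fixed or multiplicative random effects, Cochran's Q,
I²), MR-Egger with the intercept pleiotropy test and the I²GX regression
dilution statistic, the weighted median, the weighted mode, MR-PRESSO
(global, outlier and distortion tests by parametric simulation) and
multivariable MR.

See `vignettes/glaucodose-methods.Rmd` for the full model descriptions,
parameter defaults and numerical choices.

## Worked example

```r
library(glaucodose)

## a default synthetic cohort: questionnaire, covariates, PRS, per-eye
## measurements, ICD records
cd <- generateCohort(cohortConfig(n = 100000, seed = 42))
d  <- deriveExposure(cd$participants)    # category, grams/week, trimming, SD units
d  <- deriveOutcomes(d, cd$diagnoses)    # IOP, OCT, glaucoma status

perSDAnalysis(d, "iop")
#> ModelResult with 1 row and 8 columns
#>          term  estimate     ciLow    ciHigh           p         n       scale
#> 1   intakeStd 0.0785383 0.0549714  0.102105 6.49664e-11     74990    identity
```

Each additional SD of weekly intake (about 90–110 g/week) is associated
with 0.079 mmHg higher IOP (95% CI 0.055–0.102) among the 74,990 retained
regular drinkers — recovering the generator's configured 0.08 mmHg/SD.
The logistic analogue gives the glaucoma odds ratio per SD:

```r
perSDAnalysis(d, "glaucoma")
#> 1   intakeStd    1.0684   1.01671   1.12272 0.00892559     77074  odds-ratio
```

The PRS modifies the alcohol–IOP association (product-term p = 5.5e-4
here), with per-SD effects rising across PRS quintiles:

```r
ia <- interactionAnalysis(d, outcome = "iop")
as.data.frame(ia$byQuintile)[, 1:4]
#>               term    estimate        ciLow     ciHigh
#> 1 intakeStd|PRS Q1 0.006184599 -0.046622293 0.05899149
#> 2 intakeStd|PRS Q2 0.058717397  0.006209657 0.11122514
#> 3 intakeStd|PRS Q3 0.084069544  0.030990615 0.13714847
#> 4 intakeStd|PRS Q4 0.121598887  0.069645460 0.17355231
#> 5 intakeStd|PRS Q5 0.118786488  0.065537238 0.17203574
```

Two-sample MR on a default synthetic 80-SNP instrument (true causal effect
−1.52 μm mGCIPL per SD of genetically proxied intake):

```r
set <- harmonize(generateSummaryStats(summaryConfig(seed = 42)))
mrIVW(set)
#> IVW (multiplicative random) estimate over 80 SNPs
#>   estimate -1.5443 (95% CI -2.2390, -0.8497), p = 1.32e-05
#>   Cochran's Q = 78.69 (p = 0.489), I2 = 0.0%
mrEgger(set)
#> MR-Egger estimate over 80 SNPs
#>   estimate -0.9032 (95% CI -2.0182, 0.2118), p = 0.112
#>   Egger intercept = -0.007584 (p = 0.15), I2GX = 0.97
```

`runPipeline(runConfig(...))` chains all stages (simulate → derive →
associate → gxe → mr) with persisted tab-delimited outputs and a
provenance manifest; `inst/scripts/run_pipeline.R` is a command-line
wrapper.

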