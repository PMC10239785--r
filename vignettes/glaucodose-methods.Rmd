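---
title: "Models and methods in glaucodose"
author: "glaucodose authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in glaucodose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glaucodose)
```

glaucodose implements a complete analytic pipeline for studying habitual
alcohol consumption and glaucoma-related traits: exposure quantification
from a beverage-frequency questionnaire, derivation of intraocular pressure
(IOP), macular OCT thicknesses and glaucoma status, a two-step battery of
adjusted association models, a polygenic-score gene-environment interaction
test, and a from-scratch two-sample Mendelian randomization (MR) suite.
Because the individual-level cohort data such analyses run on are
access-restricted, the package ships a synthetic-data module whose defaults
encode the published summary structure of a large UK population cohort, so
every stage can be exercised, validated, and stress-tested end to end.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
emulate.

## Exposure model

Participants report a drinking frequency (six categories from
"Daily/almost daily" to "Never") and, when quantifiable, portion counts of
six beverage types. Classification follows the standard epidemiological
four-way split: *never* (frequency "Never", never drank), *infrequent*
("Special occasions only"), *regular* ("1-3 times a month" or more often)
and *former* (frequency "Never" but previously drank). Weekly ethanol grams
are

$$\mathrm{grams/week} = \sum_{i=1}^{6} \mathrm{portions}_i \times
  \mathrm{volume}_i \,(\mathrm{mL}) \times \mathrm{concentration}_i
  \,(\mathrm{g/mL}) \times k,$$

with $k = 1$ for weekly reporters and $k = 12 \times 7 / 365 \approx 0.23$
for monthly reporters (stored at full precision; 0.23 is a display
rounding). The default beverage table (175 mL wine at 12% ABV, 568 mL
beer/cider at 4%, 25 mL spirits at 40%, 50 mL fortified wine at 17.5%,
250 mL "other" at 4%; concentration = ABV $\times$ 0.789 g/mL ethanol
density) is a documented stand-in for food-composition values that are not
publicly deposited, and is fully configurable via a 3-column file.

Quantitative analyses use regular drinkers only. Their gram estimates are
trimmed at the top and bottom 1 percentiles — percentiles by linear
interpolation between closest ranks (type-7), with ties at the threshold
retained, so trimming is strict and conservative — and zero-gram reports
(implausible for regular drinkers, and unusable on the log scale) are
excluded with the bottom tail. The retained intake is standardized to mean
0, SD 1; at the default calibration one SD is roughly 90-110 g/week.
Trimming is applied before standardization, so "per SD" always means per SD
of the trimmed regular-drinker distribution. Whether trimming should happen
before or after excluding infrequent drinkers is ambiguous in the source
material; the package trims the regular-drinker quantities that actually
enter the quantitative analyses.

Unit conversions use 8 g of ethanol per UK unit and 14 g per US standard
drink, giving weekly guideline thresholds of 112 g (UK, both sexes), 98 g
(US women) and 196 g (US men).

## Phenotype derivation

**IOP.** The individual-level value is the mean of available right and left
corneal-compensated measurements. For users of ocular hypotensive
medication the pretreatment value is imputed as measured/0.7. Participants
with glaucoma surgery or laser therapy, corneal graft, refractive surgery
or significant ocular trauma are excluded from IOP (not from OCT or
glaucoma analyses). After derivation, the extreme top and bottom 0.5
percentiles are trimmed at the population level.

**OCT.** Macular RNFL and GCIPL thicknesses are per-layer means over
available eyes; participants with retinal pathology are retained.

**Glaucoma.** A participant is a case on self-reported glaucoma (or
glaucoma surgery) or on carrying a qualifying diagnosis code — ICD-10 H40.*
excluding the H40.0 suspect block plus any H42.*, ICD-9 365.* excluding
365.0 — at any time before and up to 365 days (inclusive) after baseline.
Matching is prefix-based on normalized codes, because the definitions are
wildcard patterns, not enumerations; codes outside both families never
change status. Cases diagnosed before age 30 are excluded (the age comes
from the diagnosis records; where it is absent no age exclusion applies).
Non-cases on ocular hypotensives or carrying a suspect code are excluded as
controls. Participants with glaucoma are *not* excluded from IOP/OCT
analyses by default; the `exclude-glaucoma` sensitivity variant removes
them.

## Association models

All primary models adjust for 13 covariates: age, sex, ethnicity, Townsend
deprivation index, assessment season, BMI, height, systolic blood pressure,
spherical equivalent, diabetes, smoking status, smoking intensity and
physical activity (`covariateSpec()`). Continuous outcomes use ordinary
least squares, glaucoma uses maximum-likelihood logistic regression
(iteratively reweighted least squares as implemented by `stats::glm`, with
relative convergence tolerance $10^{-10}$ and at most 100 iterations);
estimates carry Wald 95% intervals, with no robust or clustered variances.

The two analysis steps are:

1. **Categorical**: each drinking category contrasted against infrequent
   drinkers (low-volume drinkers make a better reference than never
   drinkers, who differ systematically; a pooled never+infrequent reference
   is available).
2. **Quantitative**, regular drinkers only: per-SD continuous fits;
   quintile contrasts Q2-Q5 vs Q1, with quintile boundaries from
   interpolated percentiles, lower-closed so boundary ties fall in the
   lower quintile; and a trend test refitting with each participant
   assigned their quintile's median intake as a continuous term (Wald test
   of that term — the construction fixes the covariate, not the test, so
   the Wald choice is documented here).

**Restricted cubic splines.** Nonlinearity is modeled on the natural log of
intake with Harrell's truncated-power restricted cubic basis: the linear
term plus $k-2$ terms

$$X_j = \frac{(x-t_j)_+^3 - (x-t_{k-1})_+^3 \frac{t_k-t_j}{t_k-t_{k-1}}
        + (x-t_k)_+^3 \frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2},$$

which is twice continuously differentiable and exactly linear beyond the
boundary knots (the $(t_k-t_1)^2$ normalization keeps the columns on the
scale of $x$). Knots sit at fixed heuristic percentiles of log-intake —
(10, 50, 90) for 3 knots up to (2.5, 18.33, 34.17, 50, 65.83, 81.67, 97.5)
for 7 — and the number of knots (3-7) is chosen by AIC minimization. The
reported curve is the partial spline effect relative to a reference intake
(the sample median by default) with pointwise Wald bands; for glaucoma it
is exponentiated to the OR scale. Guideline verticals (112/98/196 g/week)
are attached for plotting.

## Gene-environment interaction

The polygenic score is the standard weighted sum of risk-allele dosages,
$\sum_i \hat\beta_i \, \mathrm{SNP}_i$, with dosages flipped ($2-d$) where
the counted allele differs from the weight file's effect allele and missing
dosages mean-imputed per variant (a documented stand-in for imputed
genotypes). The score is standardized to mean 0, SD 1 within the scoring
cohort. The synthetic cohort emits the standardized score directly, since
the real weight panel is not available; `computePRS()` supports round trips
through an explicit dosage matrix and weight file.

The headline interaction test adds a single multiplicative
intake $\times$ PRS product term (continuous PRS) to the maximally adjusted
model and reports its Wald p. Covariate $\times$ PRS and covariate
$\times$ intake terms are not included by default — the source analysis
names only the product term — and the descriptive layer refits the per-SD
intake effect within PRS quintiles computed on the analysis subset actually
modeled. Product-term inference is invariant to location shifts of the PRS
(main effects absorb them), which the tests verify.

## Two-sample Mendelian randomization

`harmonize()` inner-joins exposure and outcome summary tables on variant
id, aligns the outcome beta to the exposure's effect allele (sign flip on
swapped alleles, complement matching for strand flips), drops palindromic
(A/T, C/G) variants with a report, and orders SNPs canonically by id so the
result is independent of input row order. `buildInstrument()` filters on
exposure p-value and an exclusion list; the "restricted" instrument is the
full one minus the ADH1B-like large-effect variant rs1229984, whose
biological pleiotropy motivates the exclusion.

Estimators (per-SNP Wald ratio $\hat\theta_j = \beta_{Yj}/\beta_{Xj}$, SE
by the first-order delta method $\mathrm{se}_{Yj}/|\beta_{Xj}|$, second
order optional):

- **IVW**: weighted regression of $\beta_Y$ on $\beta_X$ through the
  origin, weights $\mathrm{se}_Y^{-2}$. Default variance model is
  multiplicative random effects — SE inflated by
  $\sqrt{\max(1, Q/(n-1))}$ — with a fixed-effect flag; the source does not
  state its variance model, and random effects is common practice at this
  instrument size. Cochran's $Q$ and $I^2$ are attached. A single SNP falls
  back to the Wald ratio.
- **MR-Egger**: the same regression with an intercept, after orienting all
  $\beta_X > 0$; the intercept tests average directional pleiotropy and
  $I^2_{GX} = (Q_{GX} - (n-1))/Q_{GX}$ (floored at 0) quantifies regression
  dilution from exposure-beta measurement error.
- **Weighted median**: ratios ordered, cumulative standardized weights
  $s_j = (\sum_{i\le j} w_i - w_j/2)/\sum w_i$ with inverse ratio-variance
  weights, linear interpolation at 0.5; SE by parametric bootstrap
  (resampling betas from their SEs, default 1000 draws, seeded).
- **Weighted mode**: weighted normal-kernel density of the ratios with
  bandwidth $\varphi \times 0.9\,\min(\mathrm{sd}, \mathrm{mad})\,
  n^{-1/5}$ (default $\varphi = 1$); the estimate is the density argmax on
  a 512-point grid spanning the ratios $\pm 3$ bandwidths, augmented with
  the ratio values themselves so narrow-bandwidth spikes cannot fall
  between grid points; bootstrap SE.
- **MR-PRESSO**: observed weighted residual sum of squares around
  leave-one-out IVW predictions, compared against parametric simulations
  under the no-pleiotropy model (outcome betas redrawn about their
  leave-one-out predictions; default 1000 simulations, seeded). The global
  p is the exceedance fraction; per-SNP outlier p-values are Bonferroni
  corrected; when outliers are found an outlier-corrected IVW estimate is
  reported together with a distortion p built by removing equally many
  randomly chosen SNPs (the reference implementation bootstraps outlier
  assignment instead; the random-removal null is this package's documented
  construction). With no outliers no corrected estimate is produced. Note
  the resolution limit of simulation p-values: with $n_{sim}$ simulations
  the smallest Bonferroni-corrected outlier p is $n/(1+n_{sim})$, so
  flagging at $\alpha = 0.05$ across 50 SNPs needs $n_{sim} \ge 1000$.
- **Multivariable MR**: weighted regression of $\beta_Y$ jointly on both
  exposures' betas without intercept; reports the primary-exposure
  coefficient. The generator can correlate the two exposures' true effects
  (`exposureCorrelation`), which is what makes univariable IVW biased and
  gives the adjustment something to correct; with independent architectures
  a second-exposure pathway only adds variance.

All estimators are invariant to SNP order and to joint sign flips of
$(\beta_X, \beta_Y)$, verified by property tests.

## The synthetic-data generator

`generateCohort()` draws the 13 covariates from the published marginal
summaries (normals for age, Townsend, BMI, height, blood pressure,
spherical equivalent; categorical draws for sex, ethnicity, smoking,
season, diabetes; a gamma for physical activity, whose mean roughly equals
its SD), assigns drinking categories with probabilities
(4.8, 11.9, 79.7, 3.6)% and gives regular drinkers a log-normal weekly
intake calibrated to median 91.3 and SD 111 g/week (the distribution family
is a modeling choice; only the median/IQR and the per-SD scale are
published, and they indicate strong right skew). Solving
$\mathrm{SD}^2/m^2 = (e^{\sigma^2}-1)e^{\sigma^2}$ gives
$\sigma \approx 0.77$, implying an IQR of roughly (54, 154) g/week against
the published (43, 171) — an acceptable two-summary fit. Intake is then
expressed as integer portion counts (weekly counts for at-least-weekly
frequencies, monthly otherwise, with per-person beverage preferences), and
the grams implied by those counts are recomputed and used everywhere
downstream, so questionnaire rounding is not a source of exposure
measurement error.

Outcomes follow explicit generative models: continuous outcomes are
baseline + category contrast + confounder terms + per-SD effect
$\times$ trim-standardized intake (+ intake $\times$ PRS interaction for
IOP) + Gaussian noise; glaucoma is a logistic model whose intercept is set
so the marginal prevalence hits 1.8%. Intake and all outcomes share a
standardized 0.05 loading on age, sex, BMI, systolic blood pressure and
current smoking, inducing genuine confounding that the adjusted models must
remove. Default effects are +0.08 mmHg, $-0.17\,\mu m$, $-0.34\,\mu m$ and
OR 1.11 per SD, category contrasts matching the published categorical
results (e.g. regular-vs-infrequent IOP +0.17 mmHg, former-drinker glaucoma
OR 1.53), and an IOP interaction of 0.05 mmHg per SD intake per SD PRS —
the value implied by the published quintile gradient, since the mean of the
top quintile of a standard normal is $\phi(z_{0.8})/0.2 \approx 1.40$ and
$0.08 + 1.40 \times 0.05 = 0.15$.

Two calibration subtleties deserve emphasis:

- **Exposure scale.** Effects apply to the *trim-standardized* intake — the
  same quantity the analysis regresses on — not to a latent untrimmed
  scale. A heavy-tailed intake loses a material share of its SD to the 1%
  trim, so defining effects on the untrimmed scale would attenuate every
  recovered coefficient by the SD ratio.
- **IOP tail trimming.** Trimming the top/bottom $p = 0.5\%$ of the derived
  IOP truncates the outcome's noise tails, which attenuates every
  regression contrast on the trimmed sample by
  $\gamma = 1 - \frac{|z_{p}|\phi(z_{p}) + z_{1-p}\phi(z_{1-p})}{1-2p}
  \approx 0.925$ for normal residuals. The configured IOP effects are
  therefore treated as the estimands of the trimmed analysis — which is
  the analysis the published coefficients came from — and the latent
  effects are pre-compensated by $1/\gamma$ (the factor degenerates to 1
  at zero noise or zero trim). Without this, recovery simulations sit a
  systematic 8% low.

Cases are expressed through the raw phenotype surface: self-report flags
and/or ICD records (60% both, 20% self-report only, 20% codes only, with
qualifying codes placed inside the ascertainment window), a small share of
under-30 diagnoses and suspect-code or irrelevant-code carriers to exercise
every exclusion rule, treatment flags (50% of cases, 1% of controls, which
also scales their measured IOP by 0.7), surgery/trauma exclusion flags, and
mean-preserving left/right eye splits with small one-eye/both-eye
missingness. One integer seed drives everything through a single RNG scope
that restores the caller's random state.

`generateSummaryStats()` draws true per-allele exposure effects
$N(0, 0.01^2)$, exposure SEs $1/\sqrt{941{,}280}$ and outcome SEs
$\mathrm{SD}_Y/\sqrt{31{,}434}$ (the default mGCIPL scenario with
$\mathrm{SD}_Y = 5.2\,\mu m$ and true effect $-1.52\,\mu m$/SD over 80
independent SNPs), with optional balanced/directional pleiotropy, planted
outliers at a configurable shift, an ADH1B-like flagged variant
(id rs1229984, negative effect at $6\times$ the effect-size SD), a
correlated second exposure, and a `noiseScale` knob whose zero setting
yields the exact noiseless limit. SNPs are independent; no linkage
disequilibrium is simulated.

**What the synthetic data do not emulate** — and hence what passing tests
do not establish about real data: questionnaire field encodings and
item-level missingness; non-normal covariate shapes and covariate
*correlations* (only marginals are matched); selection ("healthy
volunteer") bias; measurement error and under-reporting of intake beyond
portion rounding; differential outcome missingness; linkage disequilibrium
and weak-instrument structure in the GWAS layer; and any real genetic
architecture behind the PRS. Parameter-recovery results certify the
*estimators* under the assumed generative models, not the substantive
findings.

## Numerical choices and degenerate inputs

Percentile operations use type-7 interpolation throughout. Quantile and
quintile boundaries are lower-closed; ties go down. Logistic fits warn on
coefficients above 15 in absolute value (quasi-separation) and error on
rank deficiency, naming the collinear terms. `rcsBasis()` rejects unsorted
or duplicated knots; `fitRCS()` skips candidate knot counts whose
percentile knots collide on ties. Wald-ratio SEs are first-order by
default. Bootstrap and simulation procedures take explicit seeds and run
under the same RNG-scoping helper as the generators, so library calls never
perturb user randomness. The weighted-mode density grid always contains the
ratio points themselves. MR-PRESSO requires at least 4 SNPs and 100
simulations; Egger, median, mode and MVMR require 3.

## Problem sizes used in validation

The test suite regenerates everything from code: parameter-recovery checks
run three cohorts of $n = 100{,}000$ at distinct seeds and compare the
pooled estimate with the configured truth within Monte-Carlo bands;
type-I-error calibration of Cochran's Q, the Egger intercept, the
interaction and the trend tests uses 1000 null replicates each (binomial
99% band around 5%); MR-PRESSO outlier detection uses 100 replicates of a
50-SNP instrument with one 10-SE outlier. The acceptance script averages 16
cohorts and 40 instruments. These sizes were chosen to keep Monte-Carlo
error well below the corresponding effect sizes.

## Known limitations

Covariates are generated independently of one another (their confounding
path runs through shared loadings on intake and outcomes, not through a
realistic joint distribution). The beverage table is a stand-in. The
age-at-diagnosis exclusion uses record-level ages because the source of
that age is not specified. Goldmann-correlated IOP, LD clumping, MTAG, and
visual-field grading are out of scope. The MR layer assumes independent
instruments; applying it to clumped real summary statistics is supported
through the file adapters (`readSummaryStats()`), but LD-aware methods are
not provided.
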