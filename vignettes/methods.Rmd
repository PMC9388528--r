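---
title: "Models and methods: from gaze traces and genotypes to association tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from gaze traces and genotypes to association tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oculoprs)
```

## What the package computes

`oculoprs` implements the analysis chain of a population-based study that
asks whether polygenic risk for Alzheimer's disease is associated with
cognitive and oculomotor performance. The chain has five stages, each of
which can be used on its own:

1. **Oculomotor signal processing** — detect saccades and blinks in raw
   1000 Hz gaze traces and reduce four tasks (fixation, smooth pursuit,
   prosaccade, antisaccade) to 16 per-subject outcome measures.
2. **Genetics** — variant and sample quality control, genome-wide
   significance filtering of a GWAS weight table, weighted polygenic score
   (PRS) construction with z-standardization, and genetic principal
   components.
3. **Association statistics** — multivariable linear models, a one-inflated
   beta regression for the antisaccade correction rate, gene–age
   interaction tests, Benjamini–Hochberg FDR within fixed families, risk
   groups and Tukey slope contrasts, and predictive-mean-matching
   imputation of covariates.
4. **Power** — the analytic noncentral-F power of the one-predictor test.
5. **Synthetic data** — a generator that emulates all the inputs
   (genotypes, weights, covariates, outcomes, gaze recordings) with known
   ground truth, so every stage is testable without access to cohort data,
   which for the motivating study is not public.

## Oculomotor event detection

Velocity is estimated by smoothing positions with a centred moving average
(7 ms at 1000 Hz) and applying a 5-point central difference; speed is the
Euclidean norm of the two velocity components and acceleration its first
difference. A sample is a saccade candidate when speed reaches 60 deg/s, or
22 deg/s together with an acceleration magnitude of 3800 deg/s²; candidate
runs are bounded by the surrounding 22 deg/s crossings, runs closer than
20 ms are merged (dynamic overshoot otherwise double-counts), and events
with amplitude ≤ 1° are discarded.

Two numerical choices matter here. First, *detection* runs on a more
heavily smoothed trace (21 ms) than *measurement* (7 ms): at a realistic
tracker noise of 0.1° RMS, the 7 ms velocity trace crosses 22 deg/s on
almost half of all samples, which makes run extension and merging
meaningless, while the 21 ms trace keeps noise far below the thresholds.
Event boundaries and kinematics are then refined on the 7 ms trace, so on
clean data onsets are recovered to within a millisecond and peak velocity
within 2%. Second, the boundary convention defines a saccade's onset as its
22 deg/s crossing; the simulator logs ground-truth onsets at the same
analytic crossing of its noiseless velocity profile, so detector and ground
truth speak the same language.

Task summaries follow the study's definitions. Fixation spatial error is
the root-mean-square Euclidean distance between gaze and the current target
over fixation periods (≥ 100 ms without saccades or padded blinks); a
refoveation grace interval after each target jump (until the first
subsequent saccade lands) keeps the saccade-latency period from being
scored against the new target. Pursuit velocity gain averages, over the
middle two temporal quarters of every complete half-cycle, the ratio of
mean horizontal eye velocity (41 ms smoothing — pursuit is an order of
magnitude slower than saccades, so the heavier low-pass is unbiased at
0.5 Hz) to mean target velocity over pursuit-classified samples
(speed < 30 deg/s in runs ≥ 50 ms, outside detected saccades). Saccade
trials are valid when fixation held the centre (≤ 3° off) for the 100 ms
before target onset without saccades or blinks, and the initial saccade
(≥ 80 ms latency) ended before the 1 s target timeout. Left-side trials are
mirrored so one code path scores both sides; spatial error is
|landing − required position| / eccentricity × 100, commensurate with
amplitude gain, so for a centre-origin horizontal saccade landing at gain
g% the spatial error is |g − 100|%.

Aggregation enforces the reliability floors: prosaccade/antisaccade means
require ≥ 7 valid trials with a directionally correct initial saccade; the
direction error rate requires ≥ 7 valid trials; the correction rate is
reported only for subjects with ≥ 5 direction errors of whom at least one
was corrected, and a subject with ≥ 5 errors and no correction at all has
all antisaccade outcomes withheld. Absent outcomes are `NA` (blank fields
on disk), never zero.

## Genetics

Variant QC drops call rate < 99%, folded MAF < 0.01 and Hardy–Weinberg
exact p < 1e-6; sample QC drops call rate < 95% and heterozygosity beyond
±3 SD of the cohort mean (the study says only "abnormal heterozygosity";
±3 SD is the conventional reading). The HWE test is the exact conditional
test: given the allele counts, the p-value is the probability mass of all
heterozygote counts no more probable than the observed one, enumerated in
full. Relatedness and sex-mismatch checks need data the synthetic module
does not model; their reason codes are reserved in the report schema.

A weight table keeps only variants with GWAS p strictly below 5e-8. The PRS
is the weighted sum of effect-allele dosages, with alleles harmonized
against the genotype file (dosage flipped to `2 − dosage` when the counted
allele is the other allele; strand-ambiguous A/T and C/G variants are kept
with a warning since the synthetic data controls strands), missing dosages
imputed with the variant's cohort mean (the PLINK score default), and the
z-score standardized with the sample SD (denominator n − 1). Principal
components come from the column-standardized dosage matrix with a fixed
sign convention (largest-magnitude loading positive).

## Association models

Every outcome is modelled as

```
outcome ~ PRS_z + age_c + age_c² + sex + PC1 … PC6
```

with age mean-centred before squaring to reduce collinearity. Seven
outcomes with right-skewed distributions (trail-making A and B, fixation
spatial error, fixation saccade and blink rates, prosaccade and antisaccade
spatial error) are natural-log transformed; `log_transformed_outcomes()`
returns the list. The interaction test adds `PRS_z:age_c` and
`PRS_z:age_c²` and compares the nested models on identical rows. The
primary statistic is the 2-df F; the asymptotically equivalent likelihood
ratio chi-square is reported alongside, since for Gaussian linear models
the two are monotone transforms of one another. FDR control is
Benjamini–Hochberg within a fixed family of 28 comparisons per score (27
for the interaction family, which has no correction-rate test), with the
family size counting tests even when a synthetic run carries fewer
outcomes.

Risk groups cut the z-standardized PRS at ±1, boundary values falling in
the medium group. Tukey slope contrasts compare the groups' marginal linear
age trends: because age is mean-centred, the average derivative of the
fitted quadratic over the observed ages is the group's `age_c` coefficient,
so the contrasts are linear functions of the coefficient vector with exact
SEs from its covariance; p-values use the studentized range with k = 3.
Whether the motivating analysis contrasted marginal trends or slopes at a
reference age is not documented; the marginal-trend convention is used
because it does not privilege an arbitrary age.

Missing covariates are imputed by predictive mean matching: each incomplete
numeric covariate is regressed on the complete ones, every missing case is
matched to the five observed cases with the nearest predictions, the model
is refit on ten bootstrap resamples, and the imputed value is drawn from
the pooled donors — so imputations always lie in the observed support.

## The one-inflated beta regression

The antisaccade correction rate is a proportion in (0, 1] with a large
point mass at exactly 1 (most subjects correct every error), too skewed for
any transform. `oibeta()` fits the mixture

* P(y = 1) = logistic(x'γ) — "does the subject correct *all* errors?", and
* y | y < 1 ~ Beta(μφ, (1 − μ)φ) with logit(μ) = x'β — "what fraction is
  corrected otherwise?",

by maximum likelihood. The likelihood factorizes, so the logistic part is
an ordinary binomial GLM on the ceiling indicator and the beta part is
maximized by BFGS with the analytic gradient, φ on the log scale, started
from moment estimates (logit of the mean; precision from the variance) and
declared converged below a 1e-8 gradient-norm tolerance. `summary()`
reports Wald z tests and, for the logistic part, odds ratios per unit
predictor: OR < 1 for the PRS means higher genetic risk lowers the odds of
correcting all errors. Effects on the complementary "percentage
uncorrected" scale are the same coefficients with flipped signs. The fit
requires at least one observation at the ceiling and one below it;
anything else is degenerate and raises an error.

## Power

The post-hoc power of the one-predictor F-test uses the noncentral F
distribution with numerator df 1, denominator df n − 2 and noncentrality
λ = f²·n — the convention of the standard power calculators for the "R²
increase" design. The alternative convention λ = f²·(n − 2) differs by
less than 10⁻³ in power at n = 5182, but the convention is pinned because
the quantity is reproduced to a printed percentage. At n = 5182 and
α = 0.05 the computed powers at f² = 0.0020, 0.0015, 0.0010 are 89.6%,
79.6% and 62.4%, which round to the 90%, 80% and 62% the study reports;
`detectable_effect()` inverts the curve by bracketed root search.

## The synthetic cohort and what it does not show

The generator's defaults are the study's conditions: ages uniform on
30–95 years (the real cohort is not uniform, but uniform maximizes
interaction-detection power in tests), 55.8% women, genotypes
Binomial(2, MAF) with MAF uniform on a configurable range and no linkage
disequilibrium, weight tables with exactly the requested number of
genome-wide significant variants (29/36/37 in the three-score default),
and a 28-outcome battery whose means and dispersions follow the study's
descriptive table. The planted effect structure is deliberately sparse: a
Corsi-forward effect of −0.038 blocks per SD of PRS at residual SD 1.1 and
a correction-rate ceiling odds ratio of 0.884 per SD, the study's two
headline associations; every other outcome carries a zero PRS effect.

The gaze simulator synthesizes saccades with a raised-cosine velocity
profile on the main sequence `V_peak = V_max (1 − exp(−A/c))` with defaults
V_max = 600 deg/s, c = 10° — chosen so a 9.63° saccade peaks near
370 deg/s, the magnitude the study reports for prosaccades. Latencies are
truncated normal with a configurable floor at 80 ms (lower it explicitly to
synthesize anticipatory saccades for negative tests); correct antisaccades
add a 90 ms cost. Direction errors occur with a configurable probability
(default 0.3, matching the reported 31.6% mean error rate) and are followed
by a midline-crossing corrective saccade with probability 0.95. Blinks are
Poisson events (100–300 ms) whose samples are flagged and blanked; pursuit
is the attenuated sinusoid `gain × target` plus optional catch-up saccades
that step the eye back onto the target. Tracker noise defaults to 0.05° per
axis, the magnitude of a video-based research tracker.

What passing tests on these data do **not** show: the generator has no
linkage disequilibrium, no population stratification beyond synthetic PC
covariates, no drift, microsaccades or pupil artefacts in the gaze traces,
no skew or heteroscedasticity beyond the planted log-scale outcomes, and
cognitive test scores are drawn directly from the generating model rather
than administered instruments. Recovery results here validate the *code*,
not the transportability of the study's estimates.

## Problem sizes and reproducibility

Every random step takes an explicit integer seed, and identical
configurations reproduce byte-identical output files. The test-suite and
acceptance problem sizes are chosen to give stable Monte-Carlo verdicts at
interactive runtimes: 100 simulated sessions per detector check, 500
replicates for the odds-ratio coverage at n = 5000, 1000 null simulations
(n = 200 each) for the interaction-test size, 50 end-to-end runs at
n = 3000, and full enumeration of all genotype tables with total ≤ 200 for
the Hardy–Weinberg oracle comparison. The pipeline's gaze branch
(`gaze_tasks = TRUE`) rasterizes roughly 250k samples per subject and is
meant for smoke-scale runs (tens of subjects); statistical studies at
thousands of subjects use the cohort-level outcome generator directly, and
the two branches share every downstream code path.

Under those planted study conditions the per-family minimum raw p-value
lands on one of the two planted outcomes in roughly three quarters of
end-to-end runs at n = 3000 — the planted Corsi effect corresponds to
t ≈ 1.9 and the correction-rate effect to z ≈ 2.8, so the smallest of the
26 null p-values frequently undercuts them. This is a property of the
planted magnitudes, which are kept at the study's reported values rather
than inflated to make localisation look sharper.

## Known limitations

* The ASC importer reads only the plain-text sample/MSG dialect and
  assumes coordinates already in degrees.
* The beta-part covariance comes from the numerical Hessian at the optimum;
  with very few below-ceiling observations it can be singular, in which
  case SEs are `NA` and the convergence flag should be inspected.
* The QC heterozygosity rule re-estimates its bounds on each call, so
  re-filtering an already filtered cohort can, rarely, exclude further
  borderline samples.
* Vertical saccade components are carried through kinematics but not scored
  as outcomes; pursuit is horizontal only.
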