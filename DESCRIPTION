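Package: oculoprs
Title: Polygenic Risk Scores, Oculomotor Metrics and Association Models for
    Population Cognitive Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline linking polygenic risk for Alzheimer's
    disease to cognitive and oculomotor performance in population-based
    cohorts. Provides saccade, fixation and smooth-pursuit event detection
    and per-subject eye-movement outcome extraction from raw gaze traces;
    genotype quality control (Hardy-Weinberg exact test, call-rate and
    allele-frequency filters), genome-wide-significance filtering, weighted
    polygenic score construction and principal components; multivariable
    linear association models with age, age-squared and sex adjustment,
    gene-age interaction tests, Benjamini-Hochberg false-discovery-rate
    control, Tukey slope contrasts and predictive-mean-matching imputation;
    a one-inflated beta regression (a logistic/beta mixture for bounded
    outcomes with a point mass at one) fitted by maximum likelihood; an
    analytic noncentral-F power calculator; and a synthetic-data generator
    that emulates 1000 Hz gaze recordings, genotype dosages, GWAS weight
    tables and cohort covariates with planted, configurable effect
    structure so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    emmeans,
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
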