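#' Cohort simulation configuration
#'
#' Defines the synthetic cohort: its size, age range (uniform draw), sex
#' ratio, and the genotype panel (number of variants, allele-frequency
#' range, number of causal variants entering the weight table, optional
#' missing-call rate). Defaults emulate a middle-aged-to-elderly European
#' population cohort with a genome-wide significant variant panel.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range min/max age in years; ages are drawn uniformly, which is
#'   not how real cohorts are distributed but maximizes power for
#'   interaction tests on synthetic data.
#' @param sex_ratio proportion of women.
#' @param n_snps number of variants in the panel.
#' @param maf_range allele-frequency interval, open at 0 and 0.5.
#' @param n_causal_snps number of variants given genome-wide significant
#'   p-values by [simulate_weight_table()].
#' @param missing_rate probability a dosage call is missing (default 0).
#' @param seed integer seed.
#' @export
cohort_config <- function(n_subjects, age_range = c(30, 95),
                          sex_ratio = 0.558, n_snps = 200,
                          maf_range = c(0.05, 0.45),
                          n_causal_snps = min(29, n_snps),
                          missing_rate = 0, seed = 1L) {
  stopifnot(n_subjects >= 2, length(age_range) == 2,
            age_range[1] < age_range[2],
            sex_ratio >= 0, sex_ratio <= 1, n_snps >= 1,
            missing_rate >= 0, missing_rate < 1,
            n_causal_snps <= n_snps)
  if (!(maf_range[1] > 0 && maf_range[1] <= maf_range[2] &&
        maf_range[2] < 0.5))
    stop("maf_range must satisfy 0 < low <= high < 0.5")
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 sex_ratio = sex_ratio, n_snps = as.integer(n_snps),
                 maf_range = maf_range,
                 n_causal_snps = as.integer(n_causal_snps),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generating-model coefficients for one continuous outcome
#'
#' The generating counterpart of the fitted association model:
#' outcome = beta0 + beta_prs * PRS_z + beta_age * age_c +
#' beta_age2 * age_c^2 + beta_sex * sex + beta_prs_by_age * PRS_z * age_c +
#' beta_prs_by_age2 * PRS_z * age_c^2 + N(0, sigma), with age mean-centred.
#' With \code{log_scale = TRUE} the linear predictor lives on the natural
#' log scale and the stored outcome is its exponential, so the analysis
#' model's log transform recovers linearity.
#'
#' @param beta0,beta_prs,beta_age,beta_age2,beta_sex coefficients in outcome
#'   units (per SD of PRS, per year, per year^2, female vs male).
#' @param beta_prs_by_age,beta_prs_by_age2 interaction coefficients.
#' @param sigma residual SD (> 0).
#' @param log_scale generate on the log scale (outcome strictly positive).
#' @export
true_effects <- function(beta0 = 0, beta_prs = 0, beta_age = 0,
                         beta_age2 = 0, beta_sex = 0,
                         beta_prs_by_age = 0, beta_prs_by_age2 = 0,
                         sigma = 1, log_scale = FALSE) {
  stopifnot(sigma > 0)
  structure(list(beta0 = beta0, beta_prs = beta_prs, beta_age = beta_age,
                 beta_age2 = beta_age2, beta_sex = beta_sex,
                 beta_prs_by_age = beta_prs_by_age,
                 beta_prs_by_age2 = beta_prs_by_age2, sigma = sigma,
                 log_scale = log_scale), class = "true_effects")
}

#' Generating parameters for a one-inflated outcome
#'
#' @param gamma0,gamma_prs logistic intercept and PRS slope for
#'   P(outcome = 1).
#' @param mu0,mu_prs beta-part mean model on the logit scale.
#' @param phi beta-part precision (> 0).
#' @export
oneinfl_effects <- function(gamma0 = 1.25, gamma_prs = 0,
                            mu0 = 1.4, mu_prs = 0, phi = 10) {
  stopifnot(phi > 0)
  structure(list(gamma0 = gamma0, gamma_prs = gamma_prs, mu0 = mu0,
                 mu_prs = mu_prs, phi = phi), class = "oneinfl_effects")
}

#' Simulate a genotype dosage matrix
#'
#' Hard-call dosages drawn Binomial(2, MAF_j) per variant, with the MAF of
#' each variant drawn uniformly from the configured range; optional missing
#' entries at the configured rate. Allele pairs are sampled among
#' non-complementary bases so no variant is strand-ambiguous.
#'
#' @param config a [cohort_config()].
#' @return list with \code{dosages} (subjects x variants matrix, dimnames
#'   set) and \code{variants} (id, chrom, pos, effect_allele, other_allele,
#'   maf).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects; m <- config$n_snps
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  D <- vapply(seq_len(m), function(j) stats::rbinom(n, 2, maf[j]),
              numeric(n))
  if (!is.matrix(D)) D <- matrix(D, nrow = n)
  if (config$missing_rate > 0)
    D[stats::runif(length(D)) < config$missing_rate] <- NA
  pairs <- rbind(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"),
                 c("C", "A"), c("G", "A"), c("T", "C"), c("T", "G"))
  pick <- pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(m)),
    chrom = sample(1:22, m, replace = TRUE),
    pos = sort(sample.int(5e7, m)),
    effect_allele = pick[, 1], other_allele = pick[, 2],
    maf = maf, stringsAsFactors = FALSE)
  dimnames(D) <- list(sprintf("S%05d", seq_len(n)), variants$id)
  list(dosages = D, variants = variants)
}

#' Simulate a GWAS weight table
#'
#' Assigns every variant an effect weight (log-odds scale, Gaussian) and a
#' p-value; exactly \code{n_significant} randomly chosen variants receive a
#' p-value strictly below the genome-wide threshold 5e-8, all others at or
#' above it, so the downstream significance filter is exercised.
#'
#' @param variants variant table from [simulate_genotypes()].
#' @param n_significant number of genome-wide significant variants.
#' @param seed integer seed.
#' @param effect_sd SD of the Gaussian effect weights.
#' @return data frame (variant_id, effect_allele, weight, pvalue).
#' @export
simulate_weight_table <- function(variants, n_significant, seed = 1L,
                                  effect_sd = 0.12) {
  m <- nrow(variants)
  stopifnot(n_significant <= m, n_significant >= 0)
  set.seed(seed)
  w <- stats::rnorm(m, 0, effect_sd)
  p <- pmax(stats::runif(m, 5e-8, 1), 5e-8)
  sig <- sample.int(m, n_significant)
  p[sig] <- 10^stats::runif(n_significant, -30, log10(5e-8) - 0.05)
  data.frame(variant_id = variants$id, effect_allele = variants$effect_allele,
             weight = w, pvalue = p, stringsAsFactors = FALSE)
}

#' Simulate covariates and cognitive outcomes
#'
#' Draws age (uniform over the configured range), sex (Bernoulli on the
#' configured ratio, 1 = female), six standard-normal population-structure
#' covariates, and one outcome column per entry of \code{effects}:
#' continuous outcomes from the [true_effects()] linear model with Gaussian
#' noise, and one-inflated outcomes ([oneinfl_effects()]) from the
#' logistic/beta mixture (exactly 1 with the logistic probability, else a
#' beta draw).
#'
#' @param config a [cohort_config()].
#' @param effects named list of [true_effects()] and/or [oneinfl_effects()]
#'   objects; names become outcome columns.
#' @param prs_z vector of z-standardized polygenic scores, one per subject.
#' @param seed integer seed (default derived from the config).
#' @return data frame: subject_id, age, age_c, age_c2, sex, PC1..PC6 and the
#'   outcome columns; attribute \code{log_scale_outcomes} names the columns
#'   generated on the log scale.
#' @export
simulate_covariates_outcomes <- function(config, effects, prs_z,
                                         seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"),
            length(prs_z) == config$n_subjects,
            length(names(effects)) == length(effects))
  set.seed(seed)
  n <- config$n_subjects
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  age_c <- age - mean(age)
  sex <- stats::rbinom(n, 1, config$sex_ratio)
  pcs <- matrix(stats::rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("PC", 1:6)))
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)), age = age,
                    age_c = age_c, age_c2 = age_c^2, sex = sex,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(pcs))
  out$prs_z <- prs_z
  log_cols <- character(0)
  for (nm in names(effects)) {
    ef <- effects[[nm]]
    if (inherits(ef, "oneinfl_effects")) {
      p1 <- stats::plogis(ef$gamma0 + ef$gamma_prs * prs_z)
      mu <- stats::plogis(ef$mu0 + ef$mu_prs * prs_z)
      out[[nm]] <- roibeta(n, p1, mu, ef$phi)
    } else if (inherits(ef, "true_effects")) {
      lp <- ef$beta0 + ef$beta_prs * prs_z + ef$beta_age * age_c +
        ef$beta_age2 * age_c^2 + ef$beta_sex * sex +
        ef$beta_prs_by_age * prs_z * age_c +
        ef$beta_prs_by_age2 * prs_z * age_c^2
      y <- lp + stats::rnorm(n, 0, ef$sigma)
      if (isTRUE(ef$log_scale)) {
        y <- exp(y)
        log_cols <- c(log_cols, nm)
      }
      out[[nm]] <- y
    } else stop("effects entries must be true_effects or oneinfl_effects")
  }
  attr(out, "log_scale_outcomes") <- log_cols
  attr(out, "age_center") <- mean(age)
  out
}

#' Default outcome battery with planted effects
#'
#' The 28-outcome battery mirroring a cognitive and oculomotor test
#' protocol: ten classical cognitive scores, three fixation measures, two
#' smooth-pursuit measures, five prosaccade and seven antisaccade measures,
#' and the one-inflated antisaccade correction rate. By default the
#' polygenic effect is planted on exactly two outcomes: Corsi forward
#' (-0.038 blocks per SD at residual SD 1.1) and the correction-rate
#' ceiling probability (odds ratio 0.884 per SD); all other outcomes carry
#' a zero polygenic effect. Outcomes analysed on the log scale are
#' generated on it.
#'
#' @param beta_corsi planted Corsi-forward effect per SD of PRS.
#' @param or_correction planted odds ratio for correcting all errors.
#' @param null_effects set TRUE to zero the planted effects too.
#' @return named list of effect objects, suitable for
#'   [simulate_covariates_outcomes()].
#' @export
standard_outcomes <- function(beta_corsi = -0.038, or_correction = 0.884,
                              null_effects = FALSE) {
  if (null_effects) { beta_corsi <- 0; or_correction <- 1 }
  g <- function(beta0, sigma, beta_age = 0, beta_prs = 0, log_scale = FALSE)
    true_effects(beta0 = beta0, beta_prs = beta_prs, beta_age = beta_age,
                 beta_age2 = if (beta_age != 0) beta_age / 50 else 0,
                 beta_sex = 0.1 * sigma, sigma = sigma,
                 log_scale = log_scale)
  list(
    digit_span_forward    = g(6.4, 1.2, -0.01),
    digit_span_backward   = g(4.8, 1.2, -0.01),
    corsi_forward         = g(4.9, 1.1, -0.015, beta_prs = beta_corsi),
    corsi_backward        = g(4.8, 1.0, -0.015),
    avlt_immediate_recall = g(51.3, 10.1, -0.2),
    avlt_delayed_recall   = g(10.3, 3.3, -0.06),
    word_fluency          = g(26.4, 6.9, -0.08),
    tmt_a                 = g(log(33), 0.30, 0.012, log_scale = TRUE),
    tmt_b                 = g(log(44), 0.35, 0.014, log_scale = TRUE),
    mwt_b                 = g(30.6, 3.4, 0.02),
    fixation_spatial_error = g(log(0.9), 0.30, 0.004, log_scale = TRUE),
    fixation_saccade_rate  = g(log(0.2), 0.50, 0.003, log_scale = TRUE),
    fixation_blink_rate    = g(log(0.1), 0.60, 0, log_scale = TRUE),
    spem_velocity_gain     = g(78.1, 16.3, -0.35),
    spem_saccade_rate      = g(2.2, 0.6, 0.005),
    prosaccade_latency     = g(190.6, 28.4, 0.5),
    prosaccade_amplitude_gain = g(93.8, 6.7, -0.05),
    prosaccade_spatial_error  = g(log(8.2), 0.45, 0.004, log_scale = TRUE),
    prosaccade_peak_velocity  = g(364.8, 57.6, -0.8),
    prosaccade_adj_peak_velocity = g(3.9, 0.6, -0.005),
    antisaccade_latency    = g(282.0, 50.6, 0.9),
    antisaccade_amplitude_gain = g(112.0, 27.8, -0.1),
    antisaccade_spatial_error  = g(log(26.7), 0.50, 0.004, log_scale = TRUE),
    antisaccade_peak_velocity  = g(346.6, 67.3, -0.8),
    antisaccade_adj_peak_velocity = g(3.2, 0.8, -0.005),
    antisaccade_costs      = g(91.8, 43.1, 0.4),
    antisaccade_error_rate = g(31.6, 23.6, 0.25),
    antisaccade_correction_rate = oneinfl_effects(
      gamma0 = stats::qlogis(0.778), gamma_prs = log(or_correction),
      mu0 = stats::qlogis(0.8), mu_prs = 0, phi = 10)
  )
}

#' Names of outcomes analysed on the natural-log scale
#' @export
log_transformed_outcomes <- function() {
  c("tmt_a", "tmt_b", "fixation_spatial_error", "fixation_saccade_rate",
    "fixation_blink_rate", "prosaccade_spatial_error",
    "antisaccade_spatial_error")
}
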