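#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count (ties included in
#' the tail). Probabilities follow the classical urn distribution
#' P(het = k | n, n_minor) computed by full enumeration over all attainable
#' heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (major homozygote, heterozygote,
#'   minor homozygote; labelling is irrelevant, the test folds alleles).
#' @return the exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)
#' hwe_exact_test(50, 0, 50)   # extreme heterozygote deficit, p < 1e-6
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  na <- 2 * n_aa + n_Aa                  # allele 'a' count
  if (na > n) na <- 2 * n - na           # fold to the minor allele
  if (na == 0) return(1)                 # monomorphic: single configuration
  ks <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  ## log P(het = k) up to the common normalizing constant
  lp <- ks * log(2) - lgamma((na - ks) / 2 + 1) - lgamma(ks + 1) -
    lgamma(n - (na + ks) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, ks)]
  if (is.na(p_obs)) stop("heterozygote count inconsistent with allele count")
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Default quality-control thresholds
#'
#' Variant filters: call rate below 99\%, folded minor allele frequency
#' below 0.01, Hardy-Weinberg exact p below 1e-6. Sample filters: call rate
#' below 95\%, heterozygosity beyond 3 SD of the cohort mean.
#' @export
qc_thresholds <- function(variant_call_rate = 0.99, maf = 0.01,
                          hwe_p = 1e-6, sample_call_rate = 0.95,
                          het_sd = 3) {
  list(variant_call_rate = variant_call_rate, maf = maf, hwe_p = hwe_p,
       sample_call_rate = sample_call_rate, het_sd = het_sd)
}

#' Variant and sample quality control of a dosage matrix
#'
#' Applies the variant filters (call rate, folded MAF, HWE exact test on
#' hard-called genotypes), then the sample filters (call rate over retained
#' variants, heterozygosity outliers). The report lists one exclusion per
#' row with a machine-readable reason. Reason codes for cryptic relatedness
#' and sex mismatch are reserved in the schema but never produced (those
#' checks need IBD and sex-chromosome data).
#'
#' @param genotypes matrix of dosages in [0, 2] (subjects x variants,
#'   dimnames required); missing entries as NA.
#' @param thresholds see [qc_thresholds()].
#' @return list with \code{genotypes} (filtered matrix) and \code{report}
#'   (data frame: unit, id, reason, value).
#' @export
qc_filter <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(is.matrix(genotypes), !is.null(colnames(genotypes)),
            !is.null(rownames(genotypes)))
  th <- thresholds
  rep_rows <- list()
  add <- function(unit, id, reason, value)
    rep_rows[[length(rep_rows) + 1]] <<- data.frame(
      unit = unit, id = id, reason = reason, value = value,
      stringsAsFactors = FALSE)

  ## variant pass
  call_rate <- colMeans(!is.na(genotypes))
  dos_mean <- colMeans(genotypes, na.rm = TRUE)
  maf <- pmin(dos_mean / 2, 1 - dos_mean / 2)
  hard <- round(genotypes)
  hwe <- vapply(seq_len(ncol(genotypes)), function(j) {
    g <- hard[, j]
    hwe_exact_test(sum(g == 0, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                   sum(g == 2, na.rm = TRUE))
  }, numeric(1))
  keep_v <- rep(TRUE, ncol(genotypes))
  for (j in seq_len(ncol(genotypes))) {
    id <- colnames(genotypes)[j]
    if (call_rate[j] < th$variant_call_rate) {
      keep_v[j] <- FALSE; add("variant", id, "low_call_rate", call_rate[j])
    } else if (maf[j] < th$maf) {
      keep_v[j] <- FALSE; add("variant", id, "low_maf", maf[j])
    } else if (hwe[j] < th$hwe_p) {
      keep_v[j] <- FALSE; add("variant", id, "hwe_failure", hwe[j])
    }
  }
  g2 <- genotypes[, keep_v, drop = FALSE]
  if (ncol(g2) == 0) stop("no variants remain after quality control")

  ## sample pass on retained variants
  s_call <- rowMeans(!is.na(g2))
  het <- rowMeans(round(g2) == 1, na.rm = TRUE)
  het_mu <- mean(het); het_sd <- stats::sd(het)
  keep_s <- rep(TRUE, nrow(g2))
  for (i in seq_len(nrow(g2))) {
    id <- rownames(g2)[i]
    if (s_call[i] < th$sample_call_rate) {
      keep_s[i] <- FALSE; add("sample", id, "low_call_rate", s_call[i])
    } else if (het_sd > 0 && abs(het[i] - het_mu) > th$het_sd * het_sd) {
      keep_s[i] <- FALSE; add("sample", id, "abnormal_heterozygosity", het[i])
    }
  }
  g3 <- g2[keep_s, , drop = FALSE]
  if (nrow(g3) == 0) stop("no samples remain after quality control")
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(unit = character(), id = character(), reason = character(),
               value = numeric(), stringsAsFactors = FALSE)
  list(genotypes = g3, report = report)
}

#' Retain genome-wide significant variants of a weight table
#'
#' Keeps rows with p-value strictly below the genome-wide significance
#' threshold (default 5e-8); a p-value exactly at the threshold is dropped.
#'
#' @param weights data frame with columns \code{variant_id},
#'   \code{effect_allele}, \code{weight}, \code{pvalue}.
#' @param threshold significance threshold.
#' @export
select_genome_wide_significant <- function(weights, threshold = 5e-8) {
  stopifnot(all(c("variant_id", "pvalue") %in% names(weights)))
  weights[weights$pvalue < threshold, , drop = FALSE]
}

#' Weighted polygenic risk score
#'
#' Per subject, the weighted sum of effect-allele dosages over the variants
#' of a weight table. Dosages are flipped (2 - dosage) for variants whose
#' counted allele in the genotype data is the weight table's other allele.
#' Missing dosages are imputed with the cohort mean dosage of the variant.
#' The z-score standardizes the raw score to mean 0, SD 1 over the cohort
#' (sample SD, denominator n - 1).
#'
#' @param genotypes dosage matrix (subjects x variants, dosage counted on
#'   \code{variants$effect_allele}).
#' @param weights weight table (variant_id, effect_allele, weight, pvalue).
#' @param variants variant table of the genotype matrix with columns
#'   \code{id}, \code{effect_allele}, \code{other_allele}; if NULL the
#'   weight-table alleles are assumed to match the counted alleles.
#' @return data frame (subject_id, raw, z) with attribute
#'   \code{n_snps_used}.
#' @export
compute_prs <- function(genotypes, weights, variants = NULL) {
  stopifnot(is.matrix(genotypes), nrow(weights) > 0)
  missing_ids <- setdiff(weights$variant_id, colnames(genotypes))
  if (length(missing_ids))
    stop("variants absent from genotypes: ",
         paste(missing_ids, collapse = ", "))
  D <- genotypes[, weights$variant_id, drop = FALSE]
  w <- weights$weight
  flip <- rep(FALSE, nrow(weights))
  if (!is.null(variants)) {
    vt <- variants[match(weights$variant_id, variants$id), ]
    same <- weights$effect_allele == vt$effect_allele
    flip <- weights$effect_allele == vt$other_allele
    if (any(!same & !flip))
      stop("allele mismatch (neither effect nor other allele) for: ",
           paste(weights$variant_id[!same & !flip], collapse = ", "))
    amb <- paste0(pmin(vt$effect_allele, vt$other_allele),
                  pmax(vt$effect_allele, vt$other_allele)) %in% c("AT", "CG")
    if (any(amb))
      warning("strand-ambiguous variants retained: ",
              paste(weights$variant_id[amb], collapse = ", "))
  }
  ## mean-impute missing dosages per variant
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  if (any(flip)) D[, flip] <- 2 - D[, flip]
  raw <- drop(D %*% w)
  s <- stats::sd(raw)
  if (!is.finite(s) || s == 0)
    stop("polygenic score has zero variance; cannot z-standardize")
  out <- data.frame(subject_id = rownames(genotypes), raw = raw,
                    z = (raw - mean(raw)) / s, stringsAsFactors = FALSE)
  attr(out, "n_snps_used") <- nrow(weights)
  out
}

#' Genetic principal components
#'
#' Principal components of the column-standardized dosage matrix (missing
#' dosages mean-imputed, zero-variance variants dropped). The sign of each
#' component is fixed so that its largest-magnitude variant loading is
#' positive.
#'
#' @param genotypes dosage matrix (subjects x variants).
#' @param k number of components (default 6).
#' @return matrix of per-subject scores (n x k, columns PC1..PCk).
#' @export
compute_pcs <- function(genotypes, k = 6) {
  stopifnot(is.matrix(genotypes), nrow(genotypes) > k)
  D <- genotypes
  if (anyNA(D)) {
    mu <- colMeans(D, na.rm = TRUE)
    idx <- which(is.na(D), arr.ind = TRUE)
    D[idx] <- mu[idx[, 2]]
  }
  v <- apply(D, 2, stats::sd)
  D <- D[, v > 0, drop = FALSE]
  if (ncol(D) < k) {
    warning("fewer informative variants than requested components")
  }
  pc <- stats::prcomp(D, center = TRUE, scale. = TRUE)
  kk <- min(k, ncol(pc$x))
  if (kk < k) warning(sprintf("rank deficiency: returning %d components", kk))
  scores <- pc$x[, seq_len(kk), drop = FALSE]
  for (j in seq_len(kk)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  colnames(scores) <- paste0("PC", seq_len(kk))
  rownames(scores) <- rownames(genotypes)
  scores
}

#' Pearson correlations between polygenic scores
#'
#' @param ... two or more numeric vectors (or PRS data frames, whose
#'   \code{z} column is used) of equal length.
#' @return the Pearson correlation matrix.
#' @export
prs_correlations <- function(...) {
  vs <- lapply(list(...), function(x) if (is.data.frame(x)) x$z else x)
  n <- unique(vapply(vs, length, integer(1)))
  if (length(n) != 1) stop("score vectors differ in length")
  m <- do.call(cbind, vs)
  if (is.null(colnames(m)) || any(colnames(m) == ""))
    colnames(m) <- paste0("PRS", seq_len(ncol(m)))
  if (any(apply(m, 2, stats::sd) == 0)) stop("zero-variance score")
  stats::cor(m)
}
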