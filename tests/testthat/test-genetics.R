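test_that("HWE exact test handles the canonical cases", {
  expect_equal(hwe_exact_test(0, 0, 100), 1)
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  ## equilibrium-looking table: matches the enumeration oracle tightly
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  ## extreme heterozygote deficit fails the QC threshold
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  ## allele labelling is irrelevant
  expect_equal(hwe_exact_test(10, 40, 80), hwe_exact_test(80, 40, 10))
  expect_error(hwe_exact_test(0, 0, 0), "zero")
})

test_that("variant QC drops by call rate, folded MAF and HWE", {
  set.seed(10)
  n <- 400
  g <- simulate_genotypes(cohort_config(n_subjects = n, n_snps = 30,
                                        maf_range = c(0.2, 0.4),
                                        seed = 4))$dosages
  ## clean matrix: nothing excluded, and filtering is idempotent
  q1 <- qc_filter(g)
  expect_equal(nrow(q1$report), 0)
  q2 <- qc_filter(q1$genotypes)
  expect_identical(q1$genotypes, q2$genotypes)
  ## 2% missing calls -> call rate 0.98 < 0.99
  g2 <- g
  g2[sample.int(n, 8), 3] <- NA
  q <- qc_filter(g2)
  expect_true("rs000003" %in% q$report$id)
  expect_equal(q$report$reason[q$report$id == "rs000003"],
               "low_call_rate")
  ## folded MAF threshold is sharp at 0.01
  g3 <- g
  g3[, 5] <- rep(0, n); g3[sample.int(n, round(2 * n * 0.009)), 5] <- 1
  g4 <- g
  g4[, 5] <- rep(0, n); g4[sample.int(n, round(2 * n * 0.011)), 5] <- 1
  expect_true("rs000005" %in% qc_filter(g3)$report$id)
  expect_false("rs000005" %in% qc_filter(g4)$report$id)
  ## HWE failure: all heterozygotes
  g5 <- g
  g5[, 7] <- 1
  q5 <- qc_filter(g5)
  expect_equal(q5$report$reason[q5$report$id == "rs000007"], "hwe_failure")
  expect_error(qc_filter(g5[, 7, drop = FALSE]), "no variants")
  ## an all-heterozygous subject is a heterozygosity outlier
  g6 <- rbind(g, rep(1, ncol(g)))
  rownames(g6)[n + 1] <- "OUTLIER"
  q6 <- qc_filter(g6)
  expect_true(any(q6$report$id == "OUTLIER" &
                    q6$report$reason == "abnormal_heterozygosity"))
  ## a subject with 90% missing calls fails the call-rate rule
  g7 <- g
  g7[2, sample.int(30, 27)] <- NA
  ## (missing calls also depress per-variant call rates; relax those)
  q7 <- qc_filter(g7, qc_thresholds(variant_call_rate = 0.9))
  expect_true(any(q7$report$unit == "sample" &
                    q7$report$reason == "low_call_rate"))
})

test_that("genome-wide significance filtering is strictly below 5e-8", {
  w <- data.frame(variant_id = c("a", "b", "c"),
                  effect_allele = "A", weight = 1,
                  pvalue = c(4.9e-8, 5e-8, 0.2))
  kept <- select_genome_wide_significant(w)
  expect_equal(kept$variant_id, "a")
  expect_equal(nrow(select_genome_wide_significant(w[0, ])), 0)
  v <- simulate_genotypes(cohort_config(n_subjects = 50, n_snps = 100,
                                        seed = 3))$variants
  wt <- simulate_weight_table(v, n_significant = 29, seed = 5)
  expect_equal(nrow(select_genome_wide_significant(wt)), 29)
  wt0 <- simulate_weight_table(v, n_significant = 0, seed = 5)
  expect_equal(nrow(select_genome_wide_significant(wt0)), 0)
})

test_that("PRS is the weighted effect-allele dosage sum", {
  g <- matrix(c(0, 1, 2,
                2, 0, 1,
                1, 2, 0), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), c("v1", "v2", "v3")))
  w <- data.frame(variant_id = c("v1", "v2", "v3"),
                  effect_allele = c("A", "A", "A"),
                  weight = c(0.1, -0.2, 0.3), pvalue = 1e-9,
                  stringsAsFactors = FALSE)
  prs <- compute_prs(g, w)
  expect_equal(prs$raw[1], 0.1 * 0 - 0.2 * 1 + 0.3 * 2)   # 0.4
  expect_equal(mean(prs$z), 0, tolerance = 1e-10)
  expect_equal(sd(prs$z), 1, tolerance = 1e-10)
  expect_equal(attr(prs, "n_snps_used"), 3)
  ## variant order is irrelevant
  expect_equal(compute_prs(g, w[3:1, ])$raw, prs$raw)
  ## allele flip with 2 - dosage leaves scores unchanged
  vt <- data.frame(id = c("v1", "v2", "v3"), effect_allele = "A",
                   other_allele = "C", stringsAsFactors = FALSE)
  g_flip <- g; g_flip[, 2] <- 2 - g[, 2]
  w_flip <- w; w_flip$effect_allele[2] <- "C"
  expect_equal(compute_prs(g_flip, w_flip, vt)$raw, prs$raw)
  ## errors: absent variant, zero variance, allele mismatch
  expect_error(compute_prs(g[, 1:2], w), "absent")
  w0 <- w; w0$weight <- 0
  expect_error(compute_prs(g, w0), "zero variance")
  w_bad <- w; w_bad$effect_allele[1] <- "G"
  expect_error(compute_prs(g, w_bad, vt), "mismatch")
})

test_that("vectorized PRS equals a double-loop oracle with missing dosages", {
  set.seed(11)
  g <- simulate_genotypes(cohort_config(n_subjects = 100, n_snps = 50,
                                        missing_rate = 0.05,
                                        seed = 11))
  wt <- simulate_weight_table(g$variants, n_significant = 50, seed = 12)
  prs <- compute_prs(g$dosages, wt, g$variants)
  D <- g$dosages
  raw <- numeric(nrow(D))
  for (i in seq_len(nrow(D))) {
    s <- 0
    for (j in seq_len(nrow(wt))) {
      d <- D[i, wt$variant_id[j]]
      if (is.na(d)) d <- mean(D[, wt$variant_id[j]], na.rm = TRUE)
      s <- s + wt$weight[j] * d
    }
    raw[i] <- s
  }
  expect_equal(prs$raw, raw, tolerance = 1e-12)
  expect_equal(prs$z, (raw - mean(raw)) / sd(raw), tolerance = 1e-12)
})

test_that("genetic PCs are orthogonal, sign-fixed and equivariant", {
  set.seed(12)
  g <- simulate_genotypes(cohort_config(n_subjects = 150, n_snps = 80,
                                        seed = 13))$dosages
  pcs <- compute_pcs(g, k = 6)
  expect_equal(dim(pcs), c(150, 6))
  cp <- crossprod(pcs)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  ## permuting subjects permutes scores identically
  perm <- sample.int(150)
  expect_equal(compute_pcs(g[perm, ], k = 6), pcs[perm, ])
  ## two subpopulations with divergent allele frequencies split on PC1
  n <- 200; m <- 60
  maf_a <- runif(m, 0.1, 0.3); maf_b <- pmin(maf_a + 0.35, 0.49)
  pop <- rep(0:1, each = n / 2)
  D <- t(vapply(pop, function(p)
    rbinom(m, 2, if (p == 1) maf_b else maf_a), numeric(m)))
  dimnames(D) <- list(paste0("s", 1:n), paste0("v", 1:m))
  pc1 <- compute_pcs(D, k = 2)[, 1]
  expect_gt(abs(cor(pc1, pop)), 0.9)
})

test_that("PRS correlations behave as planted", {
  set.seed(13)
  z <- rnorm(300)
  expect_equal(prs_correlations(z, z)[1, 2], 1)
  ## disjoint variant sets on independent genotypes: near-zero correlation
  g <- simulate_genotypes(cohort_config(n_subjects = 4000, n_snps = 40,
                                        seed = 14))
  w1 <- simulate_weight_table(g$variants[1:20, ], 20, seed = 1)
  w2 <- simulate_weight_table(g$variants[21:40, ], 20, seed = 2)
  r <- prs_correlations(compute_prs(g$dosages, w1),
                        compute_prs(g$dosages, w2))[1, 2]
  expect_lt(abs(r), 3 / sqrt(4000))
  expect_error(prs_correlations(z, rep(1, 300)), "zero-variance")
  expect_error(prs_correlations(z, rnorm(10)), "length")
})
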