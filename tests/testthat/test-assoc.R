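make_cohort <- function(n, seed, ...) {
  eff <- list(...)
  if (!length(eff)) eff <- list(y = true_effects(sigma = 1))
  cc <- cohort_config(n_subjects = n, seed = seed)
  z <- rnorm(n); z <- (z - mean(z)) / sd(z)
  simulate_covariates_outcomes(cc, eff, z, seed = seed + 1)
}

test_that("the linear association model is exact OLS", {
  set.seed(50)
  d <- make_cohort(400, 51)
  ## noiseless outcome: coefficient recovered exactly
  d$y2 <- 2 * d$prs_z
  r <- suppressWarnings(fit_linear_model("y2", d))  # perfect-fit warning
  expect_equal(r$result$b, 2, tolerance = 1e-10)
  expect_lt(suppressWarnings(summary(r$fit)$sigma), 1e-10)
  ## coefficients match the normal-equations oracle
  rn <- fit_linear_model("y", d)
  fit <- rn$fit
  X <- model.matrix(fit)
  or <- ols_oracle(X, d$y)
  expect_equal(unname(coef(fit)), unname(or$coef), tolerance = 1e-10)
  expect_equal(unname(summary(fit)$coefficients[, 2]), unname(or$se),
               tolerance = 1e-10)
  ## CI contains the point estimate; p in (0,1]
  expect_true(rn$result$ci_lo < rn$result$b &&
                rn$result$b < rn$result$ci_hi)
  ## log transform demands positivity
  d$neg <- d$y - max(d$y) - 1
  expect_error(fit_linear_model("neg", d, log_transform = TRUE),
               "positive")
})

test_that("t-based confidence intervals cover at the nominal rate", {
  set.seed(52)
  hits <- replicate(400, {
    d <- make_cohort(300, sample.int(1e6, 1),
                     y = true_effects(beta_prs = 0.2, sigma = 1))
    r <- fit_linear_model("y", d)$result
    r$ci_lo <= 0.2 && 0.2 <= r$ci_hi
  })
  se <- sqrt(0.95 * 0.05 / 400)
  expect_lt(abs(mean(hits) - 0.95), 3 * se)
})

test_that("interaction test detects planted moderation and errors on degenerate designs", {
  set.seed(53)
  d <- make_cohort(5000, 54,
                   y = true_effects(beta_prs = 0.05, beta_age = -0.02,
                                    beta_prs_by_age = 0.01, sigma = 1))
  r <- test_interaction("y", d)
  expect_lt(r$p_raw, 0.001)
  expect_equal(r$df1, 2)
  expect_gte(r$F_value, 0)
  ## LRT chi-square is the monotone companion of F
  expect_gt(r$lrt_chisq, 0)
  expect_lt(r$lrt_p, 0.001)
  ## zero-variance interaction columns (constant age) are rejected
  d2 <- make_cohort(200, 55)
  d2$age_c <- 0; d2$age_c2 <- 0
  expect_error(test_interaction("y", d2), "collinear")
})

test_that("BH adjustment follows the step-up definition with fixed m", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03), m = 3), rep(0.03, 3))
  expect_equal(bh_fdr(0.2, m = 1), 0.2)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
  expect_error(bh_fdr(c(0.1, 0.2), m = 1), "family size")
  set.seed(56)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    m <- length(p) + sample(0:10, 1)
    adj <- bh_fdr(p, m)
    expect_equal(adj, bh_oracle(p, m), tolerance = 1e-15)
    expect_true(all(adj >= p & adj <= 1))
    ## monotone in the input ranks: adjustment never reorders tests
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("risk groups partition on the unit z cutoffs", {
  z <- c(-1.5, -1, -0.999, 0, 0.999, 1, 1.5)
  g <- assign_risk_groups(z)
  expect_equal(as.character(g),
               c("low", "medium", "medium", "medium", "medium", "medium",
                 "high"))
  set.seed(57)
  z2 <- rnorm(1e5)
  fr <- as.numeric(table(assign_risk_groups(z2)) / 1e5)
  expected <- c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1))
  for (i in 1:3) {
    se <- sqrt(expected[i] * (1 - expected[i]) / 1e5)
    expect_lt(abs(fr[i] - expected[i]), 3 * se)
  }
  expect_error(assign_risk_groups(c(0, NA)), "finite")
})

test_that("Tukey slope contrasts match emmeans and respect the null", {
  skip_if_not_installed("emmeans")
  set.seed(58)
  n <- 800
  d <- data.frame(age = runif(n, 30, 95))
  d <- center_age(d)
  g <- assign_risk_groups(rnorm(n))
  d$y <- 1 + 0.04 * d$age_c + 0.07 * (g == "high") * d$age_c + rnorm(n)
  mine <- tukey_slope_contrasts(d, g, "y")
  fit <- lm(y ~ g * (age_c + age_c2),
            data = data.frame(y = d$y, g = g, age_c = d$age_c,
                              age_c2 = d$age_c2))
  em <- summary(emmeans::test(
    emmeans::contrast(emmeans::emtrends(fit, ~ g, var = "age_c"),
                      "pairwise")))
  expect_equal(mine$estimate, em$estimate, tolerance = 1e-10)
  expect_equal(mine$p_adj, em$p.value, tolerance = 1e-10)
  ## planted difference only in the high group
  expect_gt(mine$p_adj[1], 0.05)           # low - medium
  expect_lt(mine$p_adj[2], 0.01)           # low - high
  expect_lt(mine$p_adj[3], 0.01)           # medium - high
  ## identical copies of one group: zero differences, p = 1
  d3 <- d[rep(1:200, 3), ]
  g3 <- factor(rep(c("low", "medium", "high"), each = 200),
               levels = c("low", "medium", "high"))
  eq <- tukey_slope_contrasts(d3, g3, "y")
  expect_equal(eq$estimate, rep(0, 3), tolerance = 1e-12)
  expect_equal(eq$p_adj, rep(1, 3))
  expect_error(tukey_slope_contrasts(d[1:5, ], g[c(1, 1, 2, 2, 3)], "y"),
               "at least 3")
})

test_that("Tukey contrasts hold the familywise error near 5% under the null", {
  set.seed(59)
  rej <- replicate(400, {
    n <- 300
    d <- data.frame(age = runif(n, 30, 95))
    d <- center_age(d)
    g <- assign_risk_groups(rnorm(n))
    d$y <- 0.03 * d$age_c + rnorm(n)
    any(tukey_slope_contrasts(d, g, "y")$p_adj < 0.05)
  })
  se <- sqrt(0.05 * 0.95 / 400)
  expect_lt(abs(mean(rej) - 0.05), 4 * se)
})

test_that("predictive mean matching imputes from the observed support", {
  set.seed(60)
  n <- 5000
  d <- data.frame(age = runif(n, 30, 95), sex = rbinom(n, 1, 0.5))
  d$bmi <- 22 + 0.05 * d$age + rnorm(n)
  ## untouched when complete
  expect_identical(pmm_impute(d), d)
  ## MCAR missingness: support property and unbiased mean
  d2 <- d
  miss <- sample.int(n, n * 0.1)
  d2$age[miss] <- NA
  set.seed(61)
  imp <- pmm_impute(d2)
  expect_false(anyNA(imp$age))
  expect_true(all(imp$age[miss] %in% d2$age[-miss]))
  se <- sd(d$age) / sqrt(n)
  expect_lt(abs(mean(imp$age) - mean(d$age)), 3 * se)
  ## a column with nothing observed cannot be imputed
  d3 <- d; d3$age <- NA_real_
  expect_error(pmm_impute(d3), "entirely missing")
})
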