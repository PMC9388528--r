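#' Build the standard analysis frame
#'
#' Adds mean-centred age and its square to a cohort table. Centring is done
#' before squaring, which keeps the linear and quadratic terms nearly
#' orthogonal.
#'
#' @param data cohort data frame with an \code{age} column.
#' @param center optional fixed centring constant; defaults to the mean of
#'   the non-missing ages.
#' @return the data frame with \code{age_c} and \code{age_c2} columns and
#'   attribute \code{age_center}.
#' @export
center_age <- function(data, center = NULL) {
  stopifnot("age" %in% names(data))
  if (is.null(center)) center <- mean(data$age, na.rm = TRUE)
  data$age_c <- data$age - center
  data$age_c2 <- data$age_c^2
  attr(data, "age_center") <- center
  data
}

.assoc_formula <- function(outcome, log_transform, interaction, n_pcs,
                           prs_col = "prs_z") {
  lhs <- if (log_transform) sprintf("log(%s)", outcome) else outcome
  rhs <- c(prs_col, "age_c", "age_c2", "sex",
           if (n_pcs > 0) paste0("PC", seq_len(n_pcs)),
           if (interaction) c(paste0(prs_col, ":age_c"),
                              paste0(prs_col, ":age_c2")))
  stats::as.formula(paste(lhs, "~", paste(rhs, collapse = " + ")))
}

#' Multivariable linear association between a polygenic score and an outcome
#'
#' Ordinary least squares for
#' \code{outcome ~ PRS + age_c + age_c^2 + sex + PC1..PCk}, with the
#' outcome natural-log transformed when flagged. The reported effect is the
#' change in the outcome per one standard deviation of the polygenic score
#' with a t-based 95\% confidence interval and two-sided p-value.
#'
#' @param outcome name of the outcome column.
#' @param data cohort frame containing the outcome, \code{prs_z},
#'   \code{age_c}, \code{age_c2}, \code{sex} and PC columns (see
#'   [center_age()]).
#' @param log_transform natural-log transform the outcome first (requires a
#'   strictly positive outcome).
#' @param interaction also include PRS x age_c and PRS x age_c^2 terms.
#' @param n_pcs number of genetic principal components to adjust for.
#' @param prs_col name of the predictor column.
#' @return list with \code{fit} (the \code{lm} object) and \code{result}
#'   (one-row data frame: outcome, b, ci_lo, ci_hi, p_raw, n_used).
#' @export
fit_linear_model <- function(outcome, data, log_transform = FALSE,
                             interaction = FALSE, n_pcs = 6,
                             prs_col = "prs_z") {
  stopifnot(outcome %in% names(data))
  if (log_transform && any(data[[outcome]] <= 0, na.rm = TRUE))
    stop("log transform requires a strictly positive outcome: ", outcome)
  fml <- .assoc_formula(outcome, log_transform, interaction, n_pcs, prs_col)
  fit <- stats::lm(fml, data = data)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design for ", outcome)
  n <- length(stats::residuals(fit))
  if (n <= length(stats::coef(fit)) + 2)
    stop("too few observations for ", outcome)
  sm <- summary(fit)
  ci <- stats::confint(fit, prs_col, level = 0.95)
  res <- data.frame(outcome = outcome,
                    b = sm$coefficients[prs_col, 1],
                    ci_lo = ci[1], ci_hi = ci[2],
                    p_raw = sm$coefficients[prs_col, 4],
                    n_used = n, stringsAsFactors = FALSE)
  list(fit = fit, result = res)
}

#' Gene-age interaction test for one outcome
#'
#' Compares the base association model with the model extended by
#' PRS x age_c and PRS x age_c^2, on identical rows. The primary statistic
#' is the nested-model F with 2 numerator degrees of freedom; the
#' asymptotically equivalent likelihood-ratio chi-square is reported
#' alongside (for Gaussian linear models the two are monotone transforms of
#' each other).
#'
#' @inheritParams fit_linear_model
#' @return one-row data frame: outcome, F_value, df1, df2, p_raw, lrt_chisq,
#'   lrt_p, n_used.
#' @export
test_interaction <- function(outcome, data, log_transform = FALSE,
                             n_pcs = 6, prs_col = "prs_z") {
  fml0 <- .assoc_formula(outcome, log_transform, FALSE, n_pcs, prs_col)
  vars <- all.vars(fml0)
  cc <- stats::complete.cases(data[, vars, drop = FALSE])
  d <- data[cc, , drop = FALSE]
  fit0 <- stats::lm(fml0, data = d)
  fit1 <- stats::lm(.assoc_formula(outcome, log_transform, TRUE, n_pcs,
                                   prs_col), data = d)
  if (length(stats::residuals(fit0)) != length(stats::residuals(fit1)))
    stop("base and interaction models fitted on different rows")
  df_extra <- fit0$df.residual - fit1$df.residual
  if (df_extra != 2)
    stop("interaction columns collinear with the base model for ", outcome)
  an <- stats::anova(fit0, fit1)
  n <- length(stats::residuals(fit0))
  rss0 <- sum(stats::residuals(fit0)^2)
  rss1 <- sum(stats::residuals(fit1)^2)
  lrt <- n * log(rss0 / rss1)
  data.frame(outcome = outcome, F_value = an$F[2], df1 = 2,
             df2 = fit1$df.residual, p_raw = an$`Pr(>F)`[2],
             lrt_chisq = lrt,
             lrt_p = stats::pchisq(lrt, 2, lower.tail = FALSE),
             n_used = n, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values with a fixed family size
#'
#' Step-up adjustment \code{p(i) * m / i} with running-minimum enforcement
#' and cap at one. The family size \code{m} may exceed the number of
#' p-values supplied (tests absent from the vector count against the family
#' but contribute no discoveries), matching a fixed 28-comparison family.
#'
#' @param p vector of raw p-values in [0, 1].
#' @param m family size, at least \code{length(p)}.
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m below the number of p-values")
  stats::p.adjust(p, method = "BH", n = m)
}

#' Assign polygenic risk groups
#'
#' Low: z below -1; high: z above 1; medium otherwise. Values exactly at
#' the boundaries fall in the medium group (closed interval).
#'
#' @param prs_z vector of z-standardized scores.
#' @return factor with levels low, medium, high.
#' @export
assign_risk_groups <- function(prs_z) {
  stopifnot(all(is.finite(prs_z)))
  factor(ifelse(prs_z < -1, "low", ifelse(prs_z > 1, "high", "medium")),
         levels = c("low", "medium", "high"))
}

#' Tukey contrasts of group-specific age slopes
#'
#' Fits \code{outcome ~ group * (age_c + age_c^2)} and compares the
#' marginal linear age trends of the groups: because age is mean-centred,
#' the average derivative of the fitted quadratic over the observed ages is
#' the group's age_c coefficient, so the pairwise differences are contrasts
#' of those coefficients. P-values use the studentized-range distribution
#' with k = 3 means and the model's residual degrees of freedom, the
#' classical Tukey adjustment.
#'
#' @param data frame with the outcome, \code{age_c}, \code{age_c2} columns.
#' @param groups factor of risk groups (3 levels).
#' @param outcome outcome column name.
#' @return data frame: contrast, estimate (slope difference per year), se,
#'   t, p_adj.
#' @export
tukey_slope_contrasts <- function(data, groups, outcome) {
  stopifnot(is.factor(groups), nlevels(groups) == 3)
  if (any(table(groups) < 3)) stop("each group needs at least 3 subjects")
  d <- data.frame(y = data[[outcome]], g = groups,
                  age_c = data$age_c, age_c2 = data$age_c2)
  fit <- stats::lm(y ~ g * (age_c + age_c2), data = d)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  lv <- levels(groups)
  ## slope of group g = age_c coefficient + its interaction offset
  slope_vec <- function(g) {
    v <- stats::setNames(numeric(length(cf)), names(cf))
    v["age_c"] <- 1
    nm <- paste0("g", g, ":age_c")
    if (nm %in% names(v)) v[nm] <- 1
    v
  }
  combs <- utils::combn(lv, 2, simplify = FALSE)
  df <- fit$df.residual
  out <- lapply(combs, function(pr) {
    l <- slope_vec(pr[1]) - slope_vec(pr[2])
    est <- sum(l * cf)
    se <- sqrt(drop(t(l) %*% V %*% l))
    tval <- est / se
    p <- stats::ptukey(sqrt(2) * abs(tval), nmeans = 3, df = df,
                       lower.tail = FALSE)
    data.frame(contrast = paste(pr[1], "-", pr[2]), estimate = est,
               se = se, t = tval, p_adj = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
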