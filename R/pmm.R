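#' Predictive mean matching imputation of covariates
#'
#' Imputes missing values of numeric covariates by predictive mean
#' matching: each incomplete column is regressed on the complete columns,
#' every missing case is matched to the \code{k} observed cases whose
#' predicted values are nearest to its own prediction, and the imputed
#' value is an observed value drawn from that donor pool. The regression is
#' refitted on \code{n_boot} bootstrap resamples of the complete cases and
#' the final value is drawn from the donors pooled over resamples, which
#' propagates model uncertainty. Imputed values therefore always lie in the
#' observed support of the column.
#'
#' @param data data frame; missingness is allowed only in covariates, all
#'   of which must be numeric where incomplete.
#' @param k donors per match (default 5).
#' @param n_boot bootstrap replicates (default 10).
#' @return the completed data frame.
#' @export
pmm_impute <- function(data, k = 5, n_boot = 10) {
  miss_cols <- names(data)[vapply(data, anyNA, logical(1))]
  if (!length(miss_cols)) return(data)
  full_cols <- names(data)[!vapply(data, anyNA, logical(1)) &
                             vapply(data, is.numeric, logical(1))]
  if (!length(full_cols)) stop("no complete numeric columns to predict from")
  for (col in miss_cols) {
    y <- data[[col]]
    if (!is.numeric(y)) stop("incomplete covariate is not numeric: ", col)
    if (all(is.na(y))) stop("covariate entirely missing: ", col)
    obs <- which(!is.na(y)); mis <- which(is.na(y))
    X <- cbind(1, as.matrix(data[full_cols]))
    donors <- matrix(NA_real_, nrow = length(mis), ncol = n_boot * k)
    for (b in seq_len(n_boot)) {
      idx <- sample(obs, length(obs), replace = TRUE)
      beta <- tryCatch(
        stats::lm.fit(X[idx, , drop = FALSE], y[idx])$coefficients,
        error = function(e) NULL)
      if (is.null(beta)) next
      beta[is.na(beta)] <- 0
      pred <- drop(X %*% beta)
      for (i in seq_along(mis)) {
        d <- abs(pred[obs] - pred[mis[i]])
        near <- obs[order(d)[seq_len(min(k, length(obs)))]]
        donors[i, ((b - 1) * k + 1):((b - 1) * k + length(near))] <- y[near]
      }
    }
    for (i in seq_along(mis)) {
      pool <- donors[i, !is.na(donors[i, ])]
      data[[col]][mis[i]] <- pool[sample.int(length(pool), 1)]
    }
  }
  data
}
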