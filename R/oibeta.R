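#' One-inflated beta regression
#'
#' Fits a mixture model for outcomes on (0, 1] with a point mass at exactly
#' one: a logistic regression for the probability that the outcome equals
#' one, and a beta regression (logit mean link, constant precision phi) for
#' the values strictly inside (0, 1). This is the natural model for bounded
#' rates with a ceiling, e.g. the antisaccade error-correction rate where a
#' majority of subjects correct every error (outcome exactly 1) and the rest
#' correct a fraction.
#'
#' The log-likelihood factorizes into the logistic part (all observations,
#' indicator \code{y == 1}) and the beta part (observations with
#' \code{y < 1}), so the two parts are maximized separately; their sum is
#' the joint maximum likelihood. Both parts share the same design matrix as
#' given by \code{formula}.
#'
#' The logistic coefficient of a predictor, exponentiated, is the odds
#' ratio for attaining the ceiling per unit of that predictor. For effects
#' on the complementary "percentage uncorrected" scale, flip the signs of
#' the reported coefficients (the model is invariant to this relabelling).
#'
#' @param formula model formula; the response must lie in (0, 1].
#' @param data a data frame.
#' @param na.action how to handle missing values (default \code{na.omit}).
#' @param control list with elements \code{maxit} (default 500) and
#'   \code{grad_tol} (gradient-norm convergence tolerance for the beta part,
#'   default 1e-8).
#' @return an object of class \code{"oibeta"} with components
#'   \code{coefficients} (list: \code{logistic}, \code{beta}, \code{phi}),
#'   \code{vcov} (list: \code{logistic}, \code{beta} where the beta block
#'   includes \code{log(phi)}), \code{logLik}, \code{converged},
#'   \code{nobs}, \code{n_ones}.
#' @seealso [summary.oibeta()], [predict.oibeta()], [simulate.oibeta()]
#' @examples
#' set.seed(1)
#' x <- rnorm(500)
#' y <- ifelse(runif(500) < plogis(0.5 - 0.3 * x), 1,
#'             rbeta(500, 0.7 * 8, 0.3 * 8))
#' fit <- oibeta(y ~ x, data.frame(x = x, y = y))
#' summary(fit)
#' @export
oibeta <- function(formula, data, na.action = stats::na.omit,
                   control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, grad_tol = 1e-8), control)
  mf <- stats::model.frame(formula, data, na.action = na.action)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(y <= 0 | y > 1))
    stop("response must lie in (0, 1]")
  ones <- y == 1
  if (all(ones) || !any(ones))
    stop("degenerate outcome: need at least one value equal to 1 and one below 1")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  ## logistic part: P(y == 1)
  lfit <- stats::glm.fit(X, as.numeric(ones), family = stats::binomial())
  gamma <- lfit$coefficients
  w <- lfit$weights
  vcov_l <- solve(crossprod(X * sqrt(w)))
  dimnames(vcov_l) <- list(colnames(X), colnames(X))
  ll_logistic <- sum(stats::dbinom(as.numeric(ones), 1,
                                   lfit$fitted.values, log = TRUE))

  ## beta part on y < 1
  yb <- y[!ones]
  Xb <- X[!ones, , drop = FALSE]
  bp <- .fit_beta_part(yb, Xb, maxit = ctl$maxit, grad_tol = ctl$grad_tol)

  cf <- list(logistic = gamma, beta = bp$beta, phi = bp$phi)
  structure(list(
    coefficients = cf,
    vcov = list(logistic = vcov_l, beta = bp$vcov),
    logLik = ll_logistic + bp$logLik,
    logLik_parts = c(logistic = ll_logistic, beta = bp$logLik),
    converged = bp$converged,
    nobs = length(y), n_ones = sum(ones),
    terms = attr(mf, "terms"),
    xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
    call = match.call(), formula = formula,
    y = y, x = X
  ), class = "oibeta")
}

## maximum likelihood for the beta-regression component:
## y_i ~ Beta(mu_i * phi, (1 - mu_i) * phi), logit(mu_i) = x_i' beta,
## phi estimated on the log scale; analytic gradient, BFGS.
.fit_beta_part <- function(y, X, maxit = 500L, grad_tol = 1e-8) {
  stopifnot(all(y > 0 & y < 1), nrow(X) == length(y))
  p <- ncol(X)
  mu0 <- mean(y)
  v0 <- stats::var(y)
  phi0 <- max(mu0 * (1 - mu0) / max(v0, 1e-8) - 1, 0.05)
  start <- c(stats::qlogis(mu0), rep(0, p - 1), log(phi0))
  if (!"(Intercept)" %in% colnames(X)) start[seq_len(p)] <- 0
  ly <- log(y); l1y <- log1p(-y)

  nll <- function(par) {
    mu <- stats::plogis(drop(X %*% par[seq_len(p)]))
    phi <- exp(par[p + 1])
    a <- mu * phi; b <- (1 - mu) * phi
    -sum(lgamma(phi) - lgamma(a) - lgamma(b) + (a - 1) * ly + (b - 1) * l1y)
  }
  ngr <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    mu <- stats::plogis(eta)
    phi <- exp(par[p + 1])
    a <- mu * phi; b <- (1 - mu) * phi
    dl_dmu <- phi * (ly - l1y - digamma(a) + digamma(b))
    dl_deta <- dl_dmu * mu * (1 - mu)
    dl_dlphi <- phi * sum(digamma(phi) - mu * digamma(a) -
                            (1 - mu) * digamma(b) + mu * ly + (1 - mu) * l1y)
    -c(drop(crossprod(X, dl_deta)), dl_dlphi)
  }
  opt <- stats::optim(start, nll, ngr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = maxit, reltol = 1e-14))
  gnorm <- sqrt(sum(ngr(opt$par)^2))
  converged <- opt$convergence == 0 && gnorm < max(grad_tol, 1e-4 * length(y))
  vc <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, p + 1, p + 1)
  })
  nm <- c(colnames(X), "log(phi)")
  dimnames(vc) <- list(nm, nm)
  beta <- opt$par[seq_len(p)]
  names(beta) <- colnames(X)
  list(beta = beta, phi = exp(opt$par[p + 1]), vcov = vc,
       logLik = -opt$value, converged = converged, grad_norm = gnorm)
}

#' @export
print.oibeta <- function(x, digits = max(3, getOption("digits") - 3), ...) {
  cat("One-inflated beta regression\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Logistic part, P(y = 1):\n")
  print(round(x$coefficients$logistic, digits))
  cat("\nBeta part, logit(mu) on (0,1):\n")
  print(round(x$coefficients$beta, digits))
  cat("\nprecision phi:", format(x$coefficients$phi, digits = digits),
      "  logLik:", format(x$logLik, digits = digits),
      "  n:", x$nobs, sprintf("(%d at ceiling)", x$n_ones), "\n")
  if (!x$converged) cat("Warning: beta part did not converge\n")
  invisible(x)
}

#' @export
coef.oibeta <- function(object, part = c("all", "logistic", "beta"), ...) {
  part <- match.arg(part)
  cf <- object$coefficients
  switch(part,
         logistic = cf$logistic,
         beta = c(cf$beta, phi = cf$phi),
         all = c(stats::setNames(cf$logistic,
                                 paste0("p1_", names(cf$logistic))),
                 stats::setNames(cf$beta, paste0("mu_", names(cf$beta))),
                 phi = cf$phi))
}

#' @export
vcov.oibeta <- function(object, part = c("logistic", "beta"), ...) {
  part <- match.arg(part)
  object$vcov[[part]]
}

#' @export
logLik.oibeta <- function(object, ...) {
  p <- length(object$coefficients$logistic) +
    length(object$coefficients$beta) + 1L
  structure(object$logLik, df = p, nobs = object$nobs, class = "logLik")
}

#' Summary of a one-inflated beta regression fit
#'
#' Coefficient tables with Wald z statistics for both mixture components.
#' The logistic table carries odds ratios and their 95\% confidence
#' intervals for P(outcome = 1).
#'
#' @param object an \code{oibeta} fit.
#' @param ... unused.
#' @export
summary.oibeta <- function(object, ...) {
  mk <- function(est, vc) {
    se <- sqrt(diag(vc))
    z <- est / se
    cbind(Estimate = est, `Std. Error` = se, `z value` = z,
          `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  }
  lt <- mk(object$coefficients$logistic, object$vcov$logistic)
  or <- cbind(OR = exp(lt[, 1]),
              `2.5 %` = exp(lt[, 1] - 1.959963984540054 * lt[, 2]),
              `97.5 %` = exp(lt[, 1] + 1.959963984540054 * lt[, 2]))
  bt <- mk(c(object$coefficients$beta,
             `log(phi)` = log(object$coefficients$phi)),
           object$vcov$beta)
  structure(list(call = object$call, logistic = lt, odds_ratios = or,
                 beta = bt, phi = object$coefficients$phi,
                 logLik = object$logLik, nobs = object$nobs,
                 n_ones = object$n_ones, converged = object$converged),
            class = "summary.oibeta")
}

#' @export
print.summary.oibeta <- function(x, digits = 4, ...) {
  cat("One-inflated beta regression\n")
  cat("Call: ", deparse(x$call), "\n")
  cat(sprintf("\nn = %d, of which %d at the ceiling (y = 1)\n",
              x$nobs, x$n_ones))
  cat("\nLogistic part, P(y = 1):\n")
  stats::printCoefmat(x$logistic, digits = digits, has.Pvalue = TRUE)
  cat("\nOdds ratios (logistic part):\n")
  print(round(x$odds_ratios, digits))
  cat("\nBeta part, logit(mu) for y < 1:\n")
  stats::printCoefmat(x$beta, digits = digits, has.Pvalue = TRUE)
  cat("\nphi =", format(x$phi, digits = digits),
      "  logLik =", format(x$logLik, digits = digits), "\n")
  if (!x$converged) cat("Warning: beta part did not converge\n")
  invisible(x)
}

#' @export
confint.oibeta <- function(object, parm, level = 0.95,
                           part = c("logistic", "beta"), ...) {
  part <- match.arg(part)
  est <- if (part == "logistic") object$coefficients$logistic else
    c(object$coefficients$beta, `log(phi)` = log(object$coefficients$phi))
  se <- sqrt(diag(object$vcov[[part]]))
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - q * se, est + q * se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predictions from a one-inflated beta regression
#'
#' @param object an \code{oibeta} fit.
#' @param newdata optional data frame; the training frame is reused if
#'   omitted.
#' @param type \code{"p1"} for P(y = 1), \code{"mu"} for the beta-part mean,
#'   or \code{"mean"} for the marginal expectation
#'   \code{p1 + (1 - p1) * mu}.
#' @param ... unused.
#' @export
predict.oibeta <- function(object, newdata = NULL,
                           type = c("mean", "p1", "mu"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$x else
    stats::model.matrix(stats::delete.response(object$terms),
                        stats::model.frame(stats::delete.response(object$terms),
                                           newdata, xlev = object$xlevels))
  p1 <- stats::plogis(drop(X %*% object$coefficients$logistic))
  mu <- stats::plogis(drop(X %*% object$coefficients$beta))
  switch(type, p1 = p1, mu = mu, mean = p1 + (1 - p1) * mu)
}

#' @export
fitted.oibeta <- function(object, ...) predict.oibeta(object, type = "mean")

#' @export
residuals.oibeta <- function(object, type = c("response"), ...) {
  type <- match.arg(type)
  object$y - fitted.oibeta(object)
}

#' Simulate responses from a fitted one-inflated beta regression
#'
#' @param object an \code{oibeta} fit.
#' @param nsim number of response vectors.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.oibeta <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- predict.oibeta(object, type = "p1")
  mu <- predict.oibeta(object, type = "mu")
  phi <- object$coefficients$phi
  n <- length(p1)
  out <- as.data.frame(lapply(seq_len(nsim), function(i) {
    y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    y[stats::runif(n) < p1] <- 1
    y
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Draw one-inflated beta variates
#'
#' Random generation from the mixture used by [oibeta()]: with probability
#' \code{p1} the value is exactly 1, otherwise Beta(mu*phi, (1-mu)*phi).
#'
#' @param n number of draws.
#' @param p1 probability of the point mass at one (recycled).
#' @param mu beta-part mean in (0,1) (recycled).
#' @param phi beta-part precision, > 0.
#' @export
roibeta <- function(n, p1, mu, phi) {
  stopifnot(all(p1 >= 0 & p1 <= 1), all(mu > 0 & mu < 1), phi > 0)
  y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
  ## guard against numerical underflow to exactly 0 or 1
  y <- pmin(pmax(y, .Machine$double.eps), 1 - 1e-12)
  y[stats::runif(n) < p1] <- 1
  y
}
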