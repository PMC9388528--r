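#' Analytic power for the fixed-effects regression F-test
#'
#' Computes the power of the F-test for adding \code{df1} predictors to a
#' multiple regression at effect size Cohen's f^2, the convention used by
#' post-hoc power calculators for the "linear multiple regression, R^2
#' increase" design. The test statistic under the alternative follows a
#' noncentral F distribution with noncentrality \eqn{\lambda = f^2 n},
#' numerator degrees of freedom \code{df1} and denominator degrees of
#' freedom \code{n - df1 - 1}.
#'
#' @param f2 Cohen's f^2 effect size (dimensionless, >= 0): the increment in
#'   explained variance divided by the unexplained variance.
#' @param n sample size.
#' @param alpha type-I error rate of the (two-sided on the coefficient,
#'   one-sided on F) test.
#' @param df1 numerator degrees of freedom, i.e. number of tested predictors.
#' @return power as a probability in \code{[alpha, 1]}.
#' @examples
#' power_f_test(f2 = 0.002, n = 5182)   # ~0.90
#' @export
power_f_test <- function(f2, n, alpha = 0.05, df1 = 1) {
  stopifnot(is.numeric(f2), all(f2 >= 0), length(n) == 1, n > df1 + 1,
            length(alpha) == 1, alpha > 0, alpha < 1, df1 >= 1)
  df2 <- n - df1 - 1
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = f2 * n, lower.tail = FALSE)
}

#' Minimum detectable effect size at a target power
#'
#' Inverts [power_f_test()] in f^2 by bracketed root search.
#'
#' @param target_power desired power, must exceed \code{alpha}.
#' @inheritParams power_f_test
#' @return the Cohen's f^2 at which the F-test attains \code{target_power}.
#' @examples
#' detectable_effect(0.80, n = 5182)    # ~0.0015
#' @export
detectable_effect <- function(target_power, n, alpha = 0.05, df1 = 1) {
  stopifnot(length(target_power) == 1, target_power < 1)
  if (target_power <= alpha)
    stop("target_power must exceed alpha (power at f2 = 0 equals alpha)")
  f <- function(f2) power_f_test(f2, n, alpha, df1) - target_power
  upper <- 1
  while (f(upper) < 0) {
    upper <- upper * 10
    if (upper > 1e6) stop("no bracket found for target power")
  }
  stats::uniroot(f, c(0, upper), tol = 1e-10)$root
}
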