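#' Two-sample test of covariance equality in high dimension
#'
#' Tests H0: Sigma1 = Sigma2 for two independent samples when the number
#' of variables may be of the same order as the number of observations,
#' following Schott's (2007, Comput. Statist. Data Anal. 51:6535-6542)
#' trace-based statistic. With sample covariances \eqn{S_k} (divisor
#' \eqn{e_k = n_k - 1}) the squared-distance functional
#' \eqn{tr((\Sigma_1-\Sigma_2)^2)} is estimated unbiasedly by
#' \deqn{t = \hat\eta_1 + \hat\eta_2 - 2\,tr(S_1 S_2),}
#' where \eqn{\hat\eta_k = e_k^2/((e_k-1)(e_k+2)) [tr(S_k^2) -
#' tr(S_k)^2/e_k]} is the unbiased estimator of \eqn{tr(\Sigma_k^2)}
#' (Schott 2007, Sec. 2). Under H0 the statistic standardized by
#' \eqn{\hat\theta = 2 (1/e_1 + 1/e_2)\,\hat\eta} -- with \eqn{\hat\eta}
#' computed from the pooled covariance -- is asymptotically standard
#' normal (Schott 2007, Thm. 1, two-sample case); the p-value is
#' two-sided since the standardized statistic can be negative in finite
#' samples.
#'
#' A significant result (p below `level`, default 0.05) indicates
#' per-class covariances and hence the quadratic flavor of gCDA; otherwise
#' the linear flavor is recommended.
#'
#' @param X1,X2 numeric matrices, samples in rows, with the same number of
#'   columns and at least 4 rows each.
#' @param level decision level for the flavor recommendation.
#' @return An object of classes `schott_covtest` and `htest` with
#'   `statistic` (standardized, N(0,1) under H0), `p.value`, sample sizes
#'   and dimension in `parameter`, and `recommendation`
#'   (`"linear"`/`"quadratic"`).
#' @examples
#' set.seed(1)
#' X1 <- matrix(rnorm(50 * 20), 50)
#' X2 <- matrix(rnorm(50 * 20), 50)
#' schott_test(X1, X2)
#' @export
schott_test <- function(X1, X2, level = 0.05) {
  dname <- paste(deparse1(substitute(X1)), "and", deparse1(substitute(X2)))
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  p <- ncol(X1)
  if (ncol(X2) != p) stop("'X1' and 'X2' must have the same number of columns")
  n1 <- nrow(X1)
  n2 <- nrow(X2)
  if (n1 < 4L || n2 < 4L) {
    stop("at least 4 samples per group are required")
  }
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("'level' must lie in (0, 1)")
  }
  e1 <- n1 - 1
  e2 <- n2 - 1
  S1 <- cov(X1)
  S2 <- cov(X2)
  eta <- function(S, e) {
    e^2 / ((e - 1) * (e + 2)) * (sum(S * S) - sum(diag(S))^2 / e)
  }
  t_stat <- eta(S1, e1) + eta(S2, e2) - 2 * sum(S1 * S2)
  e <- e1 + e2
  Sp <- (e1 * S1 + e2 * S2) / e
  theta <- 2 * (1 / e1 + 1 / e2) * eta(Sp, e)
  z <- t_stat / theta
  pval <- 2 * pnorm(-abs(z))
  out <- list(
    statistic = c(z = z),
    p.value = pval,
    parameter = c(n1 = n1, n2 = n2, p = p),
    method = "Schott two-sample test of covariance equality (high-dimensional)",
    alternative = "the two class covariance matrices differ",
    data.name = dname,
    level = level,
    recommendation = if (pval < level) "quadratic" else "linear"
  )
  class(out) <- c("schott_covtest", "htest")
  out
}
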