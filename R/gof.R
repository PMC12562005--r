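#' One-sample Kolmogorov-Smirnov statistic
#'
#' Discrepancy between the empirical CDF of a sample and a candidate
#' continuous CDF.
#'
#' \code{type = "two_sided"} (default) is the classical statistic
#' \deqn{D = \max_i \max\{i/n - F(x_{(i)}),\ F(x_{(i)}) - (i-1)/n\}}
#' over the sorted sample.  \code{type = "upper_step"} is
#' \eqn{\max_i |F(x_i) - i/n|} evaluated in the order the data are
#' supplied, without sorting: it compares the fitted CDF with the upper
#' empirical step heights only.  This variant is provided for
#' compatibility with published reliability tables computed that way; it
#' equals the two-sided statistic only in special cases and depends on
#' the recorded data order when the sample is not sorted.
#'
#' The p-value uses the asymptotic Kolmogorov series
#' \eqn{p = 2\sum_{k\ge 1} (-1)^{k-1} e^{-2 k^2 n D^2}}.
#'
#' @param x numeric sample.
#' @param cdf vectorized CDF function of one argument.
#' @param type see Details.
#' @return A list with components \code{d} and \code{p}.
#' @examples
#' tiwd_ks(c(1, 2), function(q) ptiwd(q, 1, 1))
#' @export
tiwd_ks <- function(x, cdf, type = c("two_sided", "upper_step")) {
  type <- match.arg(type)
  x <- check_sample(x)
  n <- length(x)
  i <- seq_len(n)
  d <- if (type == "two_sided") {
    Fi <- cdf(sort(x))
    max(pmax(i / n - Fi, Fi - (i - 1) / n))
  } else {
    max(abs(cdf(x) - i / n))
  }
  list(d = d, p = kolmogorov_pvalue(d, n))
}

# asymptotic Kolmogorov tail probability 2 sum (-1)^(k-1) exp(-2 k^2 n d^2)
kolmogorov_pvalue <- function(d, n, kmax = 100L) {
  k <- seq_len(kmax)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * n * d^2))
  min(max(p, 0), 1)
}

#' Information criteria
#'
#' \eqn{AIC = -2\ell + 2k}, \eqn{AICc = AIC + 2k(k+1)/(n-k-1)} and
#' \eqn{BIC = -2\ell + k \log n}.  AICc requires \eqn{n > k + 1}.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size.
#' @return A list with components \code{aic}, \code{aicc}, \code{bic}.
#' @export
tiwd_ic <- function(loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc is undefined for n <= k + 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  aic <- -2 * loglik + 2 * k
  list(aic = aic,
       aicc = aic + 2 * k * (k + 1) / (n - k - 1),
       bic = -2 * loglik + k * log(n))
}

#' Goodness of fit of a TIWD fit
#'
#' Kolmogorov-Smirnov statistic (with asymptotic p-value) and the AIC,
#' AICc and BIC of a fitted TIWD.  Parameters are estimated from the same
#' sample before the KS statistic is computed; no small-sample
#' (Lilliefors-type) correction is applied.
#'
#' @param fit a [tiwd_fit()] object.
#' @param ks_type passed to [tiwd_ks()].
#' @return A list of class \code{"tiwd_gof"} with components \code{ks_d},
#'   \code{ks_p}, \code{aic}, \code{aicc}, \code{bic}, \code{loglik},
#'   \code{k}, \code{n}.
#' @export
tiwd_gof <- function(fit, ks_type = c("two_sided", "upper_step")) {
  stopifnot(inherits(fit, "tiwd_fit"))
  ks_type <- match.arg(ks_type)
  a <- fit$coefficients[1]
  b <- fit$coefficients[2]
  ks <- tiwd_ks(fit$data, function(q) ptiwd(q, a, b), type = ks_type)
  ic <- tiwd_ic(fit$loglik, k = 2L, n = fit$n)
  structure(list(ks_d = ks$d, ks_p = ks$p, aic = ic$aic, aicc = ic$aicc,
                 bic = ic$bic, loglik = fit$loglik, k = 2L, n = fit$n),
            class = "tiwd_gof")
}

#' @export
print.tiwd_gof <- function(x, ...) {
  cat(sprintf("KS D = %.4f (p = %.4f)\n", x$ks_d, x$ks_p))
  cat(sprintf("AIC = %.4f, AICc = %.4f, BIC = %.4f (k = %d, n = %d)\n",
              x$aic, x$aicc, x$bic, x$k, x$n))
  invisible(x)
}
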