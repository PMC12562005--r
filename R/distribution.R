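#' The transformed inverse Weibull distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the transformed inverse Weibull distribution (TIWD) with transform
#' parameter \code{alpha} and shape parameter \code{beta}.
#'
#' The density and distribution function are
#' \deqn{f(x) = \alpha\beta x^{-\beta-1}
#'   e^{\alpha(1 - e^{x^{-\beta}})} e^{x^{-\beta}}, \qquad
#'   F(x) = e^{\alpha(1 - e^{x^{-\beta}})}, \quad x > 0,}
#' and the quantile function is
#' \eqn{Q(w) = [\log(1 - \log(w)/\alpha)]^{-1/\beta}}.
#'
#' All computations are carried out in log space where over/underflow is
#' possible: \eqn{1 - e^{x^{-\beta}}} is evaluated as
#' \code{-expm1(x^(-beta))}, and \eqn{\log(1 - \log(w)/\alpha)} as
#' \code{log1p(-log(w)/alpha)}, so the functions remain accurate for
#' \code{x} near 0 (where \eqn{F} underflows) and for probabilities near 1.
#'
#' @param x,q vector of positive quantiles.
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations.
#' @param alpha positive transform parameter \eqn{\alpha}.
#' @param beta positive shape parameter \eqn{\beta}.
#' @param log,log.p logical; if \code{TRUE}, probabilities/densities are
#'   returned on the log scale.
#' @param lower.tail logical; if \code{TRUE} (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#'
#' @return \code{dtiwd} gives the density, \code{ptiwd} the distribution
#'   function, \code{qtiwd} the quantile function and \code{rtiwd}
#'   generates random deviates by inverse-transform sampling.
#'
#' @examples
#' dtiwd(1, 1, 1)            # exp(2 - e)
#' ptiwd(1, 1, 2)            # exp(1 - e), for any beta
#' qtiwd(0.5, 1, 1)          # the median, 1 / log(1 - log(0.5))
#' set.seed(1); rtiwd(5, 1, 1)
#' @name tiwd-distribution
NULL

#' @rdname tiwd-distribution
#' @export
dtiwd <- function(x, alpha, beta, log = FALSE) {
  check_params(alpha, beta)
  if (any(!is.finite(x) | x <= 0)) {
    stop("'x' must be strictly positive and finite", call. = FALSE)
  }
  u <- x^(-beta)
  # -alpha * expm1(u) is -Inf when u overflows exp(); the density then
  # underflows to 0, which is the correct limit as x -> 0+.
  ld <- log(alpha) + log(beta) - (beta + 1) * log(x) - alpha * expm1(u) + u
  if (log) ld else exp(ld)
}

#' @rdname tiwd-distribution
#' @export
ptiwd <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_params(alpha, beta)
  if (any(!is.finite(q) | q <= 0)) {
    stop("'q' must be strictly positive and finite", call. = FALSE)
  }
  lF <- -alpha * expm1(q^(-beta))    # log F, exact near F = 1
  if (lower.tail) {
    if (log.p) lF else exp(lF)
  } else {
    S <- -expm1(lF)                  # 1 - F without cancellation
    if (log.p) log(S) else S
  }
}

#' @rdname tiwd-distribution
#' @export
qtiwd <- function(p, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  check_params(alpha, beta)
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(!is.finite(p) | p <= 0 | p >= 1)) {
    stop("probabilities must lie strictly inside (0, 1)", call. = FALSE)
  }
  # log1p keeps precision when -log(p)/alpha is tiny (p near 1)
  log1p(-log(p) / alpha)^(-1 / beta)
}

#' @rdname tiwd-distribution
#' @export
rtiwd <- function(n, alpha, beta) {
  check_params(alpha, beta)
  qtiwd(runif(n), alpha, beta)
}

#' Reliability functions of the TIWD
#'
#' Survival, hazard, cumulative-hazard and reversed-hazard functions
#' evaluated on a grid of positive quantiles.
#'
#' The hazard is computed as \eqn{f/S} in log space so it never returns
#' \code{NaN} even where \eqn{F} underflows to 0, and the reversed hazard
#' uses the analytically cancelled form
#' \eqn{r(x) = f/F = \alpha\beta x^{-\beta-1} e^{x^{-\beta}}}.
#'
#' @inheritParams tiwd-distribution
#' @return A data frame with columns \code{x}, \code{sf}, \code{hazard},
#'   \code{cum_hazard} and \code{reversed_hazard}.
#' @examples
#' tiwd_reliability(c(0.5, 1, 2), 1, 1)
#' @export
tiwd_reliability <- function(x, alpha, beta) {
  check_params(alpha, beta)
  if (any(!is.finite(x) | x <= 0)) {
    stop("'x' must be strictly positive and finite", call. = FALSE)
  }
  u <- x^(-beta)
  lF <- -alpha * expm1(u)
  lS <- log(-expm1(lF))              # log survival; 0 when F underflows
  lf <- log(alpha) + log(beta) - (beta + 1) * log(x) + lF + u
  data.frame(
    x = x,
    sf = exp(lS),
    hazard = exp(lf - lS),
    cum_hazard = -lS,
    reversed_hazard = exp(log(alpha) + log(beta) - (beta + 1) * log(x) + u)
  )
}

#' Density of a TIWD order statistic
#'
#' Density of the \eqn{j}-th order statistic of an i.i.d. TIWD sample of
#' size \eqn{n},
#' \deqn{f_{(j)}(x) = \frac{n!}{(j-1)!(n-j)!}
#'   f(x) F(x)^{j-1} [1 - F(x)]^{n-j}.}
#' For \eqn{j = 1} and \eqn{j = n} this reduces to the familiar
#' minimum/maximum forms \eqn{n f (1-F)^{n-1}} and \eqn{n f F^{n-1}}.
#'
#' @param x vector of positive quantiles.
#' @param j rank of the order statistic, an integer in \code{1:n}.
#' @param n sample size.
#' @inheritParams tiwd-distribution
#' @return Density values of \eqn{X_{(j)}}.
#' @examples
#' tiwd_order_statistic(1, j = 3, n = 5, alpha = 1, beta = 1)
#' @export
tiwd_order_statistic <- function(x, j, n, alpha, beta, log = FALSE) {
  check_params(alpha, beta)
  if (length(j) != 1L || length(n) != 1L || j != round(j) || n != round(n) ||
      j < 1 || j > n) {
    stop("'j' must be an integer with 1 <= j <= n", call. = FALSE)
  }
  lF <- ptiwd(x, alpha, beta, log.p = TRUE)
  lS <- ptiwd(x, alpha, beta, lower.tail = FALSE, log.p = TRUE)
  ld <- lgamma(n + 1) - lgamma(j) - lgamma(n - j + 1) +
    dtiwd(x, alpha, beta, log = TRUE) + (j - 1) * lF + (n - j) * lS
  if (log) ld else exp(ld)
}

#' Quantile-based shape measures of the TIWD
#'
#' Bowley (quartile) skewness and Moors (octile) kurtosis,
#' \deqn{S = \frac{Q(3/4) + Q(1/4) - 2 Q(1/2)}{Q(3/4) - Q(1/4)}, \qquad
#'   K = \frac{Q(7/8) - Q(5/8) + Q(3/8) - Q(1/8)}{Q(6/8) - Q(2/8)}.}
#' Both are defined for every parameter pair because they use quantiles
#' only; no moment needs to exist.
#'
#' @inheritParams tiwd-distribution
#' @return A list with components \code{bowley_skewness} and
#'   \code{moors_kurtosis}.
#' @export
tiwd_shape_measures <- function(alpha, beta) {
  Q <- function(w) qtiwd(w, alpha, beta)
  list(
    bowley_skewness =
      (Q(3 / 4) + Q(1 / 4) - 2 * Q(1 / 2)) / (Q(3 / 4) - Q(1 / 4)),
    moors_kurtosis =
      (Q(7 / 8) - Q(5 / 8) + Q(3 / 8) - Q(1 / 8)) / (Q(6 / 8) - Q(2 / 8))
  )
}

#' Tail diagnostics for the TIWD
#'
#' Two numeric witnesses of the heavy (algebraic) tail: the product
#' \eqn{e^{tx} S(x)}, which diverges for every \eqn{t > 0} because the
#' tail is heavier than any exponential, and the Pareto ratio
#' \eqn{S(x) / (\alpha x^{-\beta})}, which tends to 1 because
#' \eqn{S(x) \sim \alpha x^{-\beta}} as \eqn{x \to \infty}.
#'
#' @param t positive exponential rate for the first diagnostic.
#' @param x_grid increasing vector of positive evaluation points.
#' @inheritParams tiwd-distribution
#' @return A data frame with columns \code{x}, \code{etx_sf}
#'   (\eqn{e^{tx}S(x)}; overflows to \code{Inf} for large \eqn{tx}),
#'   \code{log_etx_sf} (its logarithm \eqn{tx + \log S(x)}, always
#'   finite, the quantity to inspect for monotone divergence) and
#'   \code{pareto_ratio}.
#' @examples
#' tiwd_tail_diagnostics(0.1, 10^seq(1, 4, length.out = 10), 1, 1)
#' @export
tiwd_tail_diagnostics <- function(t, x_grid, alpha, beta) {
  check_params(alpha, beta)
  if (length(t) != 1L || !is.finite(t) || t <= 0) {
    stop("'t' must be a positive scalar", call. = FALSE)
  }
  if (is.unsorted(x_grid, strictly = TRUE) || any(x_grid <= 0)) {
    stop("'x_grid' must be strictly increasing and positive", call. = FALSE)
  }
  lS <- ptiwd(x_grid, alpha, beta, lower.tail = FALSE, log.p = TRUE)
  data.frame(
    x = x_grid,
    etx_sf = exp(t * x_grid + lS),
    log_etx_sf = t * x_grid + lS,
    pareto_ratio = exp(lS - log(alpha) + beta * log(x_grid))
  )
}
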