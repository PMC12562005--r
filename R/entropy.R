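# Integral of f(x)^c over (0, Inf), the common building block of the
# Renyi, Tsallis and Mathai-Haubold entropies.  The probability
# substitution x = Q(w) rewrites it as int_0^1 f(Q(w))^(c-1) dw, which
# never truncates the heavy tail.  For c >= 1 that integrand is bounded
# and the whole integral is computed in w.  For c < 1 the integrand
# blows up double-exponentially as w -> 0 (even though it is
# integrable), so the head int_0^m f^c dx is integrated directly in x,
# where it vanishes double-exponentially, and only the tail uses the
# substitution.  The tail converges iff c(beta+1) > 1; divergence is
# reported as an error, never returned as a truncated number.
tiwd_pdf_power_integral <- function(c, alpha, beta) {
  if (c * (beta + 1) <= 1) {
    stop("the integral of f^", c, " diverges in the tail: it requires ",
         "c * (beta + 1) > 1 (here ", c * (beta + 1), " <= 1)",
         call. = FALSE)
  }
  gw <- function(w) {
    exp((c - 1) * dtiwd(qtiwd(w, alpha, beta), alpha, beta, log = TRUE))
  }
  ok <- c("OK", "roundoff error was detected")
  if (c >= 1) {
    lo <- integrate(gw, 0, 0.5, rel.tol = 1e-10, subdivisions = 400L,
                    stop.on.error = FALSE)
  } else {
    m <- qtiwd(0.5, alpha, beta)
    lo <- integrate(function(x) exp(c * dtiwd(x, alpha, beta, log = TRUE)),
                    0, m, rel.tol = 1e-10, subdivisions = 400L,
                    stop.on.error = FALSE)
  }
  hi <- integrate(gw, 0.5, 1, rel.tol = 1e-10, subdivisions = 400L,
                  stop.on.error = FALSE)
  v <- lo$value + hi$value
  if (!(lo$message %in% ok) || !(hi$message %in% ok) || !is.finite(v)) {
    stop("entropy integral did not converge (", lo$message, " / ",
         hi$message, ")", call. = FALSE)
  }
  v
}

#' Entropy measures of the TIWD
#'
#' Shannon, Renyi, Tsallis and Mathai-Haubold entropies of a TIWD with
#' given parameters.  These are model entropies (functionals of the
#' density), not estimates from data.
#'
#' The Shannon entropy is assembled from its expectation decomposition
#' \deqn{H_S = -\log(\alpha\beta) + (\beta+1) E[\log X]
#'   - \alpha E[1 - e^{X^{-\beta}}] - E[X^{-\beta}],}
#' each expectation computed by probability-substitution quadrature
#' (domain \eqn{(0,1)}, so no tail truncation).  The order-\eqn{q}
#' families use the common integral \eqn{I(q) = \int_0^\infty f^q\,dx}:
#' \deqn{H_R(\xi) = \frac{\log I(\xi)}{1-\xi}, \quad
#'   H_T(\delta) = \frac{I(\delta) - 1}{1-\delta}, \quad
#'   H_M(\varsigma) = \frac{I(2-\varsigma) - 1}{\varsigma-1},}
#' so the identity \eqn{H_M(\varsigma) = H_T(2-\varsigma)} holds to
#' machine precision by construction.  \eqn{I(q)} is finite only when
#' \eqn{q(\beta+1) > 1}; outside that region a divergence error is
#' raised (for very small \eqn{\beta} this excludes orders only slightly
#' below 1, where published fixed-window quadratures produce spurious
#' finite values).
#'
#' @param alpha,beta positive TIWD parameters.
#' @param type one of \code{"shannon"}, \code{"renyi"}, \code{"tsallis"},
#'   \code{"mathai_haubold"}.
#' @param order entropy order: \eqn{\xi > 0, \xi \ne 1} for Renyi,
#'   \eqn{\delta \ne 1} for Tsallis (any value with a convergent
#'   integral), \eqn{0 < \varsigma < 2, \varsigma \ne 1} for
#'   Mathai-Haubold.  Ignored for Shannon.
#' @return The entropy value, a real number.
#' @examples
#' tiwd_entropy(1, 1)                              # Shannon
#' tiwd_entropy(1, 1, "renyi", order = 2)
#' tiwd_entropy(1, 1, "mathai_haubold", order = 1.1)
#' @export
tiwd_entropy <- function(alpha, beta,
                         type = c("shannon", "renyi", "tsallis",
                                  "mathai_haubold"),
                         order = NULL) {
  check_params(alpha, beta)
  type <- match.arg(type)
  if (type == "shannon") {
    E_logx <- tiwd_expectation(function(x) log(x), alpha, beta)
    E_one_minus_eu <- tiwd_expectation(function(x) -expm1(x^(-beta)),
                                       alpha, beta)
    E_u <- tiwd_expectation(function(x) x^(-beta), alpha, beta)
    return(-log(alpha * beta) + (beta + 1) * E_logx -
             alpha * E_one_minus_eu - E_u)
  }
  if (is.null(order) || length(order) != 1L || !is.finite(order)) {
    stop("'order' must be a finite scalar for type = '", type, "'",
         call. = FALSE)
  }
  switch(type,
    renyi = {
      if (order <= 0 || order == 1) {
        stop("Renyi order must satisfy order > 0 and order != 1",
             call. = FALSE)
      }
      log(tiwd_pdf_power_integral(order, alpha, beta)) / (1 - order)
    },
    tsallis = {
      if (order == 1) stop("Tsallis order must differ from 1",
                           call. = FALSE)
      (tiwd_pdf_power_integral(order, alpha, beta) - 1) / (1 - order)
    },
    mathai_haubold = {
      if (order <= 0 || order >= 2 || order == 1) {
        stop("Mathai-Haubold order must lie in (0, 2) with order != 1",
             call. = FALSE)
      }
      (tiwd_pdf_power_integral(2 - order, alpha, beta) - 1) / (order - 1)
    }
  )
}
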