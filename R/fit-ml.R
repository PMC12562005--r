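# --- likelihood machinery -------------------------------------------------
# The log-likelihood of an i.i.d. TIWD sample is
#   l(a, b) = n log(ab) - (b+1) sum log x - a sum(e^{x^-b} - 1) + sum x^-b.
# Setting dl/da = 0 gives the closed-form profile a(b) = n / sum expm1(x^-b),
# which is strictly positive; substituting it into dl/db leaves a
# one-dimensional score in b that (by monotonicity of both partial scores)
# has a unique root, found by bracketed bisection.

tiwd_loglik <- function(alpha, beta, x) {
  u <- x^(-beta)
  length(x) * log(alpha * beta) - (beta + 1) * sum(log(x)) -
    alpha * sum(expm1(u)) + sum(u)
}

# a(b) = n / sum(e^{x^-b} - 1); expm1 keeps precision for large x where
# x^-b is tiny.
tiwd_profile_alpha <- function(beta, x) {
  s <- sum(expm1(x^(-beta)))
  if (!is.finite(s) || s <= 0) {
    stop("profile alpha overflowed: e^(x^-beta) is not representable for ",
         "this beta and sample", call. = FALSE)
  }
  length(x) / s
}

# dl/db at (alpha, beta):
#   n/b - sum log x + a * sum e^u u log x - sum u log x,  u = x^-b.
tiwd_score_beta <- function(beta, x, alpha) {
  u <- x^(-beta)
  lx <- log(x)
  length(x) / beta - sum(lx) + alpha * sum(exp(u) * u * lx) - sum(u * lx)
}

# Profile score p(b) = dl/db with alpha = a(b) substituted.  When the
# largest u overflows exp(), alpha * sum(e^u u log x) is evaluated as a
# scaled ratio n * sum(e^{u-m} u log x) / sum(e^{u-m} - e^{-m}) so the
# score stays finite over the whole bracket.
tiwd_profile_score <- function(beta, x) {
  n <- length(x)
  u <- x^(-beta)
  lx <- log(x)
  m <- max(u)
  r <- if (m > 700) {
    sum(exp(u - m) * u * lx) / sum(exp(u - m) - exp(-m))
  } else {
    sum(exp(u) * u * lx) / sum(expm1(u))
  }
  n / beta - sum(lx) + n * r - sum(u * lx)
}

# Root-bracketing for the profile score: start from [1e-3, 64] and expand
# both ends geometrically (up to 2^10-fold) until a sign change appears.
tiwd_ml_bracket <- function(x, lower = 1e-3, upper = 64) {
  f_lo <- tiwd_profile_score(lower, x)
  f_hi <- tiwd_profile_score(upper, x)
  tries <- 0L
  while (is.finite(f_lo) && is.finite(f_hi) && sign(f_lo) == sign(f_hi) &&
         tries < 10L) {
    lower <- lower / 2
    upper <- upper * 2
    f_lo <- tiwd_profile_score(lower, x)
    f_hi <- tiwd_profile_score(upper, x)
    tries <- tries + 1L
  }
  if (!is.finite(f_lo) || !is.finite(f_hi) || sign(f_lo) == sign(f_hi)) {
    stop("the profile score has no sign change on [", format(lower), ", ",
         format(upper), "]; maximum-likelihood estimation failed for this ",
         "sample", call. = FALSE)
  }
  c(lower, upper)
}

tiwd_fit_ml <- function(x) {
  br <- tiwd_ml_bracket(x)
  root <- uniroot(tiwd_profile_score, br, x = x, tol = 1e-12,
                  maxiter = 2000L)
  beta <- root$root
  alpha <- tiwd_profile_alpha(beta, x)
  gnorm <- sqrt(
    (length(x) / alpha - sum(expm1(x^(-beta))))^2 +
      tiwd_score_beta(beta, x, alpha)^2
  )
  list(
    coefficients = c(alpha = alpha, beta = beta),
    loglik = tiwd_loglik(alpha, beta, x),
    objective = NA_real_,
    converged = abs(root$f.root) < 1e-6,
    iterations = root$iter,
    gradient_norm = gnorm
  )
}

#' Observed Fisher information of a TIWD fit
#'
#' The 2x2 observed information matrix (negative Hessian of the
#' log-likelihood) evaluated at \code{(alpha, beta)}, with entries
#' \deqn{I_{11} = n/\alpha^2, \qquad
#'   I_{12} = -\sum e^{u_i} u_i \log x_i, \qquad
#'   I_{22} = n/\beta^2
#'     + \alpha \sum e^{u_i} u_i (\log x_i)^2 (u_i + 1)
#'     - \sum u_i (\log x_i)^2,}
#' where \eqn{u_i = x_i^{-\beta}}, together with its inverse, the
#' asymptotic covariance matrix of the ML estimates.
#'
#' @param alpha,beta positive parameter values (normally ML estimates).
#' @param x the sample the likelihood was built from.
#' @return A list with components \code{info} (the information matrix),
#'   \code{cov} (its inverse), and \code{se} (square roots of the
#'   diagonal of \code{cov}), each labelled by parameter.
#' @export
tiwd_fisher_info <- function(alpha, beta, x) {
  check_params(alpha, beta)
  x <- check_sample(x, min_n = 2L)
  n <- length(x)
  u <- x^(-beta)
  lx <- log(x)
  eu <- exp(u)
  info <- matrix(c(
    n / alpha^2,
    -sum(eu * u * lx),
    -sum(eu * u * lx),
    n / beta^2 + alpha * sum(eu * u * lx^2 * (u + 1)) - sum(u * lx^2)
  ), 2, 2, dimnames = list(c("alpha", "beta"), c("alpha", "beta")))
  cov <- tryCatch(solve(info), error = function(e) {
    stop("Fisher information matrix is singular", call. = FALSE)
  })
  list(info = info, cov = cov,
       se = sqrt(pmax(diag(cov), 0)))
}
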