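# Expectation of g(X) under the TIWD by the probability substitution
# x = Q(w): E[g(X)] = integral of g(Q(w)) over w in (0,1).  Integrating in
# probability space avoids truncating the algebraic tail, which for small
# beta carries mass out to astronomically large x.  The integral is split
# at w = 1/2 because the two endpoints host the (integrable)
# singularities.
tiwd_expectation <- function(g, alpha, beta, rel.tol = 1e-10,
                             subdivisions = 400L) {
  f <- function(w) g(qtiwd(w, alpha, beta))
  lo <- integrate(f, 0, 0.5, rel.tol = rel.tol, subdivisions = subdivisions,
                  stop.on.error = FALSE)
  hi <- integrate(f, 0.5, 1, rel.tol = rel.tol, subdivisions = subdivisions,
                  stop.on.error = FALSE)
  ok <- c("OK", "roundoff error was detected")
  if (!(lo$message %in% ok) || !(hi$message %in% ok) ||
      !is.finite(lo$value + hi$value)) {
    stop("quadrature did not converge (", lo$message, " / ", hi$message,
         "); the integrand may be non-integrable for these parameters",
         call. = FALSE)
  }
  lo$value + hi$value
}

# Moment integral over a probability window [w_lo, w_hi]:
# int Q(w)^r dw.  Near w = 1 the integrand behaves like
# ((1-w)/alpha)^(-r/beta), an algebraic singularity that approaches
# non-integrability as r -> beta and defeats generic quadrature.  The
# substitution w = 1 - z^p with p = beta/(beta - r) removes it exactly:
# the transformed integrand is bounded at z = 0.
tiwd_moment_integral <- function(r, alpha, beta, w_lo = 0, w_hi = 1) {
  stopifnot(r < beta)
  g <- function(w) qtiwd(w, alpha, beta)^r
  mid <- 0.5
  v <- 0
  if (w_lo < min(mid, w_hi)) {
    v <- integrate(g, w_lo, min(mid, w_hi), rel.tol = 1e-10,
                   subdivisions = 400L)$value
  }
  if (w_hi > mid) {
    p <- beta / (beta - r)
    # quantile at w = 1 - z^p evaluated without forming w (which would
    # round to 1 for tiny z): -log(w) = -log1p(-z^p).  Where z^p
    # underflows, the regularized integrand equals its analytic limit
    # p * alpha^(r/beta) up to O(z^p) corrections.
    limit0 <- p * alpha^(r / beta)
    gz <- function(z) {
      out <- rep(limit0, length(z))
      live <- p * log(z) > -200
      if (any(live)) {
        zl <- z[live]
        out[live] <- log1p(-log1p(-zl^p) / alpha)^(-r / beta) *
          p * zl^(p - 1)
      }
      out
    }
    z_hi <- (1 - max(w_lo, mid))^(1 / p)
    z_lo <- (1 - w_hi)^(1 / p)
    v <- v + integrate(gz, z_lo, z_hi, rel.tol = 1e-10,
                       subdivisions = 400L)$value
  }
  v
}

#' Raw moments of the TIWD
#'
#' The \eqn{r}-th raw moment \eqn{\mu'_r = E[X^r]}.  Because the survival
#' function decays like \eqn{\alpha x^{-\beta}}, the moment is finite if
#' and only if \eqn{r < \beta}; for \eqn{r \ge \beta} an error is raised
#' rather than a silently truncated value returned.
#'
#' The moment is evaluated by quadrature after the probability
#' substitution \eqn{x = Q(w)}, i.e. \eqn{\mu'_r = \int_0^1 Q(w)^r\,dw},
#' which is equivalent to the classical form
#' \eqn{\int_1^\infty \alpha (\log t)^{-r/\beta} e^{\alpha(1-t)}\,dt}
#' under \eqn{t = e^{x^{-\beta}}} but has a bounded domain.
#'
#' @param r positive moment order (may be fractional).
#' @inheritParams tiwd-distribution
#' @return The moment \eqn{\mu'_r}, a positive number.
#' @seealso [tiwd_mean()], [tiwd_variance()], [tiwd_incomplete_moment()]
#' @examples
#' tiwd_moment(1, alpha = 1, beta = 3)
#' @export
tiwd_moment <- function(r, alpha, beta) {
  check_params(alpha, beta)
  if (length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("'r' must be a positive scalar", call. = FALSE)
  }
  if (r >= beta) {
    stop("the moment of order r = ", r, " is infinite: moments of the ",
         "TIWD exist only for r < beta (here beta = ", beta, ")",
         call. = FALSE)
  }
  tiwd_moment_integral(r, alpha, beta)
}

#' @rdname tiwd_moment
#' @export
tiwd_mean <- function(alpha, beta) tiwd_moment(1, alpha, beta)

#' @rdname tiwd_moment
#' @export
tiwd_variance <- function(alpha, beta) {
  tiwd_moment(2, alpha, beta) - tiwd_mean(alpha, beta)^2
}

#' Incomplete moments of the TIWD
#'
#' The lower incomplete \eqn{r}-th moment
#' \eqn{I_r(x) = \int_0^x s^r f(s)\,ds}, computed in probability space as
#' \eqn{\int_0^{F(x)} Q(w)^r\,dw}.  It is nondecreasing in \eqn{x} and
#' tends to \eqn{\mu'_r} as \eqn{x \to \infty}; like the full moment it
#' requires \eqn{r < \beta}.
#'
#' @param x positive truncation point.
#' @inheritParams tiwd_moment
#' @return The value \eqn{I_r(x) \ge 0}.
#' @export
tiwd_incomplete_moment <- function(r, x, alpha, beta) {
  check_params(alpha, beta)
  if (length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("'r' must be a positive scalar", call. = FALSE)
  }
  if (r >= beta) {
    stop("incomplete moments require r < beta (moment finiteness)",
         call. = FALSE)
  }
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'x' must be a positive scalar", call. = FALSE)
  }
  Fx <- ptiwd(x, alpha, beta)
  if (Fx == 0) return(0)
  tiwd_moment_integral(r, alpha, beta, w_lo = 0, w_hi = Fx)
}

#' Lorenz and Bonferroni curves of the TIWD
#'
#' Inequality curves built from the first incomplete moment:
#' \eqn{L(x) = I_1(x)/\mu} and \eqn{B(x) = L(x)/F(x)}.  Both require a
#' finite mean, i.e. \eqn{\beta > 1}.
#'
#' @param x positive evaluation point.
#' @inheritParams tiwd-distribution
#' @return A list with components \code{L} and \code{B}.
#' @export
tiwd_lorenz <- function(x, alpha, beta) {
  check_params(alpha, beta)
  if (beta <= 1) {
    stop("the Lorenz curve requires a finite mean, i.e. beta > 1",
         call. = FALSE)
  }
  L <- tiwd_incomplete_moment(1, x, alpha, beta) / tiwd_mean(alpha, beta)
  list(L = L, B = L / ptiwd(x, alpha, beta))
}

#' Mean residual life of the TIWD
#'
#' The expected remaining lifetime
#' \eqn{m(x) = E[X - x \mid X > x] = \int_x^\infty S(y)\,dy / S(x)},
#' evaluated as \eqn{\int_{F(x)}^1 (Q(w) - x)\,dw / S(x)} so the
#' heavy-tail integral runs over a bounded probability domain.  The
#' integral diverges unless \eqn{\beta > 1} (the \eqn{r < \beta} moment
#' condition with \eqn{r = 1}).  For large \eqn{x} the Pareto-like tail
#' gives \eqn{m(x) \approx x/(\beta - 1)}.
#'
#' @param x positive time point.
#' @inheritParams tiwd-distribution
#' @return The mean residual life, a positive number.
#' @export
tiwd_mean_residual_life <- function(x, alpha, beta) {
  check_params(alpha, beta)
  if (beta <= 1) {
    stop("mean residual life requires beta > 1 (the mean must exist, ",
         "r < beta with r = 1)", call. = FALSE)
  }
  if (length(x) != 1L || !is.finite(x) || x <= 0) {
    stop("'x' must be a positive scalar", call. = FALSE)
  }
  Fx <- ptiwd(x, alpha, beta)
  Sx <- ptiwd(x, alpha, beta, lower.tail = FALSE)
  # int_x^Inf S(y) dy = int_{F(x)}^1 (Q(w) - x) dw, with the first-moment
  # tail evaluated by the singularity-free substitution
  tail_mean <- tiwd_moment_integral(1, alpha, beta, w_lo = Fx, w_hi = 1)
  (tail_mean - x * Sx) / Sx
}
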