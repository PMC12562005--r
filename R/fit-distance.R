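# --- minimum-distance estimators ------------------------------------------
# All three estimators minimize a discrepancy between the fitted CDF and
# the empirical CDF over (alpha, beta).  Optimization runs on
# (log alpha, log beta) -- positivity without constraints -- with BFGS and
# analytic gradients built from the CDF partials, started from the ML
# estimate plus a fixed pattern of eight log-space perturbations.

#' Partial derivatives of the TIWD CDF in its parameters
#'
#' \eqn{\partial F/\partial\alpha = F(x)(1 - e^{x^{-\beta}})} and
#' \eqn{\partial F/\partial\beta =
#'   \alpha x^{-\beta} e^{x^{-\beta}} F(x) \log x},
#' the building blocks of the estimating equations of the
#' minimum-distance fits.
#'
#' @param x vector of positive quantiles.
#' @inheritParams tiwd-distribution
#' @return A list with vectors \code{theta1} (\eqn{\partial F/\partial\alpha})
#'   and \code{theta2} (\eqn{\partial F/\partial\beta}).
#' @export
tiwd_cdf_partials <- function(x, alpha, beta) {
  check_params(alpha, beta)
  u <- x^(-beta)
  Fx <- exp(-alpha * expm1(u))
  list(theta1 = Fx * (-expm1(u)),
       theta2 = alpha * u * exp(u) * Fx * log(x))
}

# Anderson-Darling objective:
#   A = -n - (1/n) sum (2i-1) [log F(x_(i)) + log S(x_(n+1-i))].
tiwd_obj_ad <- function(alpha, beta, xs) {
  n <- length(xs)
  lF <- -alpha * expm1(xs^(-beta))
  lS <- log(-expm1(lF))
  i <- seq_len(n)
  -n - sum((2 * i - 1) * (lF + rev(lS))) / n
}

# Cramer-von Mises objective: C = 1/(12n) + sum [F(x_(i)) - (2i-1)/(2n)]^2.
tiwd_obj_cvm <- function(alpha, beta, xs) {
  n <- length(xs)
  Fx <- exp(-alpha * expm1(xs^(-beta)))
  i <- seq_len(n)
  1 / (12 * n) + sum((Fx - (2 * i - 1) / (2 * n))^2)
}

# Least-squares objective on plotting positions p_i:
# L = sum [F(x_(i)) - p_i]^2, p_i = i/(n+1) ("standard") or i/(n+i)
# ("shifted").
tiwd_ols_positions <- function(n, plotting_position) {
  i <- seq_len(n)
  switch(plotting_position,
         standard = i / (n + 1),
         shifted  = i / (n + i))
}

tiwd_obj_ols <- function(alpha, beta, xs, p) {
  Fx <- exp(-alpha * expm1(xs^(-beta)))
  sum((Fx - p)^2)
}

# Analytic gradients in (alpha, beta).
tiwd_grad_ad <- function(alpha, beta, xs) {
  n <- length(xs)
  i <- seq_len(n)
  w <- 2 * i - 1
  pt <- tiwd_cdf_partials(xs, alpha, beta)
  Fx <- exp(-alpha * expm1(xs^(-beta)))
  Sx <- -expm1(-alpha * expm1(xs^(-beta)))
  rev_idx <- rev(i)
  c(-sum(w * (pt$theta1 / Fx - pt$theta1[rev_idx] / Sx[rev_idx])) / n,
    -sum(w * (pt$theta2 / Fx - pt$theta2[rev_idx] / Sx[rev_idx])) / n)
}

tiwd_grad_cvm <- function(alpha, beta, xs) {
  n <- length(xs)
  i <- seq_len(n)
  pt <- tiwd_cdf_partials(xs, alpha, beta)
  Fx <- exp(-alpha * expm1(xs^(-beta)))
  d <- Fx - (2 * i - 1) / (2 * n)
  c(2 * sum(d * pt$theta1), 2 * sum(d * pt$theta2))
}

tiwd_grad_ols <- function(alpha, beta, xs, p) {
  pt <- tiwd_cdf_partials(xs, alpha, beta)
  Fx <- exp(-alpha * expm1(xs^(-beta)))
  d <- Fx - p
  c(2 * sum(d * pt$theta1), 2 * sum(d * pt$theta2))
}

# Deterministic multistart pattern around the ML solution (log scale).
tiwd_multistart_offsets <- function() {
  rbind(c(0, 0),
        c(0.5, 0), c(-0.5, 0), c(0, 0.5), c(0, -0.5),
        c(0.5, 0.5), c(0.5, -0.5), c(-0.5, 0.5), c(-0.5, -0.5))
}

tiwd_fit_distance <- function(x, method, plotting_position = "standard") {
  xs <- sort(x)
  p <- if (method == "ols") {
    tiwd_ols_positions(length(xs), plotting_position)
  }
  obj <- switch(method,
    ad  = function(th) tiwd_obj_ad(exp(th[1]), exp(th[2]), xs),
    cvm = function(th) tiwd_obj_cvm(exp(th[1]), exp(th[2]), xs),
    ols = function(th) tiwd_obj_ols(exp(th[1]), exp(th[2]), xs, p)
  )
  grad <- switch(method,
    ad  = function(th) tiwd_grad_ad(exp(th[1]), exp(th[2]), xs) * exp(th),
    cvm = function(th) tiwd_grad_cvm(exp(th[1]), exp(th[2]), xs) * exp(th),
    ols = function(th) tiwd_grad_ols(exp(th[1]), exp(th[2]), xs, p) * exp(th)
  )
  safe_obj <- function(th) {
    v <- tryCatch(suppressWarnings(obj(th)), error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  start0 <- tryCatch(log(tiwd_fit_ml(x)$coefficients),
                     error = function(e) c(0, 0))
  starts <- sweep(tiwd_multistart_offsets(), 2, start0, `+`)
  best <- NULL
  trace <- character(0)
  for (k in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[k, ], safe_obj, gr = function(th) {
              g <- tryCatch(suppressWarnings(grad(th)),
                            error = function(e) c(0, 0))
              ifelse(is.finite(g), g, 0)
            },
            method = "BFGS",
            control = list(maxit = 500L, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(res)) {
      trace <- c(trace, sprintf("start %d: optimizer error", k))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best) || !is.finite(best$value)) {
    stop("minimum-distance optimization failed from every start (",
         paste(trace, collapse = "; "), ")", call. = FALSE)
  }
  alpha <- exp(best$par[1])
  beta <- exp(best$par[2])
  g <- switch(method,
    ad  = tiwd_grad_ad(alpha, beta, xs),
    cvm = tiwd_grad_cvm(alpha, beta, xs),
    ols = tiwd_grad_ols(alpha, beta, xs, p)
  )
  list(
    coefficients = c(alpha = alpha, beta = beta),
    loglik = tiwd_loglik(alpha, beta, x),
    objective = best$value,
    converged = best$convergence == 0,
    iterations = unname(best$counts["function"]),
    gradient_norm = sqrt(sum(g^2))
  )
}
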