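# Per-replicate seed: a deterministic integer hash of the study seed, the
# position of n in the grid, and the replicate index.  Replicate results
# are therefore invariant to the order in which cells are run.
replicate_seed <- function(seed, ni, rep) {
  (abs(seed) + 100003 * ni + 7919 * rep) %% 2147483629L + 1
}

#' Monte Carlo study of TIWD point estimators
#'
#' Repeatedly draws samples from a TIWD with known parameters, fits each
#' sample with the requested estimators, and aggregates the average
#' estimate (AE), mean squared error about the truth (MSE), and
#' coefficient of variation (CV = sd of the estimates / AE) per
#' estimator, sample size, and parameter.
#'
#' \code{"bayes_inf"} and \code{"bayes_noninf"} run MH-within-Gibbs with
#' informative Gamma(1,1) priors (hyperparameters configurable through
#' \code{prior}) and the non-informative \eqn{1/(\alpha\beta)} prior
#' respectively, summarizing each chain by its precautionary-loss
#' estimate.  Replicates whose fit fails are excluded and counted; a
#' warning is attached when more than 5 percent of a cell fails.
#'
#' @param alpha,beta true parameter values generating the data.
#' @param n_grid integer vector of sample sizes (each >= 5).
#' @param reps number of Monte Carlo replicates per sample size.
#' @param methods subset of \code{c("ml", "ad", "cvm", "ols",
#'   "bayes_inf", "bayes_noninf")}.
#' @param seed integer study seed; per-replicate seeds are derived
#'   deterministically from it.
#' @param iterations,burn_in MCMC settings for the Bayes arms.
#' @param prior informative prior for \code{"bayes_inf"}.
#' @return A data frame with columns \code{estimator}, \code{n},
#'   \code{parameter}, \code{ae}, \code{mse}, \code{cv}, \code{failures};
#'   the failure counts are also available as
#'   \code{attr(result, "failures")}.
#' @examples
#' tiwd_sim_study(0.5, 1, n_grid = 20, reps = 5, methods = "ml", seed = 1)
#' @export
tiwd_sim_study <- function(alpha, beta, n_grid = c(20, 30, 50, 80, 100),
                           reps = 1000L,
                           methods = c("ml", "ad", "cvm", "ols"),
                           seed = 1L, iterations = 5000L, burn_in = 500L,
                           prior = tiwd_prior("informative")) {
  check_params(alpha, beta)
  methods <- match.arg(methods,
                       c("ml", "ad", "cvm", "ols", "bayes_inf",
                         "bayes_noninf"), several.ok = TRUE)
  if (reps < 1L || any(n_grid < 5L)) {
    stop("'reps' must be >= 1 and every n >= 5", call. = FALSE)
  }
  one_fit <- function(x, method) {
    switch(method,
      ml = tiwd_fit_ml(x)$coefficients,
      ad = ,
      cvm = ,
      ols = tiwd_fit_distance(x, method)$coefficients,
      bayes_inf = tiwd_fit_bayes(x, prior = prior,
                                 iterations = iterations,
                                 burn_in = burn_in)$coefficients,
      bayes_noninf = tiwd_fit_bayes(x, prior = tiwd_prior("noninformative"),
                                    iterations = iterations,
                                    burn_in = burn_in)$coefficients)
  }
  truth <- c(alpha = alpha, beta = beta)
  out <- list()
  fail_tab <- list()
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    est <- array(NA_real_, dim = c(reps, 2L, length(methods)),
                 dimnames = list(NULL, c("alpha", "beta"), methods))
    for (r in seq_len(reps)) {
      set.seed(replicate_seed(seed, ni, r))
      x <- rtiwd(n, alpha, beta)
      for (m in methods) {
        est[r, , m] <- tryCatch(suppressWarnings(one_fit(x, m)),
                                error = function(e) c(NA_real_, NA_real_))
      }
    }
    for (m in methods) {
      fails <- sum(!stats::complete.cases(est[, , m, drop = TRUE]))
      fail_tab[[paste(m, n)]] <- fails
      if (fails > 0.05 * reps) {
        warning(sprintf("estimator '%s' at n = %d: %d of %d replicates failed",
                        m, n, fails, reps), call. = FALSE)
      }
      for (p in c("alpha", "beta")) {
        e <- est[, p, m]
        e <- e[is.finite(e)]
        out[[length(out) + 1L]] <- data.frame(
          estimator = m, n = n, parameter = p,
          ae = mean(e), mse = mean((e - truth[[p]])^2),
          cv = sd(e) / mean(e), failures = fails
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "failures") <- unlist(fail_tab)
  res
}

#' Coverage study for the asymptotic confidence intervals
#'
#' Repeatedly draws TIWD samples, ML-fits each, forms Fisher-information
#' intervals at each requested level, and reports the empirical coverage
#' probability (CP) and average width (AW) per sample size, parameter,
#' and level.  Intervals are used untruncated (lower bounds may be
#' negative).
#'
#' @inheritParams tiwd_sim_study
#' @param theta vector of type-I error levels; intervals have nominal
#'   coverage \eqn{100(1-\theta)\%}.
#' @return A data frame with columns \code{n}, \code{parameter},
#'   \code{theta}, \code{cp}, \code{aw}.
#' @examples
#' tiwd_coverage_study(0.5, 1, n_grid = 30, reps = 10, seed = 1)
#' @export
tiwd_coverage_study <- function(alpha, beta,
                                n_grid = c(20, 30, 50, 80, 100),
                                reps = 1000L, theta = c(0.05, 0.1),
                                seed = 1L) {
  check_params(alpha, beta)
  truth <- c(alpha = alpha, beta = beta)
  z <- qnorm(1 - theta / 2)
  out <- list()
  for (ni in seq_along(n_grid)) {
    n <- n_grid[ni]
    cover <- array(0, dim = c(2L, length(theta)),
                   dimnames = list(c("alpha", "beta"), theta))
    width <- cover
    used <- 0L
    for (r in seq_len(reps)) {
      set.seed(replicate_seed(seed, ni, r))
      x <- rtiwd(n, alpha, beta)
      res <- tryCatch({
        fit <- tiwd_fit_ml(x)
        se <- tiwd_fisher_info(fit$coefficients[1], fit$coefficients[2],
                               x)$se
        list(est = fit$coefficients, se = se)
      }, error = function(e) NULL)
      if (is.null(res)) next
      used <- used + 1L
      for (ti in seq_along(theta)) {
        lo <- res$est - z[ti] * res$se
        hi <- res$est + z[ti] * res$se
        cover[, ti] <- cover[, ti] + (lo <= truth & truth <= hi)
        width[, ti] <- width[, ti] + (hi - lo)
      }
    }
    for (p in c("alpha", "beta")) {
      for (ti in seq_along(theta)) {
        out[[length(out) + 1L]] <- data.frame(
          n = n, parameter = p, theta = theta[ti],
          cp = cover[p, ti] / used, aw = width[p, ti] / used
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
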