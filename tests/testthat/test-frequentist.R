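test_that("profile alpha solves its score equation in closed form", {
  # single observation x = 1, beta = 1: alpha = 1/(e - 1)
  expect_equal(tiwd:::tiwd_profile_alpha(1, 1), 1 / (exp(1) - 1),
               tolerance = 1e-12)
  # the alpha-score vanishes at the profile solution for any (beta, sample)
  for (b in c(0.5, 1.19, 3)) {
    a <- tiwd:::tiwd_profile_alpha(b, metal)
    score_a <- length(metal) / a - sum(expm1(metal^(-b)))
    expect_lt(abs(score_a), 1e-10 * length(metal))
  }
  # at the published Data I beta, profile alpha lands near the published alpha
  expect_equal(tiwd:::tiwd_profile_alpha(1.1908, metal), 1074.96,
               tolerance = 1e-3)
})

test_that("the beta score matches finite differences of the log-likelihood", {
  x <- synth_sample(50, 1, 1, seed = 2)
  h <- 1e-6
  fd <- (tiwd:::tiwd_loglik(1, 1 + h, x) - tiwd:::tiwd_loglik(1, 1 - h, x)) /
    (2 * h)
  expect_equal(tiwd:::tiwd_score_beta(1, x, 1), fd, tolerance = 1e-6)
})

test_that("the alpha score is strictly decreasing (uniqueness)", {
  ag <- seq(0.1, 10, length.out = 50)
  for (fixture in list(metal, cancer, synth_sample(60, 1, 1, seed = 4))) {
    p <- vapply(ag, function(a) length(fixture) / a -
                  sum(expm1(fixture^(-1))), numeric(1))
    expect_true(all(diff(p) < 0))
  }
})

test_that("the profiled beta score changes sign exactly once", {
  bg <- exp(seq(log(1e-3), log(64), length.out = 120))
  for (k in seq_len(nrow(param_grid))) {
    x <- synth_sample(200, param_grid$alpha[k], param_grid$beta[k],
                      seed = 100 + k)
    s <- vapply(bg, function(b) tiwd:::tiwd_profile_score(b, x), numeric(1))
    expect_equal(sum(diff(sign(s)) != 0), 1)
  }
})

test_that("ML fitting reproduces the published fits on both data sets", {
  f1 <- tiwd_fit(metal)
  expect_equal(unname(coef(f1)), c(1074.9606, 1.1908), tolerance = 1e-3)
  expect_true(f1$converged)
  expect_lt(abs(tiwd:::tiwd_profile_score(coef(f1)[["beta"]], metal)), 1e-6)
  f2 <- tiwd_fit(cancer)
  expect_equal(unname(coef(f2)), c(77.6807, 1.0071), tolerance = 1e-3)
  # reproducibility: identical input gives identical output
  expect_identical(coef(tiwd_fit(metal)), coef(f1))
})

test_that("ML estimates are consistent at large n", {
  est <- vapply(1:100, function(r) {
    coef(tiwd_fit(synth_sample(5000, 0.8, 1.5, seed = 1000 + r)))
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.8), 0.05)
  expect_lt(abs(mean(est[2, ]) - 1.5), 0.05)
})

test_that("the analytic Fisher information matches a numerical Hessian", {
  x <- synth_sample(100, 1, 1, seed = 3)
  fi <- tiwd_fisher_info(1, 1, x)
  expect_equal(fi$info[1, 1], length(x) / 1^2, tolerance = 1e-12)
  expect_equal(fi$info[1, 2], fi$info[2, 1], tolerance = 1e-12)
  h <- 1e-4
  num_h <- matrix(NA_real_, 2, 2)
  ll <- function(p) tiwd:::tiwd_loglik(p[1], p[2], x)
  for (i in 1:2) {
    for (j in 1:2) {
      e_i <- e_j <- c(0, 0); e_i[i] <- h; e_j[j] <- h
      num_h[i, j] <- (ll(c(1, 1) + e_i + e_j) - ll(c(1, 1) + e_i - e_j) -
                      ll(c(1, 1) - e_i + e_j) + ll(c(1, 1) - e_i - e_j)) /
        (4 * h^2)
    }
  }
  expect_equal(unname(fi$info), -num_h, tolerance = 1e-5)
  expect_equal(fi$cov %*% fi$info, diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("asymptotic confidence intervals follow the normal recipe", {
  f <- tiwd_fit(metal)
  ci <- confint(f, level = 0.95)
  z <- qnorm(0.975)
  expect_equal(z, 1.959964, tolerance = 1e-6)
  se <- sqrt(diag(vcov(f)))
  expect_equal(unname(ci[, 2] - ci[, 1]), unname(2 * z * se),
               tolerance = 1e-12)
  # untruncated: the alpha lower bound on this data set is negative
  expect_lt(ci["alpha", 1], 0)
})

test_that("CDF partials match closed forms and finite differences", {
  pt <- tiwd_cdf_partials(1, 1, 1)
  expect_equal(pt$theta1, exp(1 - exp(1)) * (1 - exp(1)), tolerance = 1e-12)
  expect_equal(pt$theta2, 0, tolerance = 1e-12)
  a <- 1.3; b <- 0.7; x <- 2; h <- 1e-6
  pt <- tiwd_cdf_partials(x, a, b)
  expect_equal(pt$theta1,
               (ptiwd(x, a + h, b) - ptiwd(x, a - h, b)) / (2 * h),
               tolerance = 1e-7)
  expect_equal(pt$theta2,
               (ptiwd(x, a, b + h) - ptiwd(x, a, b - h)) / (2 * h),
               tolerance = 1e-7)
})

test_that("minimum-distance fits are stationary and beat a grid search", {
  x <- synth_sample(50, 1, 1, seed = 6)
  grid <- exp(seq(log(0.2), log(5), length.out = 101))
  xs <- sort(x)
  p_std <- tiwd:::tiwd_ols_positions(length(xs), "standard")
  objectives <- list(
    ad = function(a, b) tiwd:::tiwd_obj_ad(a, b, xs),
    cvm = function(a, b) tiwd:::tiwd_obj_cvm(a, b, xs),
    ols = function(a, b) tiwd:::tiwd_obj_ols(a, b, xs, p_std)
  )
  for (m in c("ad", "cvm", "ols")) {
    fit <- tiwd_fit(x, method = m)
    expect_true(fit$converged)
    expect_lt(fit$gradient_norm, 1e-5)
    grid_min <- min(outer(grid, grid,
                          Vectorize(function(a, b) objectives[[m]](a, b))))
    expect_lte(fit$objective, grid_min + 1e-9)
    # determinism
    expect_identical(coef(tiwd_fit(x, method = m)), coef(fit))
  }
  # CVM objective respects its lower bound 1/(12n)
  f_cvm <- tiwd_fit(x, method = "cvm")
  expect_gte(f_cvm$objective, 1 / (12 * length(x)))
})

test_that("distance estimators recover the truth on average", {
  est <- vapply(1:100, function(r) {
    x <- synth_sample(100, 0.8, 1, seed = 5000 + r)
    c(coef(tiwd_fit(x, method = "ad")), coef(tiwd_fit(x, method = "cvm")))
  }, numeric(4))
  expect_lt(abs(mean(est[1, ]) - 0.8), 0.06)
  expect_lt(abs(mean(est[3, ]) - 0.8), 0.06)
})

test_that("the OLS plotting-position flag selects the stated conventions", {
  expect_equal(tiwd:::tiwd_ols_positions(4, "standard"), (1:4) / 5)
  expect_equal(tiwd:::tiwd_ols_positions(4, "shifted"), (1:4) / (4 + 1:4))
  x <- synth_sample(40, 1, 1, seed = 8)
  f1 <- tiwd_fit(x, method = "ols", plotting_position = "standard")
  f2 <- tiwd_fit(x, method = "ols", plotting_position = "shifted")
  expect_false(identical(coef(f1), coef(f2)))
})
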