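test_that("density, CDF and quantile agree with closed forms", {
  expect_equal(dtiwd(1, 1, 1), exp(2 - exp(1)), tolerance = 1e-12)
  expect_equal(ptiwd(1, 1, 1), exp(1 - exp(1)), tolerance = 1e-12)
  expect_equal(ptiwd(1, 1, 7), exp(1 - exp(1)), tolerance = 1e-12)
  expect_equal(ptiwd(1, 2, 1), exp(2 * (1 - exp(1))), tolerance = 1e-12)
  expect_equal(qtiwd(0.5, 1, 1), log(1 - log(0.5))^(-1), tolerance = 1e-12)
  expect_equal(qtiwd(exp(1 - exp(1)), 1, 1), 1, tolerance = 1e-10)
  expect_equal(qtiwd(exp(2 * (1 - exp(1))), 2, 3), 1, tolerance = 1e-10)
  expect_equal(dtiwd(2, 1, 1, log = TRUE), log(dtiwd(2, 1, 1)),
               tolerance = 1e-12)
})

test_that("domain violations are rejected", {
  expect_error(dtiwd(-1, 1, 1), "positive")
  expect_error(ptiwd(0, 1, 1), "positive")
  expect_error(qtiwd(1.2, 1, 1), "inside")
  expect_error(qtiwd(0, 1, 1), "inside")
  expect_error(dtiwd(1, -1, 1), "alpha")
  expect_error(dtiwd(1, 1, 0), "beta|positive")
})

test_that("density is the derivative of the CDF (central differences)", {
  cases <- rbind(c(1, 1), c(2, 0.5), c(1075, 1.19))
  for (k in seq_len(nrow(cases))) {
    a <- cases[k, 1]; b <- cases[k, 2]
    for (x in c(0.5, 1, 2, 10)) {
      h <- x * 1e-6
      fd <- (ptiwd(x + h, a, b) - ptiwd(x - h, a, b)) / (2 * h)
      expect_equal(dtiwd(x, a, b), fd, tolerance = 1e-6)
    }
  }
})

test_that("the density integrates to one over the probability domain", {
  # substitution x = Q(w) turns the normalization integral into
  # E[1] = int_0^1 dw, immune to tail truncation even for beta < 1
  for (a in c(0.5, 1, 2, 1075)) {
    for (b in c(0.5, 1, 1.19, 3)) {
      expect_equal(tiwd:::tiwd_expectation(function(x) rep(1, length(x)),
                                           a, b),
                   1, tolerance = 1e-8)
    }
  }
  # and directly in x for one well-behaved case
  expect_equal(integrate(dtiwd, 0, Inf, alpha = 1, beta = 2,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
})

test_that("quantile inverts the CDF to high precision", {
  w <- c(0.01, 0.25, 0.5, 0.75, 0.99)
  for (k in seq_len(nrow(param_grid))) {
    a <- param_grid$alpha[k]; b <- param_grid$beta[k]
    expect_lt(max(abs(ptiwd(qtiwd(w, a, b), a, b) - w)), 1e-10)
    q <- qtiwd(c(0.25, 0.5, 0.75), a, b)
    expect_true(all(diff(q) > 0))
  }
})

test_that("reliability identities hold to machine precision", {
  x <- exp(seq(log(0.05), log(50), length.out = 50))
  r <- tiwd_reliability(x, 1, 1)
  Fx <- ptiwd(x, 1, 1)
  expect_equal(r$sf + Fx, rep(1, 50), tolerance = 1e-12)
  expect_equal(r$hazard * r$sf, dtiwd(x, 1, 1), tolerance = 1e-12)
  expect_equal(r$cum_hazard, -log(r$sf), tolerance = 1e-12)
  expect_equal(r$reversed_hazard * Fx, dtiwd(x, 1, 1), tolerance = 1e-12)
  # closed forms at x = 1
  r1 <- tiwd_reliability(1, 1, 1)
  expect_equal(r1$sf, 1 - exp(1 - exp(1)), tolerance = 1e-12)
  expect_equal(r1$reversed_hazard, exp(1), tolerance = 1e-12)
})

test_that("hazard stays finite where the CDF underflows", {
  # at x = 1e-6 with beta = 5 the CDF is far below double precision
  r <- tiwd_reliability(1e-6, 1, 5)
  expect_true(is.finite(r$hazard))
  expect_identical(r$sf, 1)
  ld <- dtiwd(1e-6, 1, 5, log = TRUE)
  expect_true(is.finite(ld) || ld == -Inf)
  expect_false(is.nan(ld))
})

test_that("order-statistic density reduces correctly and normalizes", {
  x <- c(0.3, 1, 2.5)
  expect_equal(tiwd_order_statistic(x, 1, 1, 1, 1), dtiwd(x, 1, 1),
               tolerance = 1e-12)
  n <- 4
  expect_equal(tiwd_order_statistic(x, n, n, 1, 1),
               n * dtiwd(x, 1, 1) * ptiwd(x, 1, 1)^(n - 1),
               tolerance = 1e-12)
  expect_equal(tiwd_order_statistic(x, 1, n, 1, 1),
               n * dtiwd(x, 1, 1) *
                 ptiwd(x, 1, 1, lower.tail = FALSE)^(n - 1),
               tolerance = 1e-12)
  total <- integrate(function(s) tiwd_order_statistic(s, 3, 5, 1, 2),
                     0, Inf, rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  expect_error(tiwd_order_statistic(1, 6, 5, 1, 1), "j")
})

test_that("random generation is seeded, deterministic, and correct in law", {
  set.seed(7); s1 <- rtiwd(100, 1, 1)
  set.seed(7); s2 <- rtiwd(100, 1, 1)
  expect_identical(s1, s2)
  # inverse transform of w = 0.5 is the median
  set.seed(11)
  u <- runif(1)
  set.seed(11)
  expect_identical(rtiwd(1, 1, 1), qtiwd(u, 1, 1))
  # distributional self-test across 20 consecutive seeds
  pvals <- vapply(1:20, function(s) {
    set.seed(s)
    suppressWarnings(
      ks.test(rtiwd(1e5, 1, 1), function(q) ptiwd(q, 1, 1))$p.value)
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 19)
})

test_that("shape measures are quantile-consistent and bounded", {
  for (k in seq_len(nrow(param_grid))) {
    a <- param_grid$alpha[k]; b <- param_grid$beta[k]
    sm <- tiwd_shape_measures(a, b)
    expect_gt(sm$bowley_skewness, -1)
    expect_lt(sm$bowley_skewness, 1)
    Q <- function(w) qtiwd(w, a, b)
    expect_equal(sm$bowley_skewness,
                 (Q(0.75) + Q(0.25) - 2 * Q(0.5)) / (Q(0.75) - Q(0.25)),
                 tolerance = 1e-12)
    expect_equal(sm$moors_kurtosis,
                 (Q(7 / 8) - Q(5 / 8) + Q(3 / 8) - Q(1 / 8)) /
                   (Q(6 / 8) - Q(2 / 8)),
                 tolerance = 1e-12)
  }
  # skewness moves toward symmetry as beta grows at alpha = 1
  s <- vapply(c(0.5, 1, 2, 5),
              function(b) tiwd_shape_measures(1, b)$bowley_skewness,
              numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("tail diagnostics witness the algebraic (heavy) tail", {
  # e^{tx} S(x) diverges for every t > 0; on the log scale (which cannot
  # overflow) it is strictly increasing beyond moderate x
  xg <- 10^seq(1, 4, length.out = 40)
  td <- tiwd_tail_diagnostics(0.1, xg, 1, 1)
  beyond <- td$log_etx_sf[td$x > 100]
  expect_true(all(diff(beyond) > 0))
  expect_true(all(is.finite(td$log_etx_sf)))
  # S(x) / (alpha x^-beta) -> 1; the remainder is O(x^-beta), so the
  # evaluation point is taken far enough out for each beta
  td1 <- tiwd_tail_diagnostics(0.1, c(1e5, 1e6), 1, 1)
  expect_equal(td1$pareto_ratio[2], 1, tolerance = 1e-4)
  td2 <- tiwd_tail_diagnostics(0.1, c(1e8, 1e9), 2, 0.5)
  expect_equal(td2$pareto_ratio[2], 1, tolerance = 1e-4)
  # slope of log S against log x on the far tail is -beta
  xg <- exp(seq(log(1e4), log(1e6), length.out = 50))
  lS <- ptiwd(xg, 1, 1, lower.tail = FALSE, log.p = TRUE)
  slope <- coef(lm(lS ~ log(xg)))[[2]]
  expect_equal(slope, -1, tolerance = 1e-3)
})
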