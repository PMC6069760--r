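# quadrature oracle: integrate the binomial pmf against the Beta density
betabin_quadrature <- function(x, nex, a, b) {
  stats::integrate(function(p) dbinom(x, nex, p) * dbeta(p, a, b),
                   0, 1, rel.tol = 1e-10)$value
}

test_that("beta-binomial pmf matches the mixture quadrature oracle", {
  expect_equal(betabin_pmf(0, 0, 3, 7), 1)
  # uniform mixing over two trials gives a discrete uniform
  expect_equal(betabin_pmf(0:2, 2, 1, 1), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(betabin_pmf(0, 5, 2, 3), betabin_quadrature(0, 5, 2, 3),
               tolerance = 1e-8)
  expect_equal(betabin_pmf(0, 5, 2, 3), beta(2, 8) / beta(2, 3), tolerance = 1e-12)
  for (case in list(c(3, 12, 0.5, 2), c(7, 9, 4, 1.5), c(0, 20, 10, 10))) {
    expect_equal(betabin_pmf(case[1], case[2], case[3], case[4]),
                 betabin_quadrature(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-8)
  }
  expect_error(betabin_pmf(3, 2, 1, 1), "lie in")
  expect_error(betabin_pmf(-1, 2, 1, 1), "lie in")
  expect_error(betabin_pmf(0, 2, 0, 1), "positive")
})

test_that("pmf normalizes to one over its support", {
  for (nex in c(1, 5, 17, 50)) {
    for (ab in list(c(0.5, 0.5), c(1, 1), c(2, 10), c(10, 2))) {
      expect_equal(sum(betabin_pmf(0:nex, nex, ab[1], ab[2])), 1,
                   tolerance = 1e-10)
    }
  }
})

test_that("false-negative probability has its closed form and recurrence", {
  expect_equal(prob_all_negative(0, 2, 5), 1)
  # uniform mixing: 1/(nex + 1)
  expect_equal(prob_all_negative(9, 1, 1), 0.1, tolerance = 1e-12)
  expect_equal(prob_all_negative(4, 2, 3), betabin_pmf(0, 4, 2, 3), tolerance = 1e-12)
  # consecutive ratio from the Beta-function recurrence
  a <- 1.7; b <- 6.2
  for (nex in c(0, 3, 11, 30)) {
    expect_equal(prob_all_negative(nex + 1, a, b) / prob_all_negative(nex, a, b),
                 (nex + b) / (nex + b + a), tolerance = 1e-10)
  }
  # strict decrease and vanishing tail
  v <- prob_all_negative(1:100, 2, 8)
  expect_true(all(diff(v) < 0))
  expect_lt(prob_all_negative(1e4, 1, 1), 0.01)
})

test_that("maximum-likelihood fit recovers known parameters", {
  fx <- generate_node_status_fixture(5000, 2, 8, seed = 21)
  fit <- fit_betabin(fx$nex, fx$x)
  expect_lt(abs(fit$alpha - 2) / 2, 0.15)
  expect_lt(abs(fit$beta - 8) / 8, 0.15)
  expect_true(fit$alpha_ci[1] <= fit$alpha && fit$alpha <= fit$alpha_ci[2])
  expect_true(fit$beta_ci[1] <= fit$beta && fit$beta <= fit$beta_ci[2])
  # local optimum: no random perturbation improves the log-likelihood
  ll <- function(a, b) sum(betabin_pmf(fx$x, fx$nex, a, b, log = TRUE))
  set.seed(33)
  pert <- replicate(100, ll(fit$alpha * exp(rnorm(1, 0, 0.2)),
                            fit$beta * exp(rnorm(1, 0, 0.2))))
  expect_true(all(pert <= fit$loglik + 1e-6))
})

test_that("fit consistency improves with sample size", {
  err <- vapply(c(500, 5000), function(n) {
    fx <- generate_node_status_fixture(n, 2, 8, seed = 77)
    fit <- fit_betabin(fx$nex, fx$x)
    abs(fit$alpha - 2) / 2 + abs(fit$beta - 8) / 8
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("near-binomial data pushes the fit toward the binomial limit", {
  set.seed(91)
  nex <- 1L + rpois(2000, 12)
  x <- rbinom(2000, nex, 0.3)  # homogeneous p: alpha + beta -> infinity
  fit <- fit_betabin(nex, x)
  expect_gt(fit$alpha + fit$beta, 50)
  expect_equal(fit$alpha / (fit$alpha + fit$beta), 0.3, tolerance = 0.05)
})

test_that("boundary and degenerate inputs are rejected", {
  expect_error(fit_betabin(c(10, 12), c(0, 0)), "boundary")
  expect_error(fit_betabin(c(10, 12), c(10, 12)), "boundary")
  expect_error(fit_betabin(5, 2), "at least 2")
})

test_that("misclassification curve decreases and its band brackets the point", {
  fx <- generate_node_status_fixture(3000, 2, 8, seed = 3)
  fit <- fit_betabin(fx$nex, fx$x)
  cur <- misclassification_curve(fit, 1:40)
  expect_true(all(diff(cur$point) < 0))
  expect_true(all(cur$low <= cur$point + 1e-12 & cur$point <= cur$high + 1e-12))
  # corner-enumeration oracle at one grid value
  corners <- c(prob_all_negative(10, fit$alpha_ci[1], fit$beta_ci[1]),
               prob_all_negative(10, fit$alpha_ci[1], fit$beta_ci[2]),
               prob_all_negative(10, fit$alpha_ci[2], fit$beta_ci[1]),
               prob_all_negative(10, fit$alpha_ci[2], fit$beta_ci[2]))
  expect_equal(cur$low[cur$nex == 10], min(corners))
  expect_equal(cur$high[cur$nex == 10], max(corners))
  # degenerate zero-width intervals collapse the band onto the point
  fit0 <- fit
  fit0$alpha_ci <- rep(fit$alpha, 2); fit0$beta_ci <- rep(fit$beta, 2)
  cur0 <- misclassification_curve(fit0, 1:10)
  expect_equal(cur0$low, cur0$point)
  expect_equal(cur0$high, cur0$point)
  expect_error(misclassification_curve(fit, integer(0)), "nonempty")
})
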