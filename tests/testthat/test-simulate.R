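test_that("covariate generation matches its specified distributions", {
  cov <- generate_covariates(10000, seed = 11)
  freq <- tabulate(cov$stage, 3) / 10000
  expect_true(all(abs(freq - c(.22, .33, .45)) < 0.02))
  expect_equal(mean(cov$sqrt_psa), 2, tolerance = 0.05)
  expect_equal(sd(cov$sqrt_psa), 2, tolerance = 0.05)
  expect_equal(mean(cov$age), 60, tolerance = 0.1)
  expect_equal(sd(cov$age), 3, tolerance = 0.1)
  # degenerate size and determinism
  expect_equal(nrow(generate_covariates(1, seed = 3)), 1)
  expect_identical(generate_covariates(50, seed = 5), generate_covariates(50, seed = 5))
  expect_error(generate_covariates(0), "n must be")
})

test_that("treatment assignment follows the shifted Poisson mechanism", {
  cov <- generate_covariates(20000, seed = 2)
  # degenerate: lambda = exp(-inf)... use coefficients giving lambda ~ 0
  spec0 <- generation_spec(10, pm_coefficients = c(intercept = -30, sqrt_psa = 0,
                                                   age = 0, stage2 = 0, stage3 = 0),
                           seed = 1)
  trt0 <- assign_treatment(cov[1:10, ], spec0, seed = 1)
  expect_true(all(trt0$nodes_removed == 1))
  expect_true(all(trt0$group == 1))
  # constant lambda = 15: mean nodes is 16
  spec15 <- generation_spec(20000, pm_coefficients = c(intercept = log(15), sqrt_psa = 0,
                                                       age = 0, stage2 = 0, stage3 = 0))
  trt15 <- assign_treatment(cov, spec15, seed = 4)
  expect_equal(mean(trt15$nodes_removed), 16, tolerance = 0.1 / 16)
  # covariate-dependent lambda increasing in stage -> monotone group means
  spec <- generation_spec(20000, pm = "pm2")
  trt <- assign_treatment(cov, spec, seed = 9)
  m <- tapply(trt$nodes_removed, cov$stage, mean)
  expect_true(m[1] < m[2] && m[2] < m[3])
})

test_that("group banding partitions every count", {
  expect_identical(node_group(c(1, 10, 11, 20, 21, 100)), c(1L, 1L, 2L, 2L, 3L, 3L))
  nr <- 1:200
  g <- node_group(nr)
  expect_true(all(g %in% 1:3))
  expect_error(node_group(0))
})

test_that("survival generation matches the competing-exponentials closed form", {
  cov <- generate_covariates(20000, seed = 6)
  cov$group <- rep(1L, nrow(cov))
  # constant hazard 1/1000 vs censoring mean 500: P(event) = 1/3
  smc <- c(intercept = log(1 / 1000), sqrt_psa = 0, age = 0, stage2 = 0,
           stage3 = 0, group2 = 0, group3 = 0)
  spec <- generation_spec(20000, sm_coefficients = smc, censor_mean = 500)
  sv <- generate_survival(cov, spec, seed = 8)
  p <- 1 / 3
  expect_lt(abs(mean(sv$event) - p), 3 * sqrt(p * (1 - p) / 20000) + 0.001)
  # no censoring in the censor_mean -> infinity limit
  spec_inf <- generation_spec(500, sm_coefficients = smc, censor_mean = 1e12)
  sv_inf <- generate_survival(cov[1:500, ], spec_inf, seed = 8)
  expect_true(all(sv_inf$event == 1))
  # determinism
  expect_identical(generate_survival(cov, spec, seed = 3),
                   generate_survival(cov, spec, seed = 3))
})

test_that("generated cohorts satisfy their invariants and are reproducible", {
  spec <- generation_spec(n = 1000, seed = 123)
  co <- generate_cohort(spec)
  expect_s3_class(co, "cohort")
  expect_equal(nrow(co), 1000)
  expect_true(all(tabulate(co$group, 3) > 0))
  expect_true(all(co$time >= 0))
  expect_identical(co$group, node_group(co$nodes_removed))
  expect_identical(as.data.frame(generate_cohort(spec)), as.data.frame(co))
})

test_that("node-status fixture follows the beta-binomial mechanism", {
  # uniform mixing with a single trial: P(X = 0) = 1/2
  fx <- generate_node_status_fixture(10000, 1, 1, nex_sampler = function(n) rep(1L, n),
                                     seed = 5)
  expect_lt(abs(mean(fx$x == 0) - 0.5), 0.02)
  # p -> 1 limit
  fx1 <- generate_node_status_fixture(200, 1e6, 1e-3, seed = 5)
  expect_true(all(fx1$x == fx1$nex))
  fx2 <- generate_node_status_fixture(5000, 2, 8, seed = 7)
  expect_true(all(fx2$x >= 0 & fx2$x <= fx2$nex))
  expect_error(generate_node_status_fixture(100, -1, 2))
})

test_that("theoretical survival averages the exponential curve over covariates", {
  cov <- generate_covariates(50, seed = 1)
  spec <- generation_spec(50, sm = "sm3")
  expect_equal(theoretical_survival(cov, spec, 1, 0), 1)
  # covariate-free rate: exact closed form
  smc <- c(intercept = log(0.002), sqrt_psa = 0, age = 0, stage2 = 0,
           stage3 = 0, group2 = 0, group3 = 0)
  spec_c <- generation_spec(50, sm_coefficients = smc)
  expect_equal(theoretical_survival(cov, spec_c, 2, 700), exp(-0.002 * 700))
  # two-value population: direct enumeration oracle
  cov2 <- data.frame(sqrt_psa = c(1, 3), age = c(60, 60), stage = c(1, 1),
                     stage2 = 0, stage3 = 0)
  spec2 <- generation_spec(2, sm = "sm2")
  r <- exp(-7.70 + 0.15 * c(1, 3))
  expect_equal(theoretical_survival(cov2, spec2, 1, 400),
               mean(exp(-r * 400)))
  # monotone in t and within [0, 1]
  ts <- seq(0, 3000, by = 250)
  s <- theoretical_survival(cov, spec, 3, ts)
  expect_true(all(diff(s) <= 0) && all(s >= 0 & s <= 1))
  expect_error(theoretical_survival(cov, spec, 1, -5))
})

test_that("clinical fixture has the documented gradients and event rates", {
  co <- simulate_clinical_cohort(3046, seed = 31)
  expect_true(abs(mean(co$event) - 0.12) < 0.04)
  expect_true(all(tabulate(co$group, 3) > 0))
  expect_true(all(co$nodes_positive <= co$nodes_removed))
  co_os <- simulate_clinical_cohort(3046, outcome = "OS", seed = 31)
  expect_true(mean(co_os$event) < mean(co$event))
})

test_that("cohort CSV round-trips through write/read", {
  co <- simulate_clinical_cohort(200, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(back$nodes_removed, co$nodes_removed)
  expect_equal(back$time, co$time, tolerance = 1e-12)
  expect_equal(back$group, co$group)
  expect_equal(back$psa, co$psa, tolerance = 1e-12)
})
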