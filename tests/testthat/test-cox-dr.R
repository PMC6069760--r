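test_that("zero-covariate fit reduces to the weighted Nelson-Aalen estimator", {
  co <- as.data.frame(small_cohort(n = 200, seed = 73))
  set.seed(73)
  w <- runif(200, 0.5, 3)
  fit <- weighted_cox_fit(co, character(0), weights = w)
  # oracle: cumulative weighted d/n over event times
  ut <- sort(unique(co$time[co$event == 1]))
  haz <- vapply(ut, function(tt) {
    sum(w[co$time == tt & co$event == 1]) / sum(w[co$time >= tt])
  }, numeric(1))
  expect_equal(fit$basehaz$time, ut)
  expect_equal(fit$basehaz$cumhaz, cumsum(haz), tolerance = 1e-10)
})

test_that("partial-likelihood fit recovers a known log-hazard ratio", {
  set.seed(79)
  n <- 5000
  z <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.001 * exp(0.7 * z))
  cen <- rexp(n, 1 / 800)
  d <- data.frame(time = pmin(t, cen), event = as.integer(t <= cen), z = z)
  fit <- weighted_cox_fit(d, "z")
  expect_equal(unname(fit$coefficients["z"]), 0.7, tolerance = 0.1)
  # and the baseline cumulative hazard tracks 0.001 * t
  s <- predict_survival(fit, data.frame(z = 0), 1000)
  expect_equal(s, exp(-1), tolerance = 0.05)
})

test_that("integer weights equal replication for the Cox fit (Breslow ties)", {
  co <- as.data.frame(small_cohort(n = 150, seed = 83))
  set.seed(83)
  w <- sample(1:3, 150, replace = TRUE)
  covs <- c("sqrt_psa", "stage2", "stage3")
  fit_w <- weighted_cox_fit(co, covs, weights = w)
  fit_r <- weighted_cox_fit(replicate_rows(co, w), covs)
  expect_equal(fit_w$coefficients, fit_r$coefficients, tolerance = 1e-8)
  expect_equal(fit_w$basehaz$cumhaz, fit_r$basehaz$cumhaz, tolerance = 1e-8)
})

test_that("survival prediction follows the proportional-hazards identity", {
  co <- as.data.frame(small_cohort(n = 400, seed = 89))
  fit <- weighted_cox_fit(co, c("sqrt_psa", "stage2", "stage3"))
  nd <- data.frame(sqrt_psa = c(0, 2), stage2 = 0, stage3 = 0)
  expect_equal(predict_survival(fit, nd, 0), c(1, 1))
  # covariate origin reproduces the baseline
  s0 <- predict_survival(fit, nd[1, ], 600)
  h0 <- -log(s0)
  # doubling the cumulative hazard squares the survival
  expect_equal(exp(-2 * h0), s0^2)
  # and the explicit form S = exp(-H0 * exp(lp)) holds for a shifted covariate
  s2 <- predict_survival(fit, nd[2, ], 600)
  expect_equal(s2, s0^exp(2 * fit$coefficients[["sqrt_psa"]]), tolerance = 1e-10)
  expect_error(predict_survival(fit, nd, -1))
})

test_that("dr_group_survival averages counterfactual predictions over everyone", {
  co <- small_cohort(n = 500, seed = 97)
  covs <- c("sqrt_psa", "stage2", "stage3")
  fits <- lapply(1:3, function(g) {
    idx <- co$group == g
    weighted_cox_fit(as.data.frame(co)[idx, ], covs)
  })
  expect_equal(dr_group_survival(co, fits, 2, 0), 1)
  s <- dr_group_survival(co, fits, 2, 700)
  expect_equal(s, mean(predict_survival(fits[[2]], co, 700)))
  # homogeneous cohort: the average is the single prediction
  co_h <- as.data.frame(co)
  co_h$sqrt_psa <- 2; co_h$stage2 <- 0; co_h$stage3 <- 0
  expect_equal(dr_group_survival(co_h, fits, 1, 700),
               predict_survival(fits[[1]], co_h[1, ], 700))
  expect_error(dr_group_survival(co, fits[1:2], 3, 700), "missing Cox fit")
})

test_that("under no confounding the three DR estimates agree", {
  # treatment independent of covariates and outcome: constant-rate generator
  pmc <- c(intercept = log(15), sqrt_psa = 0, age = 0, stage2 = 0, stage3 = 0)
  smc <- c(intercept = log(0.001), sqrt_psa = 0, age = 0, stage2 = 0,
           stage3 = 0, group2 = 0, group3 = 0)
  co <- generate_cohort(generation_spec(5000, pm_coefficients = pmc,
                                        sm_coefficients = smc, seed = 101))
  est <- estimate_group_survival(co, 500, "doubly_robust",
                                 covariates = c("sqrt_psa", "stage2", "stage3"),
                                 convention = "shifted", cap = Inf)
  # Monte-Carlo sds of the three group estimates at these settings are about
  # (0.030, 0.012, 0.022) (smallest group ~350 patients, heavy censoring), so
  # the range of the three estimates stays below ~0.08 (about 2 sd of the
  # noisiest pairwise difference)
  expect_lt(max(est[, 1]) - min(est[, 1]), 0.08)
})

test_that("pairwise differences are the three signed contrasts", {
  expect_equal(unname(pairwise_differences(c(0.9, 0.8, 0.7))), c(0.1, 0.2, 0.1))
  expect_equal(unname(pairwise_differences(c(0.5, 0.5, 0.5))), c(0, 0, 0))
  d1 <- pairwise_differences(c(0.9, 0.8, 0.7))
  d2 <- pairwise_differences(c(0.8, 0.9, 0.7))
  expect_equal(d1[["1-2"]], -d2[["1-2"]])
})
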