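#' Named generation models for treatment intensity and survival
#'
#' The simulation harness draws the number of nodes removed from a shifted
#' Poisson model, `(Nex - 1) ~ Poisson(lambda_PM(z))`, and latent event times
#' from an exponential proportional-hazards model with per-day rate
#' `lambda_SM(z, group)`. Both log-rates are linear in the covariates; the
#' model families `pm1`-`pm3` and `sm1`-`sm4` differ in which covariates carry
#' a nonzero coefficient. Omitting a covariate from a model means its
#' coefficient is zero when generating and the covariate is excluded when
#' estimating, which is how model misspecification is produced: estimating
#' under a smaller model than the one that generated the data leaves a real
#' confounder unmodelled.
#'
#' Covariate scales: `sqrt_psa` is the square root of PSA (ng/mL), `age` is in
#' years, `stage2`/`stage3` are T-stage dummies (T1 reference), and
#' `group2`/`group3` are treatment-group dummies (1-10 nodes reference). The
#' survival models `sm1` and `sm2` carry no treatment-group effect (null
#' treatment scenarios); `sm3` and `sm4` do.
#'
#' Intercepts are calibrated so that the mean number of nodes removed is about
#' 16 and marginal survival at 1000 days is roughly one half, and the signs
#' reproduce the confounding structure of the motivating cohort: higher stage
#' and PSA increase both treatment intensity and hazard, older age slightly
#' decreases treatment intensity. Effect sizes on the treatment intensity are
#' kept moderate so that every patient has a non-negligible probability of
#' each treatment group (propensity overlap): the inverse-probability and
#' doubly-robust estimators are only identified under positivity, and a
#' generator that routinely produces group propensities below about 1/1000
#' would confound finite-sample weight instability with the model
#' misspecification the harness is designed to isolate.
#'
#' @param id model identifier: one of `"pm1"`, `"pm2"`, `"pm3"` for propensity
#'   models or `"sm1"`, `"sm2"`, `"sm3"`, `"sm4"` for survival models.
#' @return Named numeric vector of log-linear coefficients.
#' @export
#' @examples
#' pm_coefficients("pm2")
#' sm_coefficients("sm3")
pm_coefficients <- function(id) {
  id <- match.arg(id, names(.pm_registry))
  .pm_registry[[id]]
}

#' @rdname pm_coefficients
#' @export
sm_coefficients <- function(id) {
  id <- match.arg(id, names(.sm_registry))
  .sm_registry[[id]]
}

.pm_registry <- list(
  pm1 = c(intercept = 3.11, sqrt_psa = 0.05, age = -0.010, stage2 = 0.08, stage3 = 0.15),
  pm2 = c(intercept = 2.51, sqrt_psa = 0.05, age = 0.000, stage2 = 0.08, stage3 = 0.15),
  pm3 = c(intercept = 2.61, sqrt_psa = 0.00, age = 0.000, stage2 = 0.08, stage3 = 0.15)
)

.sm_registry <- list(
  sm1 = c(intercept = -8.90, sqrt_psa = 0.15, age = 0.020, stage2 = 0.20, stage3 = 0.40,
          group2 = 0.00, group3 = 0.00),
  sm2 = c(intercept = -7.70, sqrt_psa = 0.15, age = 0.000, stage2 = 0.20, stage3 = 0.40,
          group2 = 0.00, group3 = 0.00),
  sm3 = c(intercept = -7.70, sqrt_psa = 0.15, age = 0.000, stage2 = 0.20, stage3 = 0.40,
          group2 = 0.25, group3 = -0.60),
  sm4 = c(intercept = -7.40, sqrt_psa = 0.00, age = 0.000, stage2 = 0.20, stage3 = 0.40,
          group2 = 0.25, group3 = -0.60)
)

#' Covariates a model uses for estimation
#'
#' The estimation-side covariate set of a named model: the covariates with a
#' nonzero generation coefficient (intercept and treatment-group dummies
#' excluded; the treatment group is handled by fitting one model per group).
#'
#' @param id model identifier as in [pm_coefficients()].
#' @return Character vector of covariate column names.
#' @export
model_covariates <- function(id) {
  co <- if (id %in% names(.pm_registry)) .pm_registry[[id]] else sm_coefficients(id)
  co <- co[setdiff(names(co), c("intercept", "group2", "group3"))]
  names(co)[co != 0]
}

# linear predictor on the log-rate scale; `coefs` follows the registry naming,
# `data` must hold the referenced columns; group dummies are looked up only
# when the coefficient vector carries them
model_linpred <- function(coefs, data, group = NULL) {
  lp <- rep(coefs[["intercept"]], nrow(data))
  for (nm in setdiff(names(coefs), c("intercept", "group2", "group3"))) {
    if (coefs[[nm]] != 0) lp <- lp + coefs[[nm]] * data[[nm]]
  }
  if (all(c("group2", "group3") %in% names(coefs))) {
    if (is.null(group)) group <- data[["group"]]
    if (is.null(group)) stop("model requires a treatment group")
    lp <- lp + coefs[["group2"]] * (group == 2) + coefs[["group3"]] * (group == 3)
  }
  lp
}
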