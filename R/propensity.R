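#' Fit the Poisson propensity model for the number of nodes removed
#'
#' Step 1 of the weighting procedure: a log-linear Poisson regression of the
#' treatment intensity on baseline covariates. Two conventions are supported:
#' `"direct"` models `nodes_removed` itself (the clinical-analysis reading)
#' and `"shifted"` models `nodes_removed - 1` (the simulation generator's
#' mechanism, under which the fitted count distribution has no mass at zero).
#'
#' @param cohort a [cohort()] (or data.frame with the covariate columns and
#'   `nodes_removed`).
#' @param covariates character vector of covariate column names; they enter
#'   the linear predictor untransformed, so factor-like covariates (T stage)
#'   must already be dummy columns.
#' @param convention `"direct"` or `"shifted"`.
#' @return List of class `"propensity_fit"` with `coefficients`, `vcov`,
#'   `convention`, `covariates`, `n_fit`.
#' @export
fit_poisson_propensity <- function(cohort, covariates,
                                   convention = c("direct", "shifted")) {
  convention <- match.arg(convention)
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) stop("missing covariate columns: ", paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(cohort)[covariates]))
  if (any(!is.finite(X))) stop("covariates must be finite and non-missing")
  y <- cohort$nodes_removed - (convention == "shifted")
  if (any(y < 0)) stop("nodes_removed must be >= 1")
  fit <- stats::glm.fit(X, y, family = stats::poisson())
  if (!fit$converged) stop("Poisson propensity fit did not converge")
  beta <- fit$coefficients
  if (any(!is.finite(beta))) stop("singular design: non-estimable coefficients")
  # observed information for Wald intervals: X' diag(mu) X
  mu <- fit$fitted.values
  vc <- tryCatch(solve(crossprod(X * sqrt(mu))),
                 error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vc) <- list(names(beta), names(beta))
  structure(list(coefficients = beta, vcov = vc, convention = convention,
                 covariates = covariates, n_fit = length(y)),
            class = "propensity_fit")
}

#' @export
print.propensity_fit <- function(x, ...) {
  cat(sprintf("Poisson propensity fit (%s convention, n = %d)\n",
              x$convention, x$n_fit))
  print(round(x$coefficients, 4))
  invisible(x)
}

# fitted Poisson mean for each row of `data`
propensity_mean <- function(fit, data) {
  X <- cbind(1, as.matrix(as.data.frame(data)[fit$covariates]))
  unname(drop(exp(X %*% fit$coefficients)))
}

#' Predicted probability of each treatment group
#'
#' Sums the fitted count distribution over the group bands: group 1 collects
#' `Nex` in 1-10, group 2 in 11-20, group 3 the full upper tail beyond 20
#' (computed as one minus the cumulative probability, never a truncated sum).
#' Under the shifted convention the three masses partition the whole
#' distribution; under the direct convention they exclude `P(Nex = 0)` and the
#' sum is `1 - P(Nex = 0 | Z)`.
#'
#' @param fit a [fit_poisson_propensity()] result.
#' @param data data.frame of patients (covariate columns as in the fit).
#' @return data.frame with columns `p1`, `p2`, `p3`.
#' @export
group_probabilities <- function(fit, data) {
  lambda <- propensity_mean(fit, data)
  if (any(!is.finite(lambda))) stop("nonfinite linear predictor")
  if (fit$convention == "shifted") {
    # Nex = 1 + Y, Y ~ Poisson(lambda)
    p1 <- stats::ppois(9, lambda)
    p2 <- stats::ppois(19, lambda) - p1
    p3 <- stats::ppois(19, lambda, lower.tail = FALSE)
  } else {
    p0 <- stats::dpois(0, lambda)
    p1 <- stats::ppois(10, lambda) - p0
    p2 <- stats::ppois(20, lambda) - stats::ppois(10, lambda)
    p3 <- stats::ppois(20, lambda, lower.tail = FALSE)
  }
  data.frame(p1 = p1, p2 = p2, p3 = p3)
}

#' Inverse-probability weights for the observed treatment group
#'
#' Step 2: each patient is weighted by the reciprocal of the predicted
#' probability of the group they actually fell in, truncated at `cap`
#' (default 35). Weights are at least 1 because group probabilities are at
#' most 1. A numerically zero probability yields the cap and a flag.
#'
#' @param fit a [fit_poisson_propensity()] result.
#' @param cohort a [cohort()]; must carry `group`.
#' @param cap truncation ceiling for the weights.
#' @param stabilize multiply weights by the marginal group frequency
#'   (stabilized weights); off by default, matching the plain reciprocal.
#' @return List of class `"ipw_weights"`: `weights`, `probs` (the per-group
#'   probability matrix), `cap`, `n_truncated`, `flagged` (indices with
#'   numerically zero probability).
#' @export
compute_weights <- function(fit, cohort, cap = 35, stabilize = FALSE) {
  if (cap <= 0) stop("cap must be positive")
  pr <- group_probabilities(fit, cohort)
  g <- cohort$group
  if (is.null(g)) stop("cohort must carry a treatment group")
  pg <- as.matrix(pr)[cbind(seq_len(nrow(pr)), g)]
  flagged <- which(pg == 0)
  w <- ifelse(pg > 0, 1 / pg, Inf)
  if (stabilize) {
    marg <- tabulate(g, 3) / length(g)
    w <- w * marg[g]
  }
  n_trunc <- sum(w > cap)
  structure(list(weights = pmin(w, cap), probs = pr, cap = cap,
                 n_truncated = n_trunc, flagged = flagged,
                 stabilized = stabilize),
            class = "ipw_weights")
}

#' @export
print.ipw_weights <- function(x, ...) {
  cat(sprintf("IPW weights: n = %d, cap = %g, truncated = %d\n",
              length(x$weights), x$cap, x$n_truncated))
  print(summary(x$weights))
  invisible(x)
}

#' Weighted standardized mean differences across treatment groups
#'
#' Balance diagnostic: for each covariate and each pair of groups, the
#' difference of weighted means divided by the unweighted pooled standard
#' deviation. Under a correctly specified propensity model the weighted
#' populations are exchangeable and the differences should be near zero.
#'
#' @param cohort a [cohort()].
#' @param weights numeric weights (e.g. from [compute_weights()]).
#' @param covariates covariate column names.
#' @return data.frame with columns `covariate`, `pair`, `smd`.
#' @export
weighted_smd <- function(cohort, weights, covariates) {
  g <- cohort$group
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- expand.grid(covariate = covariates,
                     pair = vapply(pairs, function(p) paste(p, collapse = "v"), ""),
                     stringsAsFactors = FALSE)
  out$smd <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- as.data.frame(cohort)[[out$covariate[i]]]
    p <- pairs[[match(out$pair[i], c("1v2", "1v3", "2v3"))]]
    wm <- function(gg) stats::weighted.mean(v[g == gg], weights[g == gg])
    sd_pool <- sqrt((stats::var(v[g == p[1]]) + stats::var(v[g == p[2]])) / 2)
    out$smd[i] <- (wm(p[1]) - wm(p[2])) / sd_pool
  }
  out
}
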