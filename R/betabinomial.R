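#' Beta-binomial probability mass function
#'
#' Distribution of the number of positive nodes `x` among `nex` examined when
#' the per-node positivity probability varies across patients as
#' `p ~ Beta(alpha, beta)`:
#' `P(X = x | Nex, alpha, beta) = choose(Nex, x) * B(x + alpha, Nex + beta - x) / B(alpha, beta)`.
#' Evaluated on the log scale for numerical stability.
#'
#' @param x number of positive nodes, `0 <= x <= nex` (vectorized).
#' @param nex number of nodes examined.
#' @param alpha,beta positive shape parameters of the mixing Beta.
#' @param log return the log probability.
#' @return Probability (or log-probability) of each `x`.
#' @export
#' @examples
#' betabin_pmf(0:2, 2, 1, 1)  # uniform over {0, 1, 2}
betabin_pmf <- function(x, nex, alpha, beta, log = FALSE) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (any(x < 0) || any(x > nex)) stop("x must lie in [0, nex]")
  lp <- lchoose(nex, x) + lbeta(x + alpha, nex + beta - x) - lbeta(alpha, beta)
  if (log) lp else exp(lp)
}

#' Probability of observing no positive node
#'
#' For a node-positive patient with `nex` nodes examined, the probability of a
#' false-negative nodal staging, `P(X = 0 | Nex, alpha, beta) =
#' B(alpha, Nex + beta) / B(alpha, beta)`. Strictly decreasing in `nex`:
#' examining more nodes makes missing the disease less likely.
#'
#' @param nex number of nodes examined (vectorized, `>= 0`).
#' @inheritParams betabin_pmf
#' @return Probability for each `nex`.
#' @export
#' @examples
#' prob_all_negative(c(5, 10, 15), 2, 8)
prob_all_negative <- function(nex, alpha, beta) {
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (any(nex < 0)) stop("nex must be nonnegative")
  exp(lbeta(alpha, nex + beta) - lbeta(alpha, beta))
}

#' Fit the beta-binomial model by maximum likelihood
#'
#' Maximizes the beta-binomial log-likelihood over `(alpha, beta)` for
#' subjects with `nex` nodes examined and `x` found positive. Optimization is
#' on the log-parameter scale (positivity enforced), from three starting
#' points to guard against flat likelihoods. Marginal 95% Wald confidence
#' intervals come from the observed information on the log scale.
#'
#' The model is meant to be fitted on node-positive patients; the caller
#' selects the rows (see [misclassification_curve()] for downstream use).
#'
#' @param nex integer vector, nodes examined per subject.
#' @param x integer vector, positive nodes per subject.
#' @param conf_level confidence level for the Wald intervals.
#' @return List of class `"betabin_fit"`: `alpha`, `beta`, `loglik`,
#'   `alpha_ci`, `beta_ci`, `n_fit`, `vcov_log` (covariance on the log scale).
#' @export
fit_betabin <- function(nex, x, conf_level = 0.95) {
  stopifnot(length(nex) == length(x))
  if (length(x) < 2) stop("need at least 2 subjects")
  if (any(x < 0) || any(x > nex)) stop("x must lie in [0, nex]")
  if (all(x == 0) || all(x == nex))
    stop("likelihood maximized on the boundary (all counts 0 or all counts nex); no finite MLE")
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    v <- -sum(betabin_pmf(x, nex, a, b, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  # moment-flavoured start: match mean positivity fraction at alpha + beta = 5
  pbar <- min(max(mean(x / nex), 1e-3), 1 - 1e-3)
  starts <- list(log(c(1, 1)),
                 log(c(5 * pbar, 5 * (1 - pbar))),
                 log(c(0.5, 5)))
  # box on the log scale: alpha, beta in [1e-4, ~2e4]; near-binomial data push
  # alpha + beta to the upper bound, which the caller can read as the
  # overdispersion-free limit
  fits <- lapply(starts, function(s)
    tryCatch(stats::optim(s, nll, method = "L-BFGS-B",
                          lower = log(1e-4), upper = log(2e4)),
             error = function(e) NULL))
  fits <- Filter(function(f) !is.null(f) && is.finite(f$value), fits)
  if (!length(fits)) stop("beta-binomial likelihood maximization failed")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  hess <- stats::optimHess(best$par, nll)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- function(i) exp(best$par[i] + c(-1, 1) * zq * se[i])
  structure(list(alpha = exp(best$par[1]), beta = exp(best$par[2]),
                 loglik = -best$value,
                 alpha_ci = ci(1), beta_ci = ci(2),
                 n_fit = length(x), vcov_log = vc),
            class = "betabin_fit")
}

#' @export
print.betabin_fit <- function(x, ...) {
  cat(sprintf("beta-binomial fit (n = %d): alpha = %.3f [%.3f, %.3f], beta = %.3f [%.3f, %.3f]\n",
              x$n_fit, x$alpha, x$alpha_ci[1], x$alpha_ci[2],
              x$beta, x$beta_ci[1], x$beta_ci[2]))
  cat(sprintf("  log-likelihood %.2f\n", x$loglik))
  invisible(x)
}

#' False-negative probability curve over the number of nodes examined
#'
#' Point curve `P(X = 0 | Nex)` at the fitted `(alpha, beta)`, with a
#' confidence band formed from the endpoints of the two marginal confidence
#' intervals: the band at each `nex` is the elementwise min/max of the curve
#' over the four corner combinations of `alpha_ci x beta_ci`.
#'
#' @param fit a [fit_betabin()] result.
#' @param nex_grid increasing integer grid of nodes-examined values.
#' @return data.frame with columns `nex`, `point`, `low`, `high`.
#' @export
misclassification_curve <- function(fit, nex_grid = 1:40) {
  if (!length(nex_grid)) stop("nex_grid must be nonempty")
  corners <- expand.grid(a = fit$alpha_ci, b = fit$beta_ci)
  vals <- mapply(function(a, b) prob_all_negative(nex_grid, a, b),
                 corners$a, corners$b)
  data.frame(nex = nex_grid,
             point = prob_all_negative(nex_grid, fit$alpha, fit$beta),
             low = apply(vals, 1, min),
             high = apply(vals, 1, max))
}
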