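#' Estimate group survival probabilities by one of the three methods
#'
#' Runs the full estimation pipeline on a cohort and returns the per-group
#' survival probabilities at the requested times:
#'
#' * `"unweighted"` — naive Kaplan-Meier per observed group;
#' * `"weighted_km"` — Poisson-propensity fit, inverse-probability weights
#'   truncated at `cap`, then weighted Kaplan-Meier per group (the IPW
#'   procedure);
#' * `"doubly_robust"` — the same weights, then one weighted Cox model per
#'   group fitted on that group's patients, each predicting counterfactual
#'   survival for the whole cohort, averaged (the doubly-robust procedure).
#'
#' @param cohort a [cohort()].
#' @param times evaluation times (same unit as the cohort).
#' @param method one of `"unweighted"`, `"weighted_km"`, `"doubly_robust"`.
#' @param covariates covariate columns for the propensity and Cox models
#'   (ignored by `"unweighted"`).
#' @param convention Poisson-propensity convention, see
#'   [fit_poisson_propensity()].
#' @param cap weight truncation ceiling.
#' @return Matrix `3 x length(times)` of survival probabilities (rows =
#'   groups), with attribute `"weights"` (the [compute_weights()] object) for
#'   the two weighted methods.
#' @export
estimate_group_survival <- function(cohort, times,
                                    method = c("unweighted", "weighted_km", "doubly_robust"),
                                    covariates = NULL,
                                    convention = c("direct", "shifted"),
                                    cap = 35) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  out <- matrix(NA_real_, 3, length(times),
                dimnames = list(paste0("g", 1:3), NULL))
  if (any(tabulate(cohort$group, 3) == 0)) stop("empty treatment group")
  if (method == "unweighted") {
    for (g in 1:3) {
      idx <- cohort$group == g
      km <- kaplan_meier(cohort$time[idx], cohort$event[idx])
      out[g, ] <- survival_at(km, times)
    }
    return(out)
  }
  if (is.null(covariates)) stop("weighted methods need covariates")
  pfit <- fit_poisson_propensity(cohort, covariates, convention)
  w <- compute_weights(pfit, cohort, cap = cap)
  if (method == "weighted_km") {
    for (g in 1:3) {
      idx <- cohort$group == g
      km <- kaplan_meier(cohort$time[idx], cohort$event[idx], w$weights[idx])
      out[g, ] <- survival_at(km, times)
    }
  } else {
    fits <- lapply(1:3, function(g) {
      idx <- cohort$group == g
      weighted_cox_fit(as.data.frame(cohort)[idx, , drop = FALSE],
                       covariates = covariates, weights = w$weights[idx])
    })
    for (g in 1:3) for (j in seq_along(times))
      out[g, j] <- dr_group_survival(cohort, fits, g, times[j])
  }
  attr(out, "weights") <- w
  out
}
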