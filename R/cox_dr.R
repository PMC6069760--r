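#' Weighted Cox model with Breslow baseline hazard
#'
#' Fits a Cox proportional-hazards model by weighted partial likelihood
#' (Breslow tie handling, so integer weights are exactly equivalent to sample
#' replication) and extracts the weighted Breslow baseline cumulative hazard
#' at the covariate origin. The fit can then predict survival for any
#' covariate vector, which is what the doubly-robust estimator needs: each
#' per-group model is fitted on the patients observed in that group, weighted
#' by their inverse-probability weights, and then predicts counterfactual
#' survival for the whole cohort.
#'
#' With an empty covariate set the baseline reduces to the weighted
#' Nelson-Aalen estimator, computed directly.
#'
#' @param data data.frame with `time`, `event` and the covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param weights positive case weights (default unit).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return List of class `"wcox_fit"`: `coefficients`, `basehaz`
#'   (data.frame `time`, `cumhaz` at the covariate origin), `covariates`,
#'   `weighted` flag, `n_events`.
#' @export
weighted_cox_fit <- function(data, covariates = character(), weights = NULL,
                             ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  n <- nrow(data)
  if (is.null(weights)) weights <- rep(1, n)
  if (sum(data$event) < 2) stop("need at least 2 events")
  if (!length(covariates)) {
    # weighted Nelson-Aalen at the (empty) covariate origin
    o <- order(data$time)
    tt <- data$time[o]; ee <- data$event[o]; ww <- weights[o]
    first <- !duplicated(tt)
    ut <- tt[first]
    agg <- rowsum(cbind(ww, ww * ee), cumsum(first))
    risk <- rev(cumsum(rev(agg[, 1])))
    keep <- agg[, 2] > 0
    bh <- data.frame(time = ut[keep],
                     cumhaz = unname(cumsum(agg[keep, 2] / risk[keep])))
    return(structure(list(coefficients = numeric(0), basehaz = bh,
                          covariates = character(), weighted = !all(weights == 1),
                          n_events = sum(data$event)),
                     class = "wcox_fit"))
  }
  df <- as.data.frame(data)[c("time", "event", covariates)]
  df$.w <- weights
  fml <- stats::reformulate(covariates, response = quote(survival::Surv(time, event)))
  fit <- survival::coxph(fml, data = df, weights = .w, ties = ties,
                         robust = FALSE)
  if (any(!is.finite(stats::coef(fit))))
    stop("monotone likelihood / separation: non-finite Cox coefficients")
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(coefficients = stats::coef(fit),
                 basehaz = data.frame(time = bh$time, cumhaz = bh$hazard),
                 covariates = covariates, weighted = !all(weights == 1),
                 n_events = sum(data$event)),
            class = "wcox_fit")
}

#' @export
print.wcox_fit <- function(x, ...) {
  cat(sprintf("weighted Cox fit (%d events)%s\n", x$n_events,
              if (x$weighted) ", case-weighted" else ""))
  if (length(x$coefficients)) print(round(x$coefficients, 4)) else
    cat("  (no covariates: Nelson-Aalen baseline)\n")
  invisible(x)
}

# baseline cumulative hazard at times t (0 before the first jump)
baseline_cumhaz_at <- function(fit, t) {
  vals <- c(0, fit$basehaz$cumhaz)
  vals[findInterval(t, fit$basehaz$time) + 1]
}

#' Predict survival from a weighted Cox fit
#'
#' `S(t | Z) = exp(-Lambda0(t) * exp(beta' Z))` with the Breslow baseline at
#' the covariate origin.
#'
#' @param fit a [weighted_cox_fit()].
#' @param data data.frame of covariates (one row per patient).
#' @param t a single nonnegative time.
#' @return Numeric vector of survival probabilities, one per row of `data`.
#' @export
predict_survival <- function(fit, data, t) {
  if (length(t) != 1 || t < 0) stop("t must be a single nonnegative time")
  lp <- if (length(fit$coefficients)) {
    drop(as.matrix(as.data.frame(data)[fit$covariates]) %*% fit$coefficients)
  } else rep(0, nrow(data))
  unname(exp(-baseline_cumhaz_at(fit, t) * exp(lp)))
}

#' Doubly-robust marginal group survival
#'
#' The average, over all `n` patients (factual and counterfactual), of the
#' group-`g` Cox model's predicted survival:
#' `S_g(t) = (1/n) * sum_i S_i(t | Group = g, Z_i)`.
#'
#' @param cohort a [cohort()] (all patients).
#' @param fits list of three [weighted_cox_fit()] objects, indexed by group.
#' @param g treatment group in `{1, 2, 3}`.
#' @param t a single nonnegative time.
#' @return Survival probability (scalar).
#' @export
dr_group_survival <- function(cohort, fits, g, t) {
  stopifnot(g %in% 1:3)
  if (length(fits) < g || is.null(fits[[g]])) stop("missing Cox fit for group ", g)
  mean(predict_survival(fits[[g]], cohort, t))
}

#' Pairwise differences of the three group survival estimates
#'
#' @param s named or plain numeric vector `(S1, S2, S3)` at a common time.
#' @return Named vector `(S1-S2, S1-S3, S2-S3)`.
#' @export
pairwise_differences <- function(s) {
  stopifnot(length(s) == 3)
  c("1-2" = s[[1]] - s[[2]], "1-3" = s[[1]] - s[[3]], "2-3" = s[[2]] - s[[3]])
}
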