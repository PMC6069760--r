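#' Bootstrap confidence intervals for group survival and contrasts
#'
#' Nonparametric bootstrap over patients: each replicate resamples rows with
#' replacement and refits the entire pipeline (propensity model, weights,
#' estimator), so that propensity-estimation uncertainty propagates into the
#' intervals. Percentile 2.5/97.5 intervals are reported for each group
#' survival probability and each pairwise difference at each time. Replicates
#' in which a treatment group is empty or a fit fails are dropped and
#' counted; a warning attribute is set when more than 10% are dropped.
#'
#' @inheritParams estimate_group_survival
#' @param n_boot number of bootstrap replicates (`>= 2`).
#' @param seed integer seed or `NULL`.
#' @param refit_propensity refit the propensity model inside each replicate
#'   (default); `FALSE` reuses the full-data weights (cheaper, narrower).
#' @param conf_level confidence level.
#' @return data.frame of class `"contrast_estimates"` with columns `method`,
#'   `quantity` (`"S1"`..`"S3"`, `"S1-S2"`, `"S1-S3"`, `"S2-S3"`), `t`,
#'   `point`, `ci_low`, `ci_high`, `flagged` (point outside its own interval),
#'   and attributes `n_boot`, `n_dropped`, `seed`, `high_drop_warning`.
#' @export
bootstrap_cis <- function(cohort, times,
                          method = c("unweighted", "weighted_km", "doubly_robust"),
                          covariates = NULL,
                          convention = c("direct", "shifted"),
                          cap = 35, n_boot = 1000, seed = NULL,
                          refit_propensity = TRUE, conf_level = 0.95) {
  method <- match.arg(method)
  convention <- match.arg(convention)
  if (n_boot < 2) stop("n_boot must be >= 2")
  if (!length(times)) stop("times must be nonempty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  est_fun <- function(co, w_fixed = NULL) {
    if (!refit_propensity && method != "unweighted" && !is.null(w_fixed)) {
      # fixed-weights variant: reuse full-data weights carried with the rows
      m <- matrix(NA_real_, 3, length(times))
      for (g in 1:3) {
        idx <- co$group == g
        if (method == "weighted_km") {
          km <- kaplan_meier(co$time[idx], co$event[idx], w_fixed[idx])
          m[g, ] <- survival_at(km, times)
        }
      }
      if (method == "doubly_robust") {
        fits <- lapply(1:3, function(g) {
          idx <- co$group == g
          weighted_cox_fit(as.data.frame(co)[idx, , drop = FALSE],
                           covariates = covariates, weights = w_fixed[idx])
        })
        for (g in 1:3) for (j in seq_along(times))
          m[g, j] <- dr_group_survival(co, fits, g, times[j])
      }
      return(m)
    }
    estimate_group_survival(co, times, method, covariates, convention, cap)
  }
  point <- est_fun(cohort)
  w_full <- if (!refit_propensity && method != "unweighted")
    attr(point, "weights")$weights else NULL
  reps <- array(NA_real_, c(n_boot, 3, length(times)))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    co_b <- as.data.frame(cohort)[idx, , drop = FALSE]
    co_b$group <- cohort$group[idx]
    res <- tryCatch(est_fun(co_b, w_fixed = w_full[idx]),
                    error = function(e) NULL)
    if (is.null(res) || any(!is.finite(res))) dropped <- dropped + 1L
    else reps[b, , ] <- res
  }
  alpha <- (1 - conf_level) / 2
  qn <- c("S1", "S2", "S3", "S1-S2", "S1-S3", "S2-S3")
  rows <- list()
  for (j in seq_along(times)) {
    svals <- reps[, , j, drop = FALSE][, , 1]
    dvals <- cbind(svals[, 1] - svals[, 2], svals[, 1] - svals[, 3],
                   svals[, 2] - svals[, 3])
    allv <- cbind(svals, dvals)
    pt <- c(point[, j], pairwise_differences(point[, j]))
    for (k in seq_along(qn)) {
      ci <- stats::quantile(allv[, k], c(alpha, 1 - alpha), na.rm = TRUE,
                            names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        method = method, quantity = qn[k], t = times[j],
        point = unname(pt[k]), ci_low = ci[1], ci_high = ci[2],
        flagged = unname(pt[k] < ci[1] | pt[k] > ci[2]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("contrast_estimates", "data.frame")
  attr(out, "n_boot") <- n_boot - dropped
  attr(out, "n_dropped") <- dropped
  attr(out, "seed") <- seed
  attr(out, "high_drop_warning") <- dropped > 0.1 * n_boot
  if (attr(out, "high_drop_warning"))
    warning(sprintf("%d of %d bootstrap replicates dropped", dropped, n_boot))
  out
}

#' Tabulate contrast estimates in long format
#'
#' Reshapes one or more [bootstrap_cis()] results into the reporting layout:
#' one row per method, quantity and time, with point estimate and interval.
#'
#' @param ... `contrast_estimates` data.frames.
#' @return data.frame with columns `method`, `quantity`, `t`, `mean`,
#'   `ci_low`, `ci_high`.
#' @export
summarize_table <- function(...) {
  ests <- list(...)
  if (!length(ests)) stop("no estimates given")
  d <- do.call(rbind, lapply(ests, as.data.frame))
  data.frame(method = d$method, quantity = d$quantity, t = d$t,
             mean = d$point, ci_low = d$ci_low, ci_high = d$ci_high)
}
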