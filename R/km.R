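#' Weighted Kaplan-Meier (product-limit) estimator
#'
#' Product-limit estimator with weighted death counts and weighted risk sets:
#' `S(t) = prod_{t_k <= t} (1 - d_k^w / n_k^w)`, where `d_k^w` is the summed
#' weight of events at `t_k` and `n_k^w` the summed weight of subjects still
#' at risk. With unit weights this is the ordinary Kaplan-Meier estimator;
#' with inverse-probability weights it is the weighted estimator of the
#' counterfactual group survival. Weights enter only as ratios, so rescaling
#' all weights by a constant leaves the curve unchanged, and integer weights
#' act exactly like sample replication.
#'
#' @param time nonnegative follow-up times.
#' @param event 0/1 event indicators.
#' @param weights positive weights (default all 1).
#' @return List of class `"survcurve"`: `times` (distinct event times,
#'   increasing), `surv` (step values right after each event time), `at_risk`
#'   (weighted risk-set size at each event time), `n_subjects`.
#' @export
#' @examples
#' km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
#' km$surv  # 2/3, 1/3, 0
kaplan_meier <- function(time, event, weights = NULL) {
  n <- length(time)
  if (n == 0) stop("empty input")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(event) == n, length(weights) == n)
  if (any(time < 0)) stop("time must be nonnegative")
  if (any(weights <= 0)) stop("weights must be positive")
  o <- order(time)
  tt <- time[o]; ee <- event[o]; ww <- weights[o]
  first <- !duplicated(tt)
  ut <- tt[first]                                    # exact distinct times
  gid <- cumsum(first)
  wt_by_time <- rowsum(cbind(ww, ww * ee), gid)
  risk <- rev(cumsum(rev(wt_by_time[, 1])))          # weight with time >= ut
  dw <- wt_by_time[, 2]
  keep <- dw > 0
  times <- ut[keep]
  surv <- unname(cumprod(1 - dw[keep] / risk[keep]))
  structure(list(times = times, surv = surv, at_risk = unname(risk[keep]),
                 n_subjects = n),
            class = "survcurve")
}

#' @export
print.survcurve <- function(x, ...) {
  cat(sprintf("survival curve: %d subjects, %d event times, final S = %.3f\n",
              x$n_subjects, length(x$times),
              if (length(x$surv)) x$surv[length(x$surv)] else 1))
  invisible(x)
}

#' Evaluate a survival curve at arbitrary times
#'
#' Right-continuous step evaluation: `S(t)` is 1 before the first event time,
#' drops at each event time, and holds its last value beyond the final one.
#'
#' @param curve a [kaplan_meier()] result.
#' @param t nonnegative times (vectorized).
#' @return Survival probability at each `t`.
#' @export
survival_at <- function(curve, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  vals <- c(1, curve$surv)
  unname(vals[findInterval(t, curve$times) + 1])
}

#' Two-sample log-rank test
#'
#' The standard (unweighted) log-rank chi-square test on 1 degree of freedom
#' for a difference in survival between two groups, via
#' [survival::survdiff()]. If neither group has any event the statistic is 0
#' with p-value 1 and the result is flagged.
#'
#' @param time_a,event_a follow-up and event indicator, first group.
#' @param time_b,event_b same for the second group.
#' @return List of class `"logrank"`: `statistic`, `p_value`, `n` (per
#'   group), `flagged`.
#' @export
log_rank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b)) stop("both groups must be nonempty")
  if (sum(event_a) + sum(event_b) == 0) {
    return(structure(list(statistic = 0, p_value = 1,
                          n = c(length(time_a), length(time_b)), flagged = TRUE),
                     class = "logrank"))
  }
  d <- data.frame(time = c(time_a, time_b),
                  event = c(event_a, event_b),
                  grp = rep(c(0, 1), c(length(time_a), length(time_b))))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = d)
  structure(list(statistic = unname(sd$chisq),
                 p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 n = c(length(time_a), length(time_b)), flagged = FALSE),
            class = "logrank")
}

#' @export
print.logrank <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.3f (1 df), p = %.4g%s\n",
              x$statistic, x$p_value, if (x$flagged) " [no events]" else ""))
  invisible(x)
}

#' All pairwise log-rank tests across the three node groups
#'
#' @param cohort a [cohort()].
#' @return data.frame with columns `pair`, `statistic`, `p_value`.
#' @export
log_rank_table <- function(cohort) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  rows <- lapply(pairs, function(p) {
    a <- cohort$group == p[1]; b <- cohort$group == p[2]
    lr <- log_rank_test(cohort$time[a], cohort$event[a],
                        cohort$time[b], cohort$event[b])
    data.frame(pair = paste(p, collapse = " vs "),
               statistic = lr$statistic, p_value = lr$p_value)
  })
  do.call(rbind, rows)
}
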