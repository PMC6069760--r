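#' Assemble and validate a patient cohort
#'
#' A cohort is a plain `data.frame`, one row per patient, carrying at least
#' `nodes_removed`, `group`, `time` and `event`, plus whatever covariate
#' columns the downstream models use. `cohort()` validates the invariants
#' (group banding consistent with `nodes_removed`, node counts within range,
#' nonnegative times) and records the outcome label, time unit and provenance
#' as attributes.
#'
#' @param data data.frame of patient records.
#' @param outcome_label outcome name, e.g. `"BCR"` or `"OS"`.
#' @param time_unit `"days"` (simulation scale) or `"months"` (clinical scale).
#' @param provenance list describing how the cohort was produced (generation
#'   spec, seed, ...) or the string `"external"`.
#' @return The validated data.frame with class `"cohort"` prepended.
#' @export
cohort <- function(data, outcome_label = "BCR", time_unit = "days",
                   provenance = "external") {
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  req <- c("nodes_removed", "group", "time", "event")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (any(data$nodes_removed < 1)) stop("nodes_removed must be >= 1")
  if (!all(data$group == node_group(data$nodes_removed)))
    stop("group must be the banding of nodes_removed")
  if ("nodes_positive" %in% names(data)) {
    bad <- data$nodes_positive < 0 | data$nodes_positive > data$nodes_removed
    if (any(bad, na.rm = TRUE)) stop("nodes_positive must lie in [0, nodes_removed]")
  }
  if (any(data$time < 0)) stop("time must be nonnegative")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  structure(data,
            class = unique(c("cohort", class(data))),
            outcome_label = outcome_label,
            time_unit = time_unit,
            provenance = provenance)
}

#' Band the number of nodes removed into the three treatment groups
#'
#' Group 1: 1-10 nodes removed; group 2: 11-20; group 3: more than 20. This
#' banding partitions every count `>= 1` into exactly one group.
#'
#' @param nodes_removed integer vector of node counts (each `>= 1`).
#' @return Integer vector of group labels in `{1, 2, 3}`.
#' @export
#' @examples
#' node_group(c(1, 10, 11, 20, 21, 40))
node_group <- function(nodes_removed) {
  if (any(nodes_removed < 1)) stop("nodes_removed must be >= 1")
  ifelse(nodes_removed <= 10, 1L, ifelse(nodes_removed <= 20, 2L, 3L))
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d patients, outcome %s, time in %s\n",
              nrow(x), attr(x, "outcome_label"), attr(x, "time_unit")))
  cat(sprintf("  groups (1/2/3): %d/%d/%d; events: %d (%.1f%%)\n",
              sum(x$group == 1), sum(x$group == 2), sum(x$group == 3),
              sum(x$event), 100 * mean(x$event)))
  invisible(x)
}

#' Write / read a cohort as CSV
#'
#' The on-disk schema mirrors a clinical extract: columns `patient_id`, `age`,
#' `psa`, `gleason`, `t_stage`, `nodes_removed`, `nodes_positive`, `time`,
#' `event`. Missing Gleason scores are written as empty fields. Simulated
#' cohorts that carry `sqrt_psa` rather than `psa` are written with
#' `psa = sqrt_psa^2`.
#'
#' @param x a [cohort()].
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   [cohort()].
#' @export
write_cohort <- function(x, path) {
  psa <- if ("psa" %in% names(x)) x$psa else x$sqrt_psa^2
  t_stage <- if ("t_stage" %in% names(x)) x$t_stage else x$stage
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(x)) x$patient_id else seq_len(nrow(x)),
    age = x$age,
    psa = psa,
    gleason = if ("gleason" %in% names(x)) x$gleason else NA,
    t_stage = t_stage,
    nodes_removed = x$nodes_removed,
    nodes_positive = if ("nodes_positive" %in% names(x)) x$nodes_positive else NA,
    time = x$time,
    event = x$event)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param outcome_label,time_unit passed to [cohort()].
#' @export
read_cohort <- function(path, outcome_label = "BCR", time_unit = "months") {
  d <- utils::read.csv(path)
  d$group <- node_group(d$nodes_removed)
  d$t2 <- as.numeric(d$t_stage == 2)
  d$t3 <- as.numeric(d$t_stage == 3)
  cohort(d, outcome_label = outcome_label, time_unit = time_unit,
         provenance = "external")
}
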