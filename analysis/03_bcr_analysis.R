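#!/usr/bin/env Rscript

# Time to biochemical recurrence (BCR) by extent of lymph node dissection.
#
# Three analyses of the same contrast, survival at 60/90/120 months for the
# 1-10 / 11-20 / 21+ node groups:
#   1. unweighted Kaplan-Meier with pairwise log-rank tests (naive);
#   2. inverse-probability-weighted Kaplan-Meier (Poisson propensity on
#      age, PSA, Gleason, T stage; weights truncated at 35);
#   3. doubly-robust estimation (per-group weighted Cox models averaged
#      over the whole cohort).
# All estimates carry percentile bootstrap 95% intervals that refit the
# full pipeline in each replicate.

library(plndsurv)

co <- read_cohort("results/cohort_bcr.csv", outcome_label = "BCR")
covs <- c("gleason", "t2", "t3", "psa", "age")
times <- c(60, 90, 120)
B <- 200

cat("log-rank tests (unweighted):\n")
print(log_rank_table(co), row.names = FALSE)

pfit <- fit_poisson_propensity(co, covs, convention = "direct")
cat("\nPoisson propensity coefficients:\n")
print(pfit)
w <- compute_weights(pfit, co, cap = 35)
cat(sprintf("weights: median %.2f, max %.1f, %d truncated at 35\n\n",
            median(w$weights), max(w$weights), w$n_truncated))

tabs <- lapply(c("unweighted", "weighted_km", "doubly_robust"), function(m) {
  message("bootstrapping ", m, " (B = ", B, ") ...")
  suppressWarnings(
    bootstrap_cis(co, times = times, method = m, covariates = covs,
                  convention = "direct", cap = 35, n_boot = B, seed = 7L))
})
tab <- do.call(summarize_table, tabs)
write.csv(tab, "results/bcr_survival_table.csv", row.names = FALSE)
print(tab, row.names = FALSE, digits = 3)

s13 <- tab[tab$quantity == "S1-S3" & tab$t == 120, ]
cat("\nS(120 months), group 1 minus group 3, by method:\n")
print(s13, row.names = FALSE, digits = 3)
cat("\nIn the unweighted analysis the groups look alike; after weighting\n")
cat("(and doubly-robust adjustment) the 21+ node group shows better\n")
cat("BCR-free survival - the benefit was masked by the worse baseline\n")
cat("prognosis of extensively dissected patients.\n")
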