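#!/usr/bin/env Rscript

# Simulation study: bias and root-MSE of the three estimators of marginal
# S(1000 days) under working-model misspecification.
#
# Cohorts are generated with propensity model pm2 (treatment intensity
# log-linear in sqrt-PSA and stage) and survival model sm3 (exponential
# proportional hazards with a real treatment-group effect). Estimation
# uses either the same models ("correct") or stage-only subsets pm3 / sm4
# ("wrong"): omitted covariates have coefficient zero in generation and are
# excluded from estimation, leaving a real confounder unmodelled.

library(plndsurv)

dir.create("results", showWarnings = FALSE)
reps <- 200

grid <- list(
  scenario_spec("pm2", "sm3", "pm2", "sm3", n = 1000, reps = reps, seed = 13794),
  scenario_spec("pm2", "sm3", "pm2", "sm3", n = 5000, reps = reps, seed = 13795),
  scenario_spec("pm2", "sm3", "pm3", "sm3", n = 5000, reps = reps, seed = 13796),
  scenario_spec("pm2", "sm3", "pm2", "sm4", n = 5000, reps = reps, seed = 13797),
  scenario_spec("pm2", "sm3", "pm3", "sm4", n = 5000, reps = reps, seed = 13798)
)

t0 <- Sys.time()
res <- scenario_grid(grid)
cat(sprintf("%d scenarios x %d replicates in %.1f min\n\n", length(grid), reps,
            as.numeric(difftime(Sys.time(), t0, units = "mins"))))

res$bias <- round(res$bias, 4)
res$root_mse <- round(res$root_mse, 4)
res$true_surv <- round(res$true_surv, 4)
write.csv(res, "results/simulation_study.csv", row.names = FALSE)
print(res, row.names = FALSE)

cat("\nReading the table:\n")
cat(" - the naive estimator is biased whenever treatment is confounded\n")
cat("   (groups 1 and 3), and its root-MSE approaches |bias| as n grows;\n")
cat(" - with both working models correct, weighted and doubly-robust bias\n")
cat("   shrink toward zero as n grows;\n")
cat(" - with a wrong propensity model the weighted estimator is biased\n")
cat("   while the doubly-robust one stays consistent (its second chance:\n")
cat("   the correct outcome model);\n")
cat(" - with a wrong outcome model but correct propensity both remain\n")
cat("   approximately unbiased;\n")
cat(" - with both models wrong, both are biased.\n")

# large-sample consistency snapshot
big <- single_large_sample(scenario_spec("pm2", "sm3", "pm2", "sm3",
                                         n = 200000, reps = 1, seed = 13794))
big$true_surv <- round(big$true_surv, 4)
big$estimate <- round(big$estimate, 4)
big$error <- round(big$error, 4)
write.csv(big, "results/simulation_large_n.csv", row.names = FALSE)
cat("\nsingle large-sample run (n = 200000), correct working models:\n")
print(big, row.names = FALSE)
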