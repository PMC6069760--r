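---
title: "Methods: causal survival estimation for a count-valued treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal survival estimation for a count-valued treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plndsurv)
```

## The problem

In observational prostatectomy cohorts the number of pelvic lymph nodes
removed (`Nex`) is chosen by the surgeon in light of the patient's prognosis:
higher T stage, PSA and Gleason score lead to more extensive dissections.
`Nex`, banded into three groups (1-10, 11-20, 21+ nodes), acts as a
count-valued "treatment" whose assignment is confounded with the outcome.
Unweighted Kaplan-Meier curves by group therefore mix any causal effect of
dissection extent with the worse baseline prognosis of extensively dissected
patients. This package implements the estimation workflow for that setting:
a misclassification model for nodal staging, a Poisson propensity with
inverse-probability weights, weighted and doubly-robust survival estimators
with bootstrap inference, and a simulation harness that quantifies what each
estimator does under working-model misspecification.

## Nodal misclassification model

For a node-positive patient with `Nex` examined nodes and `X` found
positive, `X | p ~ Binomial(Nex, p)` with `p ~ Beta(alpha, beta)` across
patients, giving the beta-binomial marginal. The probability of a
false-negative staging is

$$P(X = 0 \mid Nex, \alpha, \beta) = \frac{B(\alpha, Nex + \beta)}{B(\alpha, \beta)},$$

strictly decreasing in `Nex`. Assumptions: nodes within a patient share one
positivity probability, and examined nodes are independent trials. The
likelihood is maximized on the `log(alpha), log(beta)` scale (positivity
enforced) with three starting points and an L-BFGS-B box of
`[1e-4, 2e4]` per parameter; data in which every patient shows `X = 0` or
`X = Nex` put the maximum on the boundary and are rejected as
non-identifiable. Near-binomial data (no overdispersion) drive
`alpha + beta` to the box ceiling, which callers can read as the binomial
limit. The confidence band of the false-negative curve takes, at each `Nex`,
the min and max over the four corner combinations of the two marginal 95%
Wald intervals; because the curve is monotone in each parameter the band is
exact for the box and always brackets the point curve. Fitting is meant for
the node-positive subset; note that selecting patients with `X > 0` is an
implicit truncation, so on strongly selected data the fitted `(alpha, beta)`
describe that subset rather than the latent population — the workflow keeps
the convention of the field.

## Propensity model and weights

Step 1 fits a log-linear Poisson regression for the node count and converts
it to group probabilities by summing the fitted count distribution over the
bands: `P1 = P(1 <= Nex <= 10 | Z)`, `P2 = P(11 <= Nex <= 20 | Z)`, and
`P3` as one minus the cumulative mass at 20 (never a truncated literal sum).
Two conventions are supported and recorded in the fit. The *direct*
convention models `Nex` itself, matching the clinical analysis; its three
group masses exclude `P(Nex = 0 | Z)` and are used unnormalized, following
the procedure as written (a renormalization flag is deliberately absent —
with mean counts around 15, `P(Nex = 0)` is below `1e-6` and the distinction
is immaterial). The *shifted* convention models `Nex - 1`, matching the
simulation generator, under which the three masses partition to one exactly.

Step 2 weights each patient by `1 / P_g(Z)` for their observed group `g`,
truncated at 35 by default in the clinical pipeline (an alternative cap of
20 is a one-argument change). Stabilized weights (multiplied by the marginal
group share) are available behind a flag but off by default. The simulation
harness uses untruncated weights: truncation is a finite-sample variance
device, and capping would re-bias the weighted estimator precisely where the
harness is meant to demonstrate its consistency.

## Survival estimators

*Weighted Kaplan-Meier* (IPW Steps 3-4): the product-limit estimator with
weighted event counts and weighted risk sets, fitted separately per observed
group. Weights enter only as ratios, so constant weights reproduce the
unweighted estimator exactly and integer weights are exactly equivalent to
sample replication; both identities are tested.

*Doubly-robust estimator* (Steps 3-6): one weighted Cox model per group,
fitted on that group's patients with their IPW weights and the same
covariates as the propensity model, then used to predict counterfactual
survival `S(t | Group = g, Z_i)` for *every* patient; the group-`g` marginal
estimate is the average of those `n` predictions. Consistency requires only
one of the two working models (propensity or outcome) to be correct. Ties
are handled by Breslow's method so that the replication-equivalence identity
is exact (Efron is available behind a flag); the baseline cumulative hazard
is the weighted Breslow estimator evaluated at the covariate origin (the
underlying fit centers covariates internally for numerical stability and
un-centers on extraction). With an empty covariate set the baseline reduces
to the weighted Nelson-Aalen estimator, computed directly. Curves are step
functions over observed event times with right-continuous evaluation and no
smoothing.

Whether the outcome models should use covariates beyond the propensity set
is not determined by the procedure; this implementation adopts the same
covariate set for both, which also makes the misspecification scenarios
symmetric.

## Bootstrap inference

Percentile bootstrap over patients (resampling rows with replacement),
`B = 1000` by default, refitting the entire pipeline — propensity, weights,
estimator — inside every replicate so that propensity-estimation uncertainty
propagates into the intervals; a fixed-weights variant exists for speed.
Percentile rather than BCa is the simplest defensible choice for a
"bootstrap technique" with no further specification. Replicates with an
empty group or a failed fit are dropped and counted; above 10% dropped the
result carries a warning. Percentile intervals can in principle fail to
contain the point estimate; such rows are flagged rather than silently
reordered. Percentile coverage is an asymptotic guarantee: with fewer than a
few hundred patients per group and heavy censoring at the evaluation time,
the group-survival distribution is too discrete and the intervals undercover
(the calibration test therefore runs at 1000 patients, where a 200-replicate
experiment sits inside 95% +/- 4%).

## Synthetic-data generator

The simulation covariates are `sqrt(PSA) ~ N(2, sd 2)`,
`Age ~ N(60, sd 3)` and T stage multinomial `(.22, .33, .45)`. The second
parameters of the two normal laws are read as a standard deviation for PSA
and a variance of 9 (sd 3) for age — the combination that keeps PSA mostly
positive and ages plausibly in the 50s-60s; both are arguments. Negative
`sqrt(PSA)` draws are kept: the square-root scale is what enters every
linear predictor, and truncation would distort the laws above.
`Nex - 1 ~ Poisson(lambda_PM(z))` with log-linear `lambda_PM`, so every
subject has at least one node; latent event times are exponential with
log-linear rate `lambda_SM(z, group)` (an exponential proportional-hazards
model) and censoring is exponential with mean 500 days, evaluated by default
at `t* = 1000` days (a `{500, 1000, 1500}` grid is supported). The clinical
fixture uses months, draws Gleason scores so the propensity can use all four
clinical covariates, and adds a protective effect of the 21+ group on
biochemical recurrence but none on overall survival, so the drivers can show
the confounding-masked benefit on one outcome and its absence on the other.

The named model families `pm1`-`pm3` and `sm1`-`sm4` differ only in which
covariates carry nonzero coefficients; misspecification is produced exactly
by omission — a covariate absent from the estimation model was present in
generation. The shipped coefficients (see `pm_coefficients()`) were fixed
once against four design criteria: mean `Nex` near 16; confounding direction
as in the motivating cohort (higher stage/PSA means more nodes and worse
survival, slightly younger patients get more nodes); marginal `S(1000)`
around one half; and genuine propensity overlap, meaning effect sizes
moderate enough that group propensities rarely fall below about `1/1000`.
The last criterion matters most: with a wide `lambda_PM` spread the
weighted estimator's heavy-tailed weights make finite-sample noise
indistinguishable from the model-misspecification bias the harness is
designed to isolate. The price of a Poisson treatment count with moderate
spread is underdispersion relative to the real cohort — group shares come
out near 9% / 76% / 15% rather than the clinical 27% / 45% / 28%. The
generator also omits competing risks, non-proportional hazards,
informative censoring and measurement error; passing tests demonstrate the
estimators' behavior under the stated mechanism, not robustness to these
features of real data.

## Simulation harness and problem sizes

Each scenario replicate generates a cohort, computes the true counterfactual
group survival as the covariate average
`(1/n) sum_i exp(-lambda_SM(z_i, g) t*)` on that replicate's own covariates,
and estimates it with the naive, weighted and doubly-robust estimators;
`bias` is the mean error and `root_mse` the root mean squared error across
replicates (so `root_mse >= |bias|` always). The harness uses the shifted
Poisson convention, matching the generator. Desk-scale defaults are 300
replicates at `n` of 1000 and 5000, with a single consistency run at
`n = 200000`; these sizes put Monte-Carlo error well below the bias patterns
of interest for the doubly-robust estimator, while for the weighted
estimator in the smallest group the single-replicate sampling error at
`n = 200000` is still around 0.01 — a caveat stated here because a
one-replicate check against a 0.01 bound is then a coin toss rather than a
guarantee. Failed replicates (monotone likelihood in a small group, an
empty group) are dropped and counted, with a flag above 10%.

## Known limitations

- Weights assume the propensity model family contains the truth; no
  machine-learned or nonparametric propensities.
- No competing risks (deaths censor BCR), no time-varying covariates or
  weights, no stratified baseline hazards.
- Closed-form (Greenwood / influence-function) variances are not provided;
  inference is bootstrap-only.
- The beta-binomial model keeps the field's simplifying assumptions
  (homogeneous within-patient positivity, correctly staged positives).
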