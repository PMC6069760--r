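# shared fixtures, built in code at test time

# small deterministic simulated cohort on the day scale
small_cohort <- function(n = 800, seed = 42, sm = "sm3") {
  generate_cohort(generation_spec(n = n, pm = "pm2", sm = sm, seed = seed))
}

# hand product-limit oracle: plain loop over distinct event times
km_oracle <- function(time, event, weights = rep(1, length(time))) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  vapply(ut, function(tt) {
    d <- sum(weights[time == tt & event == 1])
    r <- sum(weights[time >= tt])
    s <<- s * (1 - d / r)
    s
  }, numeric(1))
}

# replicate rows of a data.frame according to integer weights
replicate_rows <- function(d, w) d[rep(seq_len(nrow(d)), w), , drop = FALSE]
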