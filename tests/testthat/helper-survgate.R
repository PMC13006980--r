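# Shared fixtures: a down-scaled cohort + model so unit tests stay fast.
# Dimensions are small but the code paths are identical to full scale.

tiny_sim <- function(n = 30, ...) {
  sim_config(n = n, n_cancers = 2, institutions_per_cancer = 2,
             d_img = 12, d_rna = 6, d_txt = 8, ...)
}

tiny_model <- function(...) {
  model_config(d = 8, n_heads = 2, d_ff = 16, n_cancers = 2,
               d_img = 12, d_rna = 6, d_txt = 8, ...)
}

# Cohort with a couple of missing auxiliary modalities plus a fitted
# discretizer, ready for make_batch().
tiny_setup <- function(seed = 1, n = 30, ...) {
  cohort <- generate_cohort(tiny_sim(n), seed = seed)
  cohort$mask[2, 2] <- 0L
  cohort$mask[3, 3] <- 0L
  disc <- fit_discretizer(cohort$meta, n_bins = 4)
  list(cohort = cohort, cfg = tiny_model(...), disc = disc)
}

# Random censored C-index instance with at least one comparable pair
# (the earliest follow-up time is forced to be an event) and deliberate
# risk ties (risks live on a half-integer grid).
rand_cens_instance <- function(n) {
  times <- sample(100, n, replace = TRUE) + stats::runif(n)
  events <- stats::rbinom(n, 1, 0.6)
  events[which.min(times)] <- 1L
  risks <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)
  list(risks = risks, times = times, events = events)
}

# Loop oracle for the survival curve: S(t) = prod_{k<=t}(1 - h_k).
surv_loop_oracle <- function(h) {
  s <- numeric(length(h))
  acc <- 1
  for (k in seq_along(h)) {
    acc <- acc * (1 - h[k])
    s[k] <- acc
  }
  s
}
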