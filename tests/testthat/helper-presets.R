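# Shared fixtures for the test suite: the three representative patients and
# a closed-form logistic solution used as an integration oracle.

presets <- function() lapply(
  c(best = "best_responder", resp = "responder", non = "non_responder"),
  representative_patient)

table1_inits <- function() list(
  best_responder = c(606.06, 757.58, 1.94e-10),
  responder      = c(560.36, 747.59, 47.10),
  non_responder  = c(319.63, 707.76, 273.97))

# logistic growth x' = r x (1 - x/K) from x0
logistic_solution <- function(t, x0, r, K) {
  K * x0 / (x0 + (K - x0) * exp(-r * t))
}

# PSA value stored in a simulation at an exact sample time
psa_at <- function(sim, t) {
  i <- which.min(abs(sim$times - t))
  stopifnot(abs(sim$times[i] - t) < 1e-8)
  sim$psa_trace[i]
}
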