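test_that("both protocols start with treatment on and validate their input", {
  expect_identical(initial_state("MTD"), "on")
  expect_identical(initial_state("AT"), "on")
  expect_error(initial_state("weekly"))
})

test_that("switching thresholds implement the half/baseline hysteresis", {
  w <- psa_weights(1 / 3, 1 / 3)
  base <- psa_level(populations(606.06, 757.58, 1.94e-10), w)
  on_ev <- switching_event("AT", "on", base, w)
  off_ev <- switching_event("AT", "off", base, w)

  # on-treatment event vanishes where PSA = baseline / 2
  half <- populations(606.06 / 2, 757.58 / 2, 0.97e-10)
  expect_equal(on_ev(half), 0, tolerance = 1e-9)
  expect_gt(on_ev(populations(606.06, 757.58, 1.94e-10)), 0)
  # off-treatment event vanishes where PSA = baseline
  expect_equal(off_ev(populations(606.06, 757.58, 1.94e-10)), 0,
               tolerance = 1e-9)
  expect_lt(off_ev(half), 0)

  # MTD never fires regardless of the state
  mtd_ev <- switching_event("MTD", "on", base, w)
  expect_gt(mtd_ev(half), 0)
  expect_gt(mtd_ev(populations(0, 0, 0)), 0)

  expect_error(switching_event("AT", "on", 0, w), "degenerate baseline")
})

test_that("adaptive switches land exactly on the PSA thresholds and alternate", {
  pat <- representative_patient("responder")
  w <- psa_weights(0, 1)
  sim <- run_simulation(pat$params, pat$init, "AT", w, horizon = 1500)
  sw <- sim$therapy$switch_times
  base <- sim$therapy$baseline_psa

  expect_gt(nrow(sw), 2)
  expect_true(all(diff(sw$time) > 0))
  expect_identical(sw$state, rep(c("off", "on"), length.out = nrow(sw)))

  for (k in seq_len(nrow(sw))) {
    target <- if (sw$state[k] == "off") 0.5 * base else base
    expect_equal(psa_at(sim, sw$time[k]), target, tolerance = 1e-6)
  }
})

test_that("MTD dynamics never consult PSA: trajectories identical across weights", {
  pat <- representative_patient("non_responder")
  sims <- lapply(list(psa_weights(1, 0), psa_weights(0, 1), psa_weights(0, 0)),
                 function(w) run_simulation(pat$params, pat$init, "MTD", w,
                                            horizon = 300))
  expect_identical(sims[[1]]$trajectory, sims[[2]]$trajectory)
  expect_identical(sims[[1]]$trajectory, sims[[3]]$trajectory)
  expect_identical(sims[[1]]$tcr, sims[[2]]$tcr)
  expect_identical(sims[[1]]$tcr, sims[[3]]$tcr)
  expect_equal(nrow(sims[[1]]$therapy$switch_times), 0)
})

test_that("applicability requires a discontinuation before competitive release", {
  rec <- function(times, states) list(protocol = "AT",
                                      switch_times = data.frame(time = times,
                                                                state = states))
  expect_true(at_applicable(rec(c(10, 30), c("off", "on")), tcr = 50, horizon = 100))
  expect_false(at_applicable(rec(c(60, 80), c("off", "on")), tcr = 50, horizon = 100))
  expect_false(at_applicable(rec(numeric(0), character(0)), tcr = 50, horizon = 100))
  expect_true(at_applicable(rec(10, "off"), tcr = NA, horizon = 100))
  expect_false(at_applicable(list(protocol = "MTD",
                                  switch_times = data.frame(time = 10, state = "off")),
                             tcr = NA, horizon = 100))
})

test_that("zero baseline PSA degrades to a not-applicable run, not an error", {
  pat <- representative_patient("non_responder")
  sim <- run_simulation(pat$params, populations(100, 200, 0), "AT",
                        psa_weights(0, 0), horizon = 500)
  expect_false(sim$at_applicable)
  expect_equal(nrow(sim$therapy$switch_times), 0)
  expect_equal(sim$therapy$baseline_psa, 0)
})
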