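test_that("competition matrices are sampled from the admissible discrete set", {
  set.seed(101)
  A <- sample_competition_matrix()
  expect_equal(unname(diag(A)), c(1, 1, 1))
  set.seed(101)
  expect_identical(sample_competition_matrix(), A)

  set.seed(202)
  draws <- replicate(10000, sample_competition_matrix()[row(diag(3)) != col(diag(3))])
  expect_true(all(draws %in% seq(0.4, 0.9, by = 0.1)))
  # uniformity over the six values: binomial 3-sigma band around 1/6
  freq <- table(factor(draws, levels = seq(0.4, 0.9, by = 0.1))) / length(draws)
  se <- sqrt((1 / 6) * (5 / 6) / length(draws))
  expect_true(all(abs(freq - 1 / 6) < 3 * se))
})

test_that("the printed matrices classify into their categories", {
  best <- classify_patient(competition_matrix("best_responder"))
  expect_equal(best$category, "best_responder")
  expect_lt(best$tminus_fraction, 1e-6)

  resp <- classify_patient(competition_matrix("responder"))
  expect_equal(resp$category, "responder")
  expect_equal(resp$tminus_fraction, 0.0344828, tolerance = 1e-5)

  non <- classify_patient(competition_matrix("non_responder"))
  expect_equal(non$category, "non_responder")
  expect_equal(non$tminus_fraction, 0.2105263, tolerance = 1e-5)
})

test_that("classification is invariant to the carrying-capacity scale", {
  set.seed(33)
  for (i in 1:20) {
    p <- model_params(A = sample_competition_matrix())
    f1 <- untreated_equilibrium(p, scale_K = 1000)$tminus_fraction
    f2 <- untreated_equilibrium(p, scale_K = 10000)$tminus_fraction
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("cohorts are reproducible and anchored to the untreated equilibrium", {
  cohort <- generate_cohort(50, seed = 7)
  expect_identical(generate_cohort(50, seed = 7), cohort)
  expect_equal(nrow(cohort), 50)
  expect_true(all(cohort$category %in%
                    c("best_responder", "responder", "non_responder")))
  expect_true(all(as.matrix(cohort[, c("a12", "a13", "a21", "a23", "a31", "a32")])
                  %in% seq(0.4, 0.9, by = 0.1)))

  # initial conditions = init_fraction x untreated equilibrium at K = 10000
  row <- cohort[17, ]
  eq <- untreated_equilibrium(model_params(A = cohort_matrix(row)),
                              scale_K = 10000)
  expect_equal(c(row$init_tplus, row$init_tp, row$init_tminus),
               unname(0.1 * eq$populations), tolerance = 1e-10)
  expect_equal(row$eq_tminus_fraction, eq$tminus_fraction, tolerance = 1e-10)
})

test_that("representative initial conditions are recovered from the generator scheme", {
  t1 <- table1_inits()
  for (cat in names(t1)) {
    eq <- untreated_equilibrium(model_params(A = competition_matrix(cat)),
                                scale_K = 10000)
    tol <- if (cat == "responder") 0.5 else 0.01  # printed responder row is
    # itself a rounded numerical equilibrium, exact only to ~0.4 cells
    expect_true(all(abs(0.1 * eq$populations - t1[[cat]]) < tol),
                info = cat)
  }
})

test_that("synthetic PSA series sample the model exactly and carry unit-mean noise", {
  pat <- representative_patient("non_responder")
  sim <- run_simulation(pat$params, pat$init, "MTD", psa_weights(1 / 3, 1 / 3),
                        horizon = 200, sample_dt = 1)
  obs <- synthesize_psa_series(sim, sampling_interval = 10, noise_cv = 0)
  expect_equal(obs$time, seq(0, 200, by = 10))
  expect_equal(obs$psa_observed,
               sim$psa_trace[match(obs$time, sim$times)], tolerance = 1e-12)

  # sampling interval beyond the horizon: a single baseline measurement
  one <- synthesize_psa_series(sim, sampling_interval = 500)
  expect_equal(nrow(one), 1)
  expect_equal(one$time, 0)

  # multiplicative lognormal noise has unit mean: sample mean within 1%
  flat <- sim
  flat$times <- 0:9999
  flat$psa_trace <- rep(100, 10000)
  flat$horizon <- 9999
  set.seed(5)
  noisy <- synthesize_psa_series(flat, sampling_interval = 1, noise_cv = 0.1)
  expect_equal(nrow(noisy), 10000)
  expect_lt(abs(mean(noisy$psa_observed) - 100) / 100, 0.01)
  expect_error(synthesize_psa_series(sim, sampling_interval = 0), "sampling_interval")
  expect_error(synthesize_psa_series(sim, 10, noise_cv = -1), "noise_cv")
})
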