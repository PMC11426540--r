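test_that("carrying capacities follow the treatment regime and the TP coupling", {
  p <- model_params(A = competition_matrix("best_responder"))
  pops <- populations(606.06, 757.58, 1.94e-10)

  K_off <- carrying_capacities(pops, p, treatment_on = FALSE)
  expect_equal(unname(K_off[["K_tplus"]]), 1.5 * 757.58, tolerance = 1e-12)
  expect_equal(unname(K_off[["K_tp"]]), 10000)
  expect_equal(unname(K_off[["K_tminus"]]), 10000)

  K_on <- carrying_capacities(pops, p, treatment_on = TRUE)
  expect_equal(unname(K_on[["K_tplus"]]), 0.5 * 757.58, tolerance = 1e-12)
  expect_equal(unname(K_on[["K_tp"]]), 100)
  expect_equal(unname(K_on[["K_tminus"]]), 10000)

  # degenerate K_T+ = 0 when TP is extinct is legal output in both regimes
  no_tp <- populations(10, 0, 10)
  expect_equal(unname(carrying_capacities(no_tp, p, TRUE)[["K_tplus"]]), 0)
  expect_equal(unname(carrying_capacities(no_tp, p, FALSE)[["K_tplus"]]), 0)
})

test_that("right-hand side matches direct evaluation of the growth law", {
  p <- model_params(A = competition_matrix("best_responder"))

  expect_equal(unname(lv_rhs(populations(0, 0, 0), p, FALSE)), c(0, 0, 0))
  # single resistant population at half capacity: r*x*(1 - x/K)
  dx <- lv_rhs(populations(0, 0, 5000), p, FALSE)
  expect_equal(unname(dx[["x_tminus"]]), 0.0066542 * 5000 * 0.5,
               tolerance = 1e-12)
  expect_equal(unname(dx[["x_tminus"]]), 16.6355, tolerance = 1e-6)
  # population sitting exactly at carrying capacity does not move
  expect_equal(unname(lv_rhs(populations(0, 10000, 0), p, FALSE)[["x_tp"]]), 0)
  # derivative stays finite when the TP collapse floors K_T+
  dx <- lv_rhs(populations(50, 0, 0), p, TRUE)
  expect_true(all(is.finite(dx)))
  expect_lt(dx[["x_tplus"]], 0)
})

test_that("parameter and state validation rejects invalid input", {
  A <- competition_matrix("responder")
  expect_error(model_params(r_tplus = -1, A = A), "growth rates")
  expect_error(model_params(K_tp_off = 0, A = A), "carrying capacities")
  bad <- A; bad[1, 1] <- 0.9
  expect_error(model_params(A = bad), "diagonal")
  bad <- A; bad[1, 2] <- 1.2
  expect_error(model_params(A = bad), "off-diagonal")
  expect_error(populations(-1, 0, 0), "non-negative")
})

test_that("PSA model evaluates the weighted combination and validates weights", {
  pops <- populations(606.06, 757.58, 1.94e-10)
  expect_equal(psa_level(pops, psa_weights(1, 0)), 606.06)
  expect_equal(psa_level(pops, psa_weights(0, 0)), 1.94e-10)
  expect_equal(psa_level(pops, psa_weights(1 / 3, 1 / 3)),
               (606.06 + 757.58 + 1.94e-10) / 3, tolerance = 1e-12)

  expect_error(psa_weights(1.5, 0), "invalid weights")
  expect_error(psa_weights(-0.1, 0.5), "invalid weights")
  expect_error(psa_weights(0.5, 0.6), "invalid weights")
})

test_that("PSA always lies between the smallest and largest subpopulation", {
  set.seed(11)
  for (i in 1:200) {
    x <- populations(runif(1, 0, 1e4), runif(1, 0, 1e4), runif(1, 0, 1e4))
    a <- runif(1)
    w <- psa_weights(a, runif(1, 0, 1 - a))
    v <- psa_level(x, w)
    expect_gte(v, min(x) - 1e-9)
    expect_lte(v, max(x) + 1e-9)
  }
})

test_that("single-type dynamics match the closed-form logistic solution", {
  p <- model_params(A = competition_matrix("best_responder"))
  ts <- seq(0, 2000, by = 20)

  # resistant type alone, untreated: grows to K = 10000
  tr <- lv_integrate(p, populations(0, 0, 100), ts, treatment_on = FALSE)
  expect_lt(max(abs(tr$x_tminus - logistic_solution(ts, 100, p$r[["tminus"]], 1e4)) /
                logistic_solution(ts, 100, p$r[["tminus"]], 1e4)), 1e-6)

  # TP alone under treatment: declines towards K = 100
  tr <- lv_integrate(p, populations(0, 757.58, 0), ts, treatment_on = TRUE)
  ref <- logistic_solution(ts, 757.58, p$r[["tp"]], 100)
  expect_lt(max(abs(tr$x_tp - ref) / ref), 1e-6)
})

test_that("trajectories from non-negative states stay non-negative", {
  set.seed(7)
  p <- model_params(A = competition_matrix("non_responder"))
  for (i in 1:5) {
    init <- populations(runif(1, 0, 2000), runif(1, 0, 2000),
                        if (i %% 2) 0 else runif(1, 0, 2000))
    for (on in c(TRUE, FALSE)) {
      tr <- lv_integrate(p, init, seq(0, 3000, by = 30), treatment_on = on)
      expect_true(all(as.matrix(tr[, -1]) >= -1e-8))
      if (init[[3]] == 0) expect_equal(tr$x_tminus, rep(0, nrow(tr)))
    }
  }
})
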