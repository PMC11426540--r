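#' Treatment-dependent carrying capacities
#'
#' Abiraterone blocks testosterone production by `TP` cells, which is
#' modelled as a drop of the `TP` carrying capacity from `K_tp_off` to
#' `K_tp_on`. `T+` cells rely on the testosterone produced by `TP` cells,
#' so their carrying capacity is a linear function of the current `TP`
#' density, `K_T+ = mu * x_TP`, with `mu = mu_off` without treatment and
#' `mu = mu_on` under treatment. The resistant `T-` capacity is constant.
#'
#' A degenerate `K_T+ = 0` (when `x_TP = 0`) is legal output here; the
#' right-hand side [lv_rhs()] floors capacities at `params$K_floor` before
#' dividing.
#'
#' @param pops Population vector, see [populations()].
#' @param params Model parameters, see [model_params()].
#' @param treatment_on Logical; is abiraterone currently administered?
#' @return Named numeric vector `c(K_tplus, K_tp, K_tminus)` in cells.
#' @examples
#' p <- model_params(A = competition_matrix("best_responder"))
#' carrying_capacities(populations(606.06, 757.58, 0), p, treatment_on = FALSE)
#' @export
carrying_capacities <- function(pops, params, treatment_on) {
  mu <- if (treatment_on) params$mu_on else params$mu_off
  c(K_tplus = mu * pops[[2]],
    K_tp = if (treatment_on) params$K_tp_on else params$K_tp_off,
    K_tminus = params$K_tminus)
}

#' Right-hand side of the competition model
#'
#' Instantaneous rate of change of each subpopulation:
#' `dx_i/dt = r_i * x_i * (1 - sum_j a_ij * x_j / K_i)`, with carrying
#' capacities from [carrying_capacities()]. Capacities are floored at
#' `params$K_floor` so the vector field stays finite when `x_TP -> 0`
#' drives `K_T+` to zero; with the capacity at the floor and `x_T+ > 0`
#' the term is a large negative per-capita rate, i.e. rapid death of
#' `T+` cells deprived of testosterone. The per-capita decline is capped
#' at `params$decline_cap` (see [model_params()]) so that this extinction
#' regime, while still effectively instantaneous, does not make the
#' system arbitrarily stiff.
#'
#' @inheritParams carrying_capacities
#' @return Named numeric vector of per-day derivatives.
#' @examples
#' p <- model_params(A = competition_matrix("best_responder"))
#' lv_rhs(populations(0, 0, 5000), p, treatment_on = FALSE)
#' @export
lv_rhs <- function(pops, params, treatment_on) {
  x <- as_populations(pops)
  K <- pmax(carrying_capacities(x, params, treatment_on), params$K_floor)
  percap <- pmax(params$r * (1 - as.vector(params$A %*% x) / K),
                 -params$decline_cap)
  dx <- x * percap
  names(dx) <- c("x_tplus", "x_tp", "x_tminus")
  dx
}

# deSolve-facing derivative: parms = list(params = <lv_params>, on = <flag>).
# Unchecked on purpose (called thousands of times per integration).
.lv_deriv <- function(t, x, parms) {
  p <- parms$params
  mu <- if (parms$on) p$mu_on else p$mu_off
  K <- c(max(mu * x[2], p$K_floor),
         if (parms$on) p$K_tp_on else p$K_tp_off,
         p$K_tminus)
  list(x * pmax(p$r * (1 - as.vector(p$A %*% x) / K), -p$decline_cap))
}

#' Integrate the model under a fixed treatment regime
#'
#' Low-level integration with treatment permanently on or off (no
#' protocol switching). Used for equilibrium checks and as the
#' integration oracle in tests; [run_simulation()] is the protocol-aware
#' driver.
#'
#' @inheritParams carrying_capacities
#' @param init Initial population vector.
#' @param times Numeric vector of output times (days), increasing.
#' @param rtol,atol Relative / absolute solver tolerances. The absolute
#'   tolerance default is far below the smallest population of interest
#'   (the best-responder preset starts with `x_T- = 1.94e-10` cells).
#' @return Data frame with columns `time`, `x_tplus`, `x_tp`, `x_tminus`.
#' @examples
#' p <- model_params(A = competition_matrix("best_responder"))
#' tr <- lv_integrate(p, populations(0, 0, 100), times = seq(0, 500, 10),
#'                    treatment_on = FALSE)
#' tail(tr, 2)
#' @export
lv_integrate <- function(params, init, times, treatment_on = FALSE,
                         rtol = 1e-8, atol = 1e-12) {
  init <- as_populations(init)
  out <- deSolve::lsoda(y = unname(init), times = times, func = .lv_deriv,
                        parms = list(params = params, on = treatment_on),
                        rtol = rtol, atol = atol)
  out <- as.data.frame(out)
  names(out) <- c("time", "x_tplus", "x_tp", "x_tminus")
  out
}

#' PSA observation model
#'
#' Serum PSA as a weighted combination of the subpopulation sizes:
#' `PSA(t) = alpha * x_T+(t) + beta * x_TP(t) + (1 - alpha - beta) * x_T-(t)`.
#' Because the weights are a convex combination, the PSA level always lies
#' between the smallest and largest subpopulation.
#'
#' @param pops Population vector, see [populations()].
#' @param weights PSA production weights, see [psa_weights()].
#' @return PSA level (weighted cell-count units).
#' @examples
#' psa_level(populations(606.06, 757.58, 1.94e-10), psa_weights(1/3, 1/3))
#' @export
psa_level <- function(pops, weights) {
  if (!inherits(weights, "psa_weights")) stop("weights must be psa_weights()")
  x <- as_populations(pops)
  weights$alpha * x[[1]] + weights$beta * x[[2]] + weights$gamma * x[[3]]
}

# Jacobian of the fixed-regime vector field by central differences.
.lv_jacobian <- function(x, params, treatment_on) {
  f <- function(z) unlist(.lv_deriv(0, z, list(params = params, on = treatment_on)))
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    h <- 1e-6 * max(abs(x[j]), 1)
    up <- x; up[j] <- up[j] + h
    dn <- x; dn[j] <- dn[j] - h
    J[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' Untreated coexistence equilibrium
#'
#' Solves for the stable equilibrium of the off-treatment model: for every
#' cell type either `x_i = 0` or `sum_j a_ij x_j = K_i`, with the `T+`
#' capacity coupled to `TP` as `K_T+ = mu_off * x_TP` (which keeps the
#' system linear on every support). All seven non-empty supports are
#' enumerated, each feasible non-negative candidate is checked for local
#' stability via the eigenvalues of the Jacobian, and among stable
#' candidates the largest support is returned (a deterministic
#' tie-break). Patient response categories are defined from the `T-`
#' frequency at this equilibrium.
#'
#' For the solve, the `TP` and `T-` carrying capacities are both set to
#' `scale_K`; equilibria scale linearly in `scale_K`, so the `T-`
#' frequency used for classification is scale-free.
#'
#' @param params Model parameters ([model_params()]); only the competition
#'   matrix, growth rates and `mu_off` matter here.
#' @param scale_K Carrying capacity (cells) used for both `TP` and `T-`
#'   in the solve (> 0).
#' @return List with `populations` (named vector), `support` (character
#'   vector of the coexisting types), and `tminus_fraction` (the `T-`
#'   share of the total equilibrium population).
#' @examples
#' p <- model_params(A = competition_matrix("best_responder"))
#' untreated_equilibrium(p, scale_K = 1000)
#' @export
untreated_equilibrium <- function(params, scale_K = 1000) {
  if (!is.finite(scale_K) || scale_K <= 0) stop("scale_K must be > 0")
  A <- params$A
  mu <- params$mu_off
  solve_params <- model_params(
    r_tplus = params$r[[1]], r_tp = params$r[[2]], r_tminus = params$r[[3]],
    K_tp_off = scale_K, K_tp_on = params$K_tp_on, K_tminus = scale_K,
    mu_off = mu, mu_on = params$mu_on, A = A, K_floor = params$K_floor,
    decline_cap = params$decline_cap)

  supports <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L), 1:3)
  candidates <- list()
  for (S in supports) {
    M <- A[S, S, drop = FALSE]
    b <- c(0, scale_K, scale_K)[S]
    # K_T+ = mu * x_TP moves mu*x_tp to the left-hand side of the T+ row
    if (1L %in% S) {
      if (2L %in% S) {
        M[match(1L, S), match(2L, S)] <- M[match(1L, S), match(2L, S)] - mu
      }
      # without TP, K_T+ = 0 and the T+ row forces x_T+ <= 0: never feasible
      if (!(2L %in% S)) next
    }
    xS <- tryCatch(solve(M, b), error = function(e) NULL)
    if (is.null(xS)) next
    x <- numeric(3)
    x[S] <- xS
    if (any(x < -1e-9 * scale_K)) next
    x <- pmax(x, 0)
    if (any(x[S] <= 0)) next  # collapses onto a smaller support
    candidates[[length(candidates) + 1]] <- list(x = x, support = S)
  }
  if (length(candidates) == 0)
    stop("no feasible equilibrium: every support yields negative populations")

  stable <- Filter(function(cand) {
    J <- .lv_jacobian(cand$x, solve_params, treatment_on = FALSE)
    max(Re(eigen(J, only.values = TRUE)$values)) < 1e-8
  }, candidates)
  if (length(stable) == 0)
    warning("no locally stable equilibrium found; returning the largest feasible support")
  pool <- if (length(stable) > 0) stable else candidates
  sizes <- vapply(pool, function(cand) length(cand$support), integer(1))
  best <- pool[[which.max(sizes)]]

  x <- populations(best$x[1], best$x[2], best$x[3])
  list(populations = x,
       support = cell_types()[best$support],
       tminus_fraction = unname(x[3] / sum(x)))
}
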