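#' Model parameters for the three-type Lotka-Volterra competition model
#'
#' Bundles the growth rates, carrying capacities, treatment multipliers and
#' the competition matrix of the mCRPC model. Three cell types are tracked:
#' testosterone-dependent (`T+`), testosterone-producing (`TP`) and
#' testosterone-independent (`T-`). Abiraterone acts by lowering carrying
#' capacities: the `TP` capacity drops from `K_tp_off` to `K_tp_on`, and the
#' `T+` capacity, which is proportional to the current `TP` density
#' (`K_T+ = mu * x_TP`), has its multiplier reduced from `mu_off` to
#' `mu_on`. The resistant `T-` type keeps a fixed capacity.
#'
#' Default growth rates derive from doubling times of representative cell
#' lines (LNCaP for `T+`, H295R for `TP`, PC-3 for `T-`); time is measured
#' in days throughout (the `T+` doubling time is ln(2)/r ~ 250 days).
#'
#' @param r_tplus,r_tp,r_tminus Per-day intrinsic growth rates (> 0).
#' @param K_tp_off,K_tp_on `TP` carrying capacity (cells) without / under
#'   treatment.
#' @param K_tminus `T-` carrying capacity (cells), treatment-independent.
#' @param mu_off,mu_on Dimensionless multiplier linking the `T+` carrying
#'   capacity to the `TP` density, without / under treatment.
#' @param A 3x3 competition matrix; `A[i, j]` is the effect of type `j` on
#'   type `i`, rows/columns ordered (`T+`, `TP`, `T-`). Diagonal must be
#'   exactly 1; off-diagonals in (0, 1].
#' @param K_floor Lower bound (cells) applied to every carrying capacity
#'   inside the right-hand side, so that `K_T+ = mu * x_TP -> 0` does not
#'   produce a division by zero. With a positive `T+` population and the
#'   capacity at the floor the per-capita growth is strongly negative,
#'   i.e. `T+` cells die out rapidly without testosterone.
#' @param decline_cap Upper bound (per day) on the magnitude of the
#'   per-capita decline rate. With the capacity floored, the raw decline
#'   rate grows like `1 / K_floor` and its Lipschitz constant (~1e13/day)
#'   stalls any error-controlled integrator while a population underflows
#'   through the sub-cell range. The cap bounds that rate at a value that
#'   is still instantaneous extinction on the model's time scale (100/day
#'   halves a population every 10 minutes) and only engages once the
#'   coupled capacity `mu * x_TP` is below about one cell — far outside
#'   the regime where any reported quantity (TCR, PSA switching) is
#'   decided.
#'
#' @return An object of class `lv_params` (a validated list).
#' @examples
#' p <- model_params(A = competition_matrix("best_responder"))
#' p$r
#' @export
model_params <- function(r_tplus = 0.0027726,
                         r_tp = 0.0034657,
                         r_tminus = 0.0066542,
                         K_tp_off = 10000,
                         K_tp_on = 100,
                         K_tminus = 10000,
                         mu_off = 1.5,
                         mu_on = 0.5,
                         A,
                         K_floor = 1e-9,
                         decline_cap = 100) {
  r <- c(tplus = r_tplus, tp = r_tp, tminus = r_tminus)
  if (!all(is.finite(r)) || any(r <= 0))
    stop("invalid parameters: growth rates must be finite and > 0")
  K_fixed <- c(K_tp_off = K_tp_off, K_tp_on = K_tp_on, K_tminus = K_tminus)
  if (!all(is.finite(K_fixed)) || any(K_fixed <= 0))
    stop("invalid parameters: carrying capacities must be finite and > 0")
  if (!all(is.finite(c(mu_off, mu_on))) || mu_off <= 0 || mu_on <= 0)
    stop("invalid parameters: mu multipliers must be finite and > 0")
  A <- validate_competition_matrix(A)
  if (!is.finite(K_floor) || K_floor <= 0)
    stop("invalid parameters: K_floor must be finite and > 0")
  if (!is.finite(decline_cap) || decline_cap <= 0)
    stop("invalid parameters: decline_cap must be finite and > 0")
  structure(
    list(r = r, K_tp_off = K_tp_off, K_tp_on = K_tp_on,
         K_tminus = K_tminus, mu_off = mu_off, mu_on = mu_on,
         A = A, K_floor = K_floor, decline_cap = decline_cap),
    class = "lv_params"
  )
}

validate_competition_matrix <- function(A) {
  A <- as.matrix(A)
  if (!identical(dim(A), c(3L, 3L)) || !all(is.finite(A)))
    stop("invalid parameters: A must be a finite 3x3 matrix")
  if (!identical(unname(diag(A)), c(1, 1, 1)))
    stop("invalid parameters: diagonal of A must equal 1 exactly")
  off <- A[row(A) != col(A)]
  if (any(off <= 0) || any(off > 1))
    stop("invalid parameters: off-diagonal competition coefficients must lie in (0, 1]")
  dimnames(A) <- list(cell_types(), cell_types())
  A
}

cell_types <- function() c("T+", "TP", "T-")

#' Population state vector
#'
#' @param tplus,tp,tminus Cell counts (finite, >= 0) of the
#'   testosterone-dependent, testosterone-producing and
#'   testosterone-independent types.
#' @return Named numeric vector `c(x_tplus, x_tp, x_tminus)`.
#' @examples
#' populations(606.06, 757.58, 1.94e-10)
#' @export
populations <- function(tplus, tp, tminus) {
  x <- c(x_tplus = as.numeric(tplus), x_tp = as.numeric(tp),
         x_tminus = as.numeric(tminus))
  if (length(x) != 3 || !all(is.finite(x)) || any(x < 0))
    stop("populations must be three finite non-negative cell counts")
  x
}

as_populations <- function(x) {
  if (length(x) != 3) stop("expected three population components")
  populations(x[[1]], x[[2]], x[[3]])
}

#' PSA production weights
#'
#' The serum PSA level is modelled as a convex combination of the three
#' subpopulation sizes: `PSA = alpha * x_T+ + beta * x_TP +
#' (1 - alpha - beta) * x_T-`. The weights live on the simplex
#' `0 <= alpha <= 1`, `0 <= beta <= 1 - alpha`; the `T-` weight
#' `1 - alpha - beta` is implied.
#'
#' @param alpha PSA production weight of `T+` cells.
#' @param beta PSA production weight of `TP` cells.
#' @return An object of class `psa_weights`.
#' @examples
#' psa_weights(1, 0)        # only T+ cells produce PSA
#' psa_weights(1/3, 1/3)    # all types contribute equally
#' @export
psa_weights <- function(alpha, beta) {
  if (!is.finite(alpha) || !is.finite(beta))
    stop("invalid weights: alpha and beta must be finite")
  tol <- 1e-12
  if (alpha < -tol || alpha > 1 + tol || beta < -tol || beta > 1 - alpha + tol)
    stop("invalid weights: need 0 <= alpha <= 1 and 0 <= beta <= 1 - alpha")
  structure(list(alpha = min(max(alpha, 0), 1),
                 beta = min(max(beta, 0), 1 - alpha),
                 gamma = max(1 - alpha - beta, 0)),
            class = "psa_weights")
}

#' @export
print.psa_weights <- function(x, ...) {
  cat(sprintf("PSA weights: alpha = %g (T+), beta = %g (TP), 1-alpha-beta = %g (T-)\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' @export
print.lv_params <- function(x, ...) {
  cat("Lotka-Volterra mCRPC model parameters\n")
  cat(sprintf("  growth rates r (per day): T+ %g, TP %g, T- %g\n",
              x$r[1], x$r[2], x$r[3]))
  cat(sprintf("  K_TP: %g (off treatment) / %g (on treatment); K_T-: %g\n",
              x$K_tp_off, x$K_tp_on, x$K_tminus))
  cat(sprintf("  K_T+ = mu * x_TP with mu = %g (off) / %g (on)\n",
              x$mu_off, x$mu_on))
  cat("  competition matrix A:\n")
  print(x$A)
  invisible(x)
}
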