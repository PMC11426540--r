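#' Draw a random competition matrix
#'
#' Samples the six off-diagonal competition coefficients independently and
#' uniformly from the discrete set {0.4, 0.5, 0.6, 0.7, 0.8, 0.9} used to
#' construct the patient categories; the diagonal is fixed at 1. Uses the
#' current R random number generator state — call `set.seed()` (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @return A 3x3 competition matrix.
#' @examples
#' set.seed(1)
#' sample_competition_matrix()
#' @export
sample_competition_matrix <- function() {
  values <- seq(0.4, 0.9, by = 0.1)
  A <- diag(3)
  A[row(A) != col(A)] <- sample(values, 6, replace = TRUE)
  dimnames(A) <- list(cell_types(), cell_types())
  A
}

#' Classify a patient by the equilibrium frequency of resistant cells
#'
#' Response categories are defined by the `T-` share of the untreated
#' coexistence equilibrium: best responders have (numerically) no
#' resistant cells at equilibrium (frequency < 1e-6), non-responders have
#' a high resistant share (>= 20%), responders lie in between. The
#' frequency is scale-free, so the classification does not depend on the
#' carrying-capacity scale.
#'
#' @param A Competition matrix (3x3, unit diagonal).
#' @param params Optional [model_params()] supplying growth rates and
#'   `mu_off`; its competition matrix is replaced by `A`.
#' @return List with `category`, `tminus_fraction`, and `equilibrium`
#'   (the [untreated_equilibrium()] result).
#' @examples
#' classify_patient(competition_matrix("non_responder"))$category
#' @export
classify_patient <- function(A, params = NULL) {
  params <- if (is.null(params)) model_params(A = A) else
    model_params(r_tplus = params$r[[1]], r_tp = params$r[[2]],
                 r_tminus = params$r[[3]], K_tp_off = params$K_tp_off,
                 K_tp_on = params$K_tp_on, K_tminus = params$K_tminus,
                 mu_off = params$mu_off, mu_on = params$mu_on,
                 A = A, K_floor = params$K_floor,
                 decline_cap = params$decline_cap)
  eq <- untreated_equilibrium(params, scale_K = 1000)
  f <- eq$tminus_fraction
  category <- if (f < 1e-6) "best_responder"
              else if (f >= 0.20) "non_responder"
              else "responder"
  list(category = category, tminus_fraction = f, equilibrium = eq)
}

#' Generate a virtual patient cohort
#'
#' Emulates the construction of the representative patients at cohort
#' scale: each virtual patient gets a competition matrix sampled by
#' [sample_competition_matrix()], is classified by the `T-` frequency of
#' their untreated equilibrium, and starts therapy at a fixed fraction of
#' that equilibrium (default one tenth of the equilibrium at carrying
#' capacity `scale_K` = 10000, which reproduces the representative
#' initial conditions when the matrix is one of the three printed ones).
#'
#' @param n Number of patients (>= 1).
#' @param seed Integer seed; the cohort is fully reproducible.
#' @param init_fraction Fraction of the untreated equilibrium used as the
#'   initial condition, in (0, 1].
#' @param scale_K Carrying capacity (cells) for `TP` and `T-` at which the
#'   equilibrium is computed.
#' @return Data frame with one row per patient: `patient_id`, the six
#'   off-diagonal coefficients `a12`..`a32`, `category`,
#'   `eq_tminus_fraction`, `init_tplus`, `init_tp`, `init_tminus`, `seed`.
#' @examples
#' cohort <- generate_cohort(5, seed = 42)
#' table(cohort$category)
#' @export
generate_cohort <- function(n, seed, init_fraction = 0.1, scale_K = 10000) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(init_fraction) || init_fraction <= 0 || init_fraction > 1)
    stop("init_fraction must be in (0, 1]")
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    A <- sample_competition_matrix()
    cls <- classify_patient(A)
    eq <- untreated_equilibrium(model_params(A = A), scale_K = scale_K)
    init <- init_fraction * eq$populations
    data.frame(patient_id = i,
               a12 = A[1, 2], a13 = A[1, 3], a21 = A[2, 1],
               a23 = A[2, 3], a31 = A[3, 1], a32 = A[3, 2],
               category = cls$category,
               eq_tminus_fraction = cls$tminus_fraction,
               init_tplus = init[[1]], init_tp = init[[2]],
               init_tminus = init[[3]],
               seed = seed)
  })
  do.call(rbind, rows)
}

#' Competition matrix of a cohort row
#'
#' Rebuilds the 3x3 competition matrix from the off-diagonal columns of a
#' [generate_cohort()] row.
#'
#' @param row One-row data frame (or list) with `a12`, `a13`, `a21`,
#'   `a23`, `a31`, `a32`.
#' @return A 3x3 competition matrix.
#' @export
cohort_matrix <- function(row) {
  A <- matrix(c(1, row$a12, row$a13,
                row$a21, 1, row$a23,
                row$a31, row$a32, 1), 3, 3, byrow = TRUE)
  dimnames(A) <- list(cell_types(), cell_types())
  A
}

#' Sample a noisy PSA measurement series from a simulation
#'
#' Produces measurement-like PSA observations: the continuous PSA trace is
#' sampled on a regular grid and multiplied by lognormal noise with unit
#' mean and the requested coefficient of variation. With `noise_cv = 0`
#' the exact model PSA at the grid times is returned. The model itself is
#' deterministic; noise here emulates assay variability for testing
#' protocol logic against sampled rather than continuous PSA.
#'
#' @param result A `psa_simulation` from [run_simulation()].
#' @param sampling_interval Days between measurements (> 0).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @return Data frame with columns `time` and `psa_observed`.
#' @examples
#' pat <- representative_patient("non_responder")
#' sim <- run_simulation(pat$params, pat$init, "MTD", horizon = 200)
#' head(synthesize_psa_series(sim, sampling_interval = 30))
#' @export
synthesize_psa_series <- function(result, sampling_interval, noise_cv = 0) {
  if (!is.finite(sampling_interval) || sampling_interval <= 0)
    stop("sampling_interval must be > 0")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")
  grid <- seq(0, result$horizon, by = sampling_interval)
  psa <- stats::approx(result$times, result$psa_trace, xout = grid)$y
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    psa <- psa * stats::rlnorm(length(psa), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  data.frame(time = grid, psa_observed = psa)
}
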