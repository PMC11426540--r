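#' Compare adaptive therapy with continuous dosing for one patient
#'
#' Runs both protocols for a patient preset and one PSA-weight setting and
#' summarises the outcome as one comparison row. The adaptive-therapy TCR
#' is reported as `NA` when the protocol never discontinued treatment
#' before competitive release (AT not applicable). Improvements are
#' computed from the unrounded TCRs.
#'
#' @param preset A [representative_patient()] preset (or any list with
#'   `category`, `params`, `init`).
#' @param weights [psa_weights()].
#' @param horizon Simulation horizon in days.
#' @param ... Further arguments passed to [run_simulation()] (tolerances,
#'   `sample_dt`, `thresholds`).
#' @return One-row data frame: `category`, `alpha`, `beta`, `tcr_mtd`,
#'   `tcr_at`, `abs_improvement`, `pct_improvement`, `at_applicable`.
#' @examples
#' \donttest{
#' pat <- representative_patient("non_responder")
#' compare_protocols(pat, psa_weights(0, 1))
#' }
#' @export
compare_protocols <- function(preset, weights, horizon = 10000, ...) {
  mtd <- run_simulation(preset$params, preset$init, "MTD", weights,
                        horizon = horizon, ...)
  at <- run_simulation(preset$params, preset$init, "AT", weights,
                       horizon = horizon, ...)
  tcr_at <- if (at$at_applicable) at$tcr else NA_real_
  data.frame(category = preset$category,
             alpha = weights$alpha, beta = weights$beta,
             tcr_mtd = mtd$tcr,
             tcr_at = tcr_at,
             abs_improvement = tcr_at - mtd$tcr,
             pct_improvement = 100 * (tcr_at - mtd$tcr) / mtd$tcr,
             at_applicable = at$at_applicable)
}

#' Protocol comparison table for a patient category
#'
#' Iterates [compare_protocols()] over the four standard PSA-production
#' assumptions — only `T+` produces PSA (alpha = 1, beta = 0), only `TP`
#' (0, 1), equal contributions (1/3, 1/3), and only `T-` (0, 0) — giving
#' the standard comparison table for one patient category.
#'
#' @inheritParams compare_protocols
#' @param weight_settings List of [psa_weights()] to evaluate.
#' @return Data frame with one row per weight setting.
#' @examples
#' \donttest{
#' comparison_table(representative_patient("non_responder"))
#' }
#' @export
comparison_table <- function(preset,
                             weight_settings = list(psa_weights(1, 0),
                                                    psa_weights(0, 1),
                                                    psa_weights(1 / 3, 1 / 3),
                                                    psa_weights(0, 0)),
                             horizon = 10000, ...) {
  do.call(rbind, lapply(weight_settings, function(w)
    compare_protocols(preset, w, horizon = horizon, ...)))
}

#' Scan the PSA-weight simplex
#'
#' Evaluates the protocol comparison on a regular lattice over the
#' feasible weight simplex (`alpha`, `beta` multiples of `step` with
#' `alpha + beta <= 1`), the grid behind the TCR heatmaps. The MTD run
#' does not depend on the weights and is computed once.
#'
#' @inheritParams compare_protocols
#' @param step Grid spacing in (0, 0.5].
#' @param sample_dt Trajectory sampling interval passed to
#'   [run_simulation()]; the scan only needs events, so it defaults to
#'   the horizon.
#' @return Data frame with columns `alpha`, `beta`, `tcr_mtd`, `tcr_at`,
#'   `at_applicable`, `abs_improvement`, `pct_improvement`; one row per
#'   lattice point.
#' @examples
#' \donttest{
#' scan <- alpha_beta_scan(representative_patient("non_responder"), step = 0.5)
#' }
#' @export
alpha_beta_scan <- function(preset, step = 0.05, horizon = 10000,
                            sample_dt = horizon, ...) {
  if (!is.finite(step) || step <= 0 || step > 0.5)
    stop("step must be in (0, 0.5]")
  vals <- seq(0, 1, by = step)
  grid <- expand.grid(alpha = vals, beta = vals)
  grid <- grid[grid$alpha + grid$beta <= 1 + 1e-9, ]
  mtd <- run_simulation(preset$params, preset$init, "MTD",
                        horizon = horizon, sample_dt = sample_dt, ...)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    w <- psa_weights(grid$alpha[i], grid$beta[i])
    at <- run_simulation(preset$params, preset$init, "AT", w,
                         horizon = horizon, sample_dt = sample_dt, ...)
    tcr_at <- if (at$at_applicable) at$tcr else NA_real_
    data.frame(alpha = w$alpha, beta = w$beta,
               tcr_mtd = mtd$tcr, tcr_at = tcr_at,
               at_applicable = at$at_applicable,
               abs_improvement = tcr_at - mtd$tcr,
               pct_improvement = 100 * (tcr_at - mtd$tcr) / mtd$tcr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
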