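#' Representative competition matrices
#'
#' The three representative competition matrices used for the patient
#' response categories. Rows/columns are ordered (`T+`, `TP`, `T-`);
#' entry `A[i, j]` is the competitive effect of type `j` on type `i`.
#'
#' @param category One of `"best_responder"`, `"responder"`,
#'   `"non_responder"`.
#' @return A 3x3 numeric matrix with unit diagonal.
#' @examples
#' competition_matrix("non_responder")
#' @export
competition_matrix <- function(category = c("best_responder", "responder",
                                            "non_responder")) {
  category <- match.arg(category)
  A <- switch(category,
    best_responder = matrix(c(1.0, 0.7, 0.8,
                              0.4, 1.0, 0.5,
                              0.6, 0.9, 1.0), 3, 3, byrow = TRUE),
    responder      = matrix(c(1.0, 0.7, 0.8,
                              0.4, 1.0, 0.6,
                              0.5, 0.9, 1.0), 3, 3, byrow = TRUE),
    non_responder  = matrix(c(1.0, 0.7, 0.9,
                              0.4, 1.0, 0.6,
                              0.5, 0.8, 1.0), 3, 3, byrow = TRUE))
  dimnames(A) <- list(cell_types(), cell_types())
  A
}

#' Representative patient presets
#'
#' The three representative virtual patients: a category-specific
#' competition matrix together with the standard initial cell counts.
#' The initial conditions coincide with one tenth of the untreated
#' equilibrium at carrying capacity 10000 (equivalently, the equilibrium
#' at capacity 1000), so therapy starts from a tumor in its
#' pre-treatment composition at a tenth of its steady-state burden.
#'
#' @inheritParams competition_matrix
#' @return Object of class `patient_preset`: list with `category`, `A`
#'   (competition matrix), `init` (initial [populations()]), and `params`
#'   (the default [model_params()] carrying that matrix).
#' @examples
#' representative_patient("responder")$init
#' @export
representative_patient <- function(category = c("best_responder", "responder",
                                                "non_responder")) {
  category <- match.arg(category)
  init <- switch(category,
    best_responder = populations(606.06, 757.58, 1.94e-10),
    responder      = populations(560.36, 747.59, 47.10),
    non_responder  = populations(319.63, 707.76, 273.97))
  A <- competition_matrix(category)
  structure(list(category = category, A = A, init = init,
                 params = model_params(A = A)),
            class = "patient_preset")
}

#' @export
print.patient_preset <- function(x, ...) {
  cat(sprintf("Representative patient: %s\n", x$category))
  cat(sprintf("  initial cells: T+ %g, TP %g, T- %g\n",
              x$init[1], x$init[2], x$init[3]))
  cat("  competition matrix:\n")
  print(x$A)
  invisible(x)
}
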