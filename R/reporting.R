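#' Validated run configuration
#'
#' Collects every knob of a simulation or scan run into one validated
#' object, so the analysis drivers fail before any computation starts.
#' Validation reuses the constructors of the underlying types
#' ([model_params()], [populations()], [psa_weights()]).
#'
#' @param category Patient category (see [representative_patient()]), or
#'   `NULL` when `A` and `init` are given explicitly.
#' @param A,init Explicit competition matrix and initial populations
#'   (ignored when `category` is set).
#' @param alpha,beta PSA production weights.
#' @param protocol `"MTD"` or `"AT"`.
#' @param horizon Simulation horizon (days).
#' @param rtol,atol Solver tolerances.
#' @param step Simplex scan spacing.
#' @param n,seed Cohort size and seed.
#' @param init_fraction Cohort initial-condition fraction.
#' @param outdir Output directory for the writers.
#' @return Object of class `run_config`.
#' @export
run_config <- function(category = NULL, A = NULL, init = NULL,
                       alpha = 1 / 3, beta = 1 / 3,
                       protocol = c("MTD", "AT"),
                       horizon = 10000, rtol = 1e-8, atol = 1e-12,
                       step = 0.05, n = 100, seed = 1,
                       init_fraction = 0.1, outdir = "results") {
  protocol <- match.arg(protocol)
  if (!is.null(category)) {
    preset <- representative_patient(category)
    A <- preset$A
    init <- preset$init
  } else {
    if (is.null(A) || is.null(init))
      stop("either category or both A and init must be given")
    A <- validate_competition_matrix(A)
    init <- as_populations(init)
  }
  psa_weights(alpha, beta)  # validation only
  if (!is.finite(horizon) || horizon <= 0) stop("invalid horizon: must be > 0")
  if (!is.finite(step) || step <= 0 || step > 0.5) stop("step must be in (0, 0.5]")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.finite(init_fraction) || init_fraction <= 0 || init_fraction > 1)
    stop("init_fraction must be in (0, 1]")
  structure(list(category = category, A = A, init = init,
                 alpha = alpha, beta = beta, protocol = protocol,
                 horizon = horizon, rtol = rtol, atol = atol, step = step,
                 n = as.integer(n), seed = as.integer(seed),
                 init_fraction = init_fraction, outdir = outdir),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' Round-trips a [run_config()] through a flat YAML file; reading
#' revalidates through the constructor.
#'
#' @param config A `run_config`.
#' @param path File path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  lst <- unclass(config)
  lst$A <- as.vector(t(config$A))
  lst$init <- as.vector(config$init)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  lst$A <- if (is.null(lst$A)) NULL else matrix(unlist(lst$A), 3, 3, byrow = TRUE)
  lst$init <- if (is.null(lst$init)) NULL else unlist(lst$init)
  if (!is.null(lst$category)) { lst$A <- NULL; lst$init <- NULL }
  do.call(run_config, lst)
}

#' Export a simulation as CSV plus JSON summary
#'
#' Writes the sampled trajectory as a CSV (columns `time`, `x_tplus`,
#' `x_tp`, `x_tminus`, `psa`, `treatment_on`, numbers at 6 significant
#' digits) and a JSON sidecar (`<path>.json`, full precision) with the
#' scalar outcomes: TCR, switch times, applicability flag, baseline PSA.
#'
#' @param result A `psa_simulation` from [run_simulation()].
#' @param path CSV file path; the sidecar replaces the extension by
#'   `.json`.
#' @return Invisibly, the two paths written.
#' @export
write_trajectory <- function(result, path) {
  df <- data.frame(time = result$times,
                   result$trajectory,
                   psa = result$psa_trace,
                   treatment_on = result$treatment_on)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.[^.]*$", ".json", path)
  jsonlite::write_json(
    list(protocol = result$therapy$protocol,
         baseline_psa = result$therapy$baseline_psa,
         tcr = if (is.na(result$tcr)) NULL else result$tcr,
         switch_times = result$therapy$switch_times,
         at_applicable = result$at_applicable,
         horizon = result$horizon,
         alpha = result$weights$alpha, beta = result$weights$beta),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv = path, json = side))
}

#' Write an analysis table as CSV
#'
#' Shared writer for comparison tables, simplex scans and cohorts:
#' numeric columns at 6 significant digits, `NA` cells left empty.
#'
#' @param df Data frame.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
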