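#' Treatment protocols
#'
#' Two treatment controllers are supported:
#'
#' * `"MTD"` — continuous maximum tolerable dose: treatment is on for the
#'   whole simulation; PSA is never consulted.
#' * `"AT"` — PSA-guided adaptive therapy: treatment starts on, is
#'   discontinued when PSA falls to half of its baseline (PSA at t = 0)
#'   and readministered when PSA recovers to baseline, cycling with
#'   hysteresis. The 0.5/1.0 thresholds can be overridden via the
#'   `thresholds` argument of [run_simulation()].
#'
#' @name protocols
NULL

#' Initial treatment state of a protocol
#'
#' Both protocols begin with treatment active at t = 0 (patients enter
#' after responding to initial dosing); baseline PSA is the PSA level at
#' t = 0.
#'
#' @param protocol `"MTD"` or `"AT"`.
#' @return `"on"`.
#' @export
initial_state <- function(protocol = c("MTD", "AT")) {
  match.arg(protocol)
  "on"
}

#' Switching threshold function for a protocol state
#'
#' Returns the event function whose zero-crossing triggers a treatment
#' switch: under AT with treatment on, the event is
#' `PSA(t) - lower * baseline` (crossed from above, i.e. PSA dropping to
#' the lower threshold); with treatment off it is
#' `PSA(t) - upper * baseline` (crossed from below, PSA recovering). The
#' hysteresis makes the crossing direction automatic: after switching
#' off at the lower threshold, the active event function jumps to the
#' upper threshold, so no event re-fires at the switch point. MTD returns
#' a never-firing event.
#'
#' @param protocol `"MTD"` or `"AT"`.
#' @param current_state `"on"` or `"off"`.
#' @param baseline_psa PSA at t = 0 (must be > 0 for AT).
#' @param weights [psa_weights()] used to evaluate PSA.
#' @param thresholds Numeric `c(lower, upper)` as fractions of baseline.
#' @return Function of the population vector returning the event value.
#' @export
switching_event <- function(protocol = c("MTD", "AT"),
                            current_state = c("on", "off"),
                            baseline_psa, weights,
                            thresholds = c(lower = 0.5, upper = 1)) {
  protocol <- match.arg(protocol)
  current_state <- match.arg(current_state)
  if (protocol == "MTD") return(function(x) 1)
  if (!is.finite(baseline_psa) || baseline_psa <= 0)
    stop("degenerate baseline: adaptive therapy needs baseline PSA > 0")
  target <- if (current_state == "on") thresholds[[1]] * baseline_psa
            else thresholds[[2]] * baseline_psa
  function(x) psa_level(x, weights) - target
}

#' Was adaptive therapy actually applied?
#'
#' By convention a run counts as adaptive therapy only if treatment was
#' discontinued at least once before competitive release: at least one
#' on-to-off switch strictly before the time to competitive release (if
#' one occurred) or before the horizon (if not). Runs where PSA never
#' falls to half its baseline before the resistant clone takes over are
#' reported as AT-not-applicable.
#'
#' @param record Therapy record from [run_simulation()] (list with
#'   `protocol` and `switch_times`, a data frame of `time`/`state`).
#' @param tcr Time to competitive release, or `NA` if none.
#' @param horizon Simulation horizon (days).
#' @return Logical flag.
#' @export
at_applicable <- function(record, tcr, horizon) {
  if (!identical(record$protocol, "AT")) return(FALSE)
  sw <- record$switch_times
  if (is.null(sw) || nrow(sw) == 0) return(FALSE)
  off <- sw$time[sw$state == "off"]
  limit <- if (is.na(tcr)) horizon else tcr
  any(off < limit)
}
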