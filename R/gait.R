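#' Gait spatiotemporal parameters and their variability
#'
#' Computes per-trial stance time, swing time and cadence, with their
#' step-to-step percent coefficients of variation (CV = 100 * sd / mean,
#' sample standard deviation). Cycle durations come from consecutive
#' touchdowns of the recorded limb, so the last listed cycle (without a
#' following touchdown) is dropped; swing is the cycle duration minus
#' stance; cadence assumes symmetric stepping, two steps per single-limb
#' gait cycle: cadence_i = 120 / duration_i steps/min.
#'
#' @param events a \code{\link{gait_cycle_times}} with >= 2 cycles.
#' @return A `gait_summary` list: `stance_mean`, `swing_mean`,
#'   `cadence_mean` (s, s, steps/min), `stance_cv`, `swing_cv`,
#'   `cadence_cv` (percent), `n_cycles`, and the per-cycle series
#'   `stance`, `swing`, `cadence`.
#' @export
gait_summary <- function(events) {
  td <- events$touchdown
  st <- events$stance_duration
  n <- length(td)
  if (n < 2) stop("need at least 2 cycles")
  if (any(diff(td) <= 0)) stop("touchdown times must strictly increase")
  dur <- diff(td)
  stance <- st[-n]
  if (any(stance >= dur)) stop("stance must be shorter than the cycle")
  swing <- dur - stance
  cadence <- 120 / dur
  cv <- function(x) if (mean(x) == 0) NA_real_ else 100 * sd(x) / mean(x)
  structure(list(
    stance_mean = mean(stance), swing_mean = mean(swing),
    cadence_mean = mean(cadence),
    stance_cv = cv(stance), swing_cv = cv(swing), cadence_cv = cv(cadence),
    n_cycles = n - 1,
    stance = stance, swing = swing, cadence = cadence),
    class = "gait_summary")
}
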