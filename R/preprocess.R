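#' EMG linear envelope
#'
#' Classical linear-envelope chain, per channel: zero-phase Butterworth
#' high-pass, full-wave rectification, zero-phase Butterworth low-pass. The
#' filters are designed at `design_order` and applied forward-backward
#' (zero-phase), which doubles the effective order: the default 2nd-order
#' design yields the conventional 4th-order effective response of
#' movement-science envelope pipelines.
#'
#' @param raw an \code{\link{emg_recording}}.
#' @param hp_cutoff high-pass cut-off, Hz (default 50).
#' @param lp_cutoff low-pass cut-off, Hz (default 20).
#' @param design_order Butterworth design order before forward-backward
#'   application (default 2).
#' @return An `envelope_matrix` list: `values` (13 x n, non-negative), `fs`,
#'   `meta`.
#' @export
emg_envelope <- function(raw, hp_cutoff = 50, lp_cutoff = 20,
                         design_order = 2L) {
  stopifnot(inherits(raw, "emg_recording"))
  if (raw$fs <= 2 * hp_cutoff) stop("sampling rate too low for hp_cutoff")
  if (anyNA(raw$samples)) stop("NaN/NA in EMG samples")
  hp <- signal::butter(design_order, hp_cutoff / (raw$fs / 2), type = "high")
  lp <- signal::butter(design_order, lp_cutoff / (raw$fs / 2), type = "low")
  env <- raw$samples
  for (m in seq_len(nrow(env))) {
    x <- signal::filtfilt(hp, env[m, ])
    x <- abs(x)
    env[m, ] <- signal::filtfilt(lp, x)
  }
  env <- pmax(env, 0)  # zero-phase low-pass can undershoot slightly
  structure(list(values = env, fs = raw$fs, meta = raw$meta),
            class = "envelope_matrix")
}

#' Per-muscle amplitude normalization
#'
#' For every channel, subtracts the channel minimum and divides by the
#' resulting channel maximum, so each muscle's envelope spans [0, 1] within
#' the trial. Constant channels map to all zeros with a warning.
#'
#' @param env an `envelope_matrix`.
#' @return The normalized `envelope_matrix`.
#' @export
normalize_amplitude <- function(env) {
  stopifnot(inherits(env, "envelope_matrix"))
  v <- env$values
  for (m in seq_len(nrow(v))) {
    x <- v[m, ] - min(v[m, ])
    mx <- max(x)
    if (mx == 0) {
      warning("channel ", rownames(v)[m] %||% m,
              " is constant; normalized to all zeros")
      v[m, ] <- 0
    } else {
      v[m, ] <- x / mx
    }
  }
  env$values <- v
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Time-normalize envelopes onto the gait cycle
#'
#' Resamples each gait cycle to 200 points by linear interpolation: 100
#' points for the stance phase and 100 for the swing phase, so results are
#' comparable across cycles and participants regardless of absolute phase
#' durations. Phases are half-open: stance covers [touchdown, lift-off) and
#' swing [lift-off, next touchdown). At most `max_cycles` cycles (the first
#' 30 by default) are kept. The last listed cycle has no following touchdown;
#' its end boundary is estimated as its touchdown plus the median cycle
#' duration and the cycle is dropped if the recording ends first.
#'
#' @param env an `envelope_matrix` (typically amplitude-normalized).
#' @param events a \code{\link{gait_cycle_times}}.
#' @param max_cycles maximum number of cycles to keep (default 30).
#' @param points_per_phase points per phase (default 100).
#' @return A `normalized_cycles` list: `values` (13 x 200*n_cycles),
#'   `n_cycles`, `stance_points`, `swing_points`, `meta`.
#' @export
time_normalize <- function(env, events, max_cycles = 30L,
                           points_per_phase = 100L) {
  stopifnot(inherits(env, "envelope_matrix"))
  n_samp <- ncol(env$values)
  t_end <- (n_samp - 1) / env$fs
  td <- events$touchdown
  st <- events$stance_duration
  n_ev <- length(td)
  if (n_ev < 2) stop("fewer than 2 cycles")
  # per-cycle end boundaries; the last one is estimated
  ends <- c(td[-1], td[n_ev] + median(diff(td)))
  keep <- which(ends <= t_end + 1e-9)
  if (td[1] < -1e-9) stop("cycle boundary outside recording")
  keep <- keep[seq_len(min(length(keep), max_cycles))]
  if (length(keep) < 1) stop("no complete cycle inside the recording")

  q <- points_per_phase
  t_grid <- (seq_len(n_samp) - 1) / env$fs
  out <- matrix(0, nrow(env$values), 2 * q * length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    lo <- td[i] + st[i]
    if (lo >= ends[i]) stop("stance extends beyond cycle ", i)
    stance_t <- td[i] + (0:(q - 1)) / q * st[i]
    swing_t <- lo + (0:(q - 1)) / q * (ends[i] - lo)
    cols <- (j - 1) * 2 * q + seq_len(2 * q)
    for (m in seq_len(nrow(out))) {
      out[m, cols] <- approx(t_grid, env$values[m, ],
                             xout = c(stance_t, swing_t), rule = 2)$y
    }
  }
  rownames(out) <- rownames(env$values)
  structure(list(values = out, n_cycles = length(keep),
                 stance_points = q, swing_points = q, meta = env$meta),
            class = "normalized_cycles")
}
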