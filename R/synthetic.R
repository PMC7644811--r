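#' Generate gait-cycle event times
#'
#' Draws per-cycle gait events (touchdown time and stance duration) with a
#' specified mean and step-to-step coefficient of variation, emulating the
#' cycle-breakdown tables that accompany recorded trials (one row per gait
#' cycle: incremental touchdown time in seconds, stance duration in seconds).
#'
#' Cycle durations and stance durations are drawn independently as Gaussians
#' with the requested mean and CV; stance is clamped into (5%, 95%) of its
#' cycle's duration so the stance < cycle invariant always holds.
#'
#' @param n_cycles number of gait cycles (>= 2).
#' @param stance_mean mean stance duration in seconds.
#' @param stance_cv step-to-step coefficient of variation of stance, percent.
#' @param cycle_mean mean full-cycle duration in seconds.
#' @param cycle_cv step-to-step coefficient of variation of cycle duration,
#'   percent.
#' @param seed integer seed; the draw is bit-reproducible for a fixed seed.
#' @return A `gait_cycle_times` data frame with columns `touchdown`
#'   (strictly increasing, starting at 0) and `stance_duration`.
#' @export
generate_cycle_times <- function(n_cycles, stance_mean, stance_cv,
                                 cycle_mean, cycle_cv, seed = 1L) {
  set.seed(seed)
  .gen_cycles(n_cycles, stance_mean, stance_cv, cycle_mean, cycle_cv)$events
}

# internal: also returns the drawn per-cycle durations (the last cycle's
# duration is not recoverable from touchdowns alone)
.gen_cycles <- function(n_cycles, stance_mean, stance_cv,
                        cycle_mean, cycle_cv) {
  if (n_cycles < 2) stop("n_cycles must be at least 2")
  if (stance_mean <= 0 || cycle_mean <= 0) stop("durations must be positive")
  if (stance_mean >= cycle_mean) {
    stop("stance_mean must be smaller than cycle_mean")
  }
  dur <- rnorm(n_cycles, cycle_mean, cycle_mean * cycle_cv / 100)
  dur <- pmax(dur, 0.2 * cycle_mean)
  stance <- rnorm(n_cycles, stance_mean, stance_mean * stance_cv / 100)
  stance <- pmin(pmax(stance, 0.05 * dur), 0.95 * dur)
  touchdown <- cumsum(c(0, dur[-n_cycles]))
  list(events = gait_cycle_times(touchdown, stance), durations = dur)
}

#' Generate fractional Gaussian noise
#'
#' Exact simulation of stationary fractional Gaussian noise (fGn) with Hurst
#' parameter `h_true` by circulant embedding of the fGn autocovariance
#' (Davies-Harte construction). Used as the calibration input for the
#' rescaled-range Hurst estimator: `h_true = 0.5` is white noise,
#' `h_true > 0.5` persistent, `h_true < 0.5` anti-persistent.
#'
#' @param h_true Hurst parameter, strictly inside (0, 1).
#' @param n series length (>= 16).
#' @param seed integer seed.
#' @return Numeric vector of length `n` with unit marginal variance.
#' @export
generate_fgn <- function(h_true, n, seed = 1L) {
  if (h_true <= 0 || h_true >= 1) stop("h_true must lie strictly in (0, 1)")
  if (n < 16) stop("n too small")
  set.seed(seed)
  # fGn autocovariance gamma(k) = 0.5 (|k+1|^2H - 2|k|^2H + |k-1|^2H)
  k <- 0:n
  g <- 0.5 * ((k + 1)^(2 * h_true) - 2 * k^(2 * h_true) +
                abs(k - 1)^(2 * h_true))
  row1 <- c(g, g[n:2])                      # circulant first row, length 2n
  lambda <- Re(fft(row1))
  lambda[lambda < 0 & lambda > -1e-8] <- 0  # clip fft round-off
  if (any(lambda < 0)) stop("circulant embedding not non-negative definite")
  m <- 2 * n
  z <- rnorm(m)
  a <- complex(length.out = m)
  a[1] <- sqrt(lambda[1] / m) * z[1]
  a[n + 1] <- sqrt(lambda[n + 1] / m) * z[2]
  idx <- seq_len(n - 1)
  a[idx + 1] <- sqrt(lambda[idx + 1] / (2 * m)) *
    complex(real = z[2 * idx + 1], imaginary = z[2 * idx + 2])
  a[m + 1 - idx] <- Conj(a[idx + 1])
  Re(fft(a))[seq_len(n)]
}

# wrapped-Gaussian motor primitive bells: circular in the 200-point cycle so
# late-swing activity wraps into the next cycle's start
.wrapped_bell <- function(peak, sigma, p = 200L) {
  t <- 0:(p - 1)
  d <- ((t - peak + p / 2) %% p) - p / 2
  exp(-d^2 / (2 * sigma^2))
}

# physiological module templates for the four fundamental synergies
# (weight acceptance, propulsion, early swing, late swing), canonical
# muscle order ME MA FL RF VM VL ST BF TA PL GM GL SO
.module_templates <- function() {
  cbind(
    weight_acceptance = c(0.80, 0.70, 0.50, 0.60, 1.00, 0.90, 0.10, 0.15,
                          0.20, 0.20, 0.15, 0.10, 0.15),
    propulsion        = c(0.10, 0.10, 0.25, 0.15, 0.10, 0.10, 0.10, 0.15,
                          0.05, 0.80, 1.00, 0.90, 0.95),
    early_swing       = c(0.15, 0.10, 0.30, 0.50, 0.20, 0.20, 0.10, 0.10,
                          1.00, 0.30, 0.05, 0.05, 0.05),
    late_swing        = c(0.30, 0.35, 0.20, 0.15, 0.10, 0.10, 1.00, 0.90,
                          0.60, 0.20, 0.10, 0.10, 0.10))
}

#' Generate a ground-truth synthetic locomotion trial
#'
#' Builds a complete synthetic trial: non-negative ground-truth motor modules
#' and wrapped-Gaussian motor primitives, cycle-normalized envelopes with
#' additive truncated-Gaussian noise, gait events with realistic step-to-step
#' variability, and a raw-like 13-channel EMG signal at `fs` Hz obtained by
#' amplitude-modulating a band-limited (10-500 Hz) Gaussian carrier with each
#' muscle's envelope. For `r = 4` the modules follow physiological templates
#' for the four fundamental locomotor synergies (weight acceptance,
#' propulsion, early swing, late swing) with peaks at cycle points 25, 75,
#' 125, 175; for other ranks, random unit-max modules and evenly spaced peaks
#' are drawn.
#'
#' @param r number of ground-truth synergies, 1-12.
#' @param n_cycles number of gait cycles (>= 2).
#' @param noise_sd envelope noise standard deviation as a fraction of the
#'   noiseless envelope maximum; the noisy envelope is clipped at zero.
#' @param jitter_sd per-cycle jitter of each primitive's peak phase, in
#'   normalized cycle points.
#' @param seed integer seed; bundles are bit-reproducible for a fixed seed.
#' @param fs sampling rate of the raw-like signal, Hz.
#' @param stance_mean,stance_cv,cycle_mean,cycle_cv gait-event parameters
#'   passed to the cycle generator (seconds / percent CV).
#' @param width standard deviation of the primitive bells, in cycle points.
#' @param peaks optional vector of r peak phases in cycle points (0-based,
#'   0-200); defaults to 25, 75, 125, 175 for `r = 4` and evenly spaced
#'   otherwise.
#' @return A `synthetic_trial` list with elements `raw` (an
#'   \code{emg_recording}), `events` (a \code{gait_cycle_times}),
#'   `envelopes` (13 x 200*n_cycles noisy envelope matrix), `truth`
#'   (modules_true, primitives_true, peak_phases, widths, jitter_sd),
#'   `noise_sd` and `seed`.
#' @export
generate_trial <- function(r = 4L, n_cycles = 30L, noise_sd = 0.05,
                           jitter_sd = 3, seed = 1L, fs = 2000,
                           stance_mean = 0.6, stance_cv = 3,
                           cycle_mean = 1.0, cycle_cv = 2,
                           width = 12, peaks = NULL) {
  if (r < 1 || r > 12) stop("r must lie in [1, 12]")
  if (n_cycles < 2) stop("n_cycles must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set.seed(seed)

  cyc <- .gen_cycles(n_cycles, stance_mean, stance_cv, cycle_mean, cycle_cv)
  events <- cyc$events
  dur <- cyc$durations

  p <- 200L
  if (r == 4L) {
    modules <- .module_templates() +
      matrix(runif(13 * 4, 0, 0.05), 13, 4)
    if (is.null(peaks)) peaks <- c(25, 75, 125, 175)
  } else {
    modules <- matrix(runif(13 * r)^2, 13, r)
    if (is.null(peaks)) peaks <- (p / r) * (seq_len(r) - 0.5)
  }
  stopifnot(length(peaks) == r)
  modules <- pmax(modules, 0)
  modules <- sweep(modules, 2, apply(modules, 2, max), "/")
  rownames(modules) <- muscle_labels()

  widths <- rep(width, r)
  primitives <- matrix(0, r, p * n_cycles)
  peak_phases <- matrix(0, r, n_cycles)
  for (i in seq_len(r)) {
    for (c in seq_len(n_cycles)) {
      pk <- peaks[i] + if (jitter_sd > 0) rnorm(1, 0, jitter_sd) else 0
      peak_phases[i, c] <- pk %% p
      primitives[i, (c - 1) * p + seq_len(p)] <-
        .wrapped_bell(peak_phases[i, c], widths[i], p)
    }
  }

  v_true <- modules %*% primitives
  env <- v_true
  if (noise_sd > 0) {
    env <- pmax(v_true + matrix(rnorm(length(v_true), 0,
                                      noise_sd * max(v_true)),
                                nrow(v_true)), 0)
  }

  # raw-like signal: band-limited carrier amplitude-modulated by the envelope
  total_time <- sum(dur)
  n_samp <- round(total_time * fs)
  t_samp <- (seq_len(n_samp) - 1) / fs
  # envelope support times: 100 stance + 100 swing points per cycle
  env_t <- numeric(p * n_cycles)
  for (c in seq_len(n_cycles)) {
    td <- events$touchdown[c]
    st <- events$stance_duration[c]
    sw <- dur[c] - st
    env_t[(c - 1) * p + seq_len(p)] <-
      c(td + (0:99) / 100 * st, td + st + (0:99) / 100 * sw)
  }
  bp <- signal::butter(4, c(10, 500) / (fs / 2), type = "pass")
  raw <- matrix(0, 13, n_samp)
  for (m in seq_len(13)) {
    carrier <- signal::filtfilt(bp, rnorm(n_samp))
    carrier <- carrier / sqrt(mean(carrier^2))
    amp <- approx(env_t, env[m, ], xout = t_samp, rule = 2)$y
    raw[m, ] <- carrier * amp
  }

  meta <- trial_meta(participant_code = sprintf("S%04d", seed %% 10000L),
                    locomotion = "W", environment = "O",
                    speed = 1.4)
  structure(list(
    raw = emg_recording(raw, fs = fs, meta = meta),
    events = events,
    envelopes = env,
    truth = list(modules_true = modules, primitives_true = primitives,
                 peak_phases = peak_phases, widths = widths,
                 jitter_sd = jitter_sd),
    noise_sd = noise_sd,
    seed = seed), class = "synthetic_trial")
}
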