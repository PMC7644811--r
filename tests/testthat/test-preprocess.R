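make_rec <- function(x, fs = 2000) {
  emg_recording(matrix(rep(x, each = 13), 13, byrow = FALSE), fs = fs)
}

test_that("an all-zero channel stays all zero through the envelope chain", {
  rec <- make_rec(numeric(2000))
  env <- emg_envelope(rec)
  expect_true(all(env$values == 0))
})

test_that("a 100 Hz sinusoid yields a flat envelope at the rectified mean", {
  rec <- make_rec(sin(2 * pi * 100 * (0:3999) / 2000))
  env <- emg_envelope(rec)
  mid <- env$values[1, 500:3500]
  # zero-phase gain of the 2nd-order high-pass at 100 Hz is |H|^2;
  # rectified mean of a unit sinusoid is 2/pi; the 20 Hz low-pass keeps DC
  level <- 2 / pi * (1 / (1 + (50 / 100)^4))
  expect_equal(mean(mid), level, tolerance = 0.02)
  expect_lt((max(mid) - min(mid)) / mean(mid), 0.05)
})

test_that("the envelope chain matches an independent implementation", {
  set.seed(10)
  tr <- generate_trial(r = 4, n_cycles = 3, noise_sd = 0.05, seed = 10)
  x <- tr$raw$samples[1:3, 1:4000, drop = FALSE]
  rec <- emg_recording(rbind(x, matrix(0, 10, 4000)), fs = 2000)
  env <- emg_envelope(rec)
  for (m in 1:3) {
    ref <- envelope_ref(x[m, ], fs = 2000)
    rmse <- sqrt(mean((env$values[m, ] - ref)^2))
    expect_lt(rmse, 1e-9)
  }
})

test_that("amplitude normalization is affine, warned when degenerate, and idempotent", {
  env <- structure(list(values = rbind(c(2, 4, 6),
                                       matrix(runif(36), 12, 3)),
                        fs = 2000, meta = trial_meta()),
                   class = "envelope_matrix")
  out <- normalize_amplitude(env)
  expect_equal(out$values[1, ], c(0, 0.5, 1))
  expect_true(all(apply(out$values, 1, min) == 0))
  expect_true(all(apply(out$values, 1, max) == 1))
  # idempotence
  out2 <- normalize_amplitude(out)
  expect_equal(out2$values, out$values)
  # constant channel -> zeros with a warning
  env$values[1, ] <- 3
  expect_warning(outc <- normalize_amplitude(env), "constant")
  expect_equal(outc$values[1, ], c(0, 0, 0))
})

test_that("time normalization resamples stance and swing to 100 points each", {
  fs <- 2000
  n <- 8000  # 4 s
  ramp <- (0:(n - 1)) / (n - 1)
  env <- structure(list(values = matrix(rep(ramp, each = 13), 13,
                                        byrow = FALSE),
                        fs = fs, meta = trial_meta()),
                   class = "envelope_matrix")
  ev <- gait_cycle_times(c(0, 1, 2, 3), rep(0.6, 4))
  nc <- time_normalize(env, ev)
  expect_equal(ncol(nc$values), 200 * 3)  # last cycle end at 4 s = t_end
  # a linear ramp stays a linear ramp on each phase grid
  stance1 <- nc$values[1, 1:100]
  expect_equal(stance1, seq(stance1[1], stance1[100], length.out = 100),
               tolerance = 1e-9)
  expect_equal(stance1[1], ramp[1])
  # stance occupies the first 100 points: value at point 101 jumps to the
  # lift-off sample of the same cycle
  expect_gt(nc$values[1, 101], nc$values[1, 100])
})

test_that("cycle counts beyond 30 are truncated; short trials accepted", {
  fs <- 200
  mk_env <- function(n_cycles) {
    n <- (n_cycles + 1) * fs  # 1 s cycles, one spare second
    structure(list(values = matrix(runif(13 * n), 13), fs = fs,
                   meta = trial_meta()),
              class = "envelope_matrix")
  }
  ev35 <- gait_cycle_times(0:34, rep(0.6, 35))
  out35 <- time_normalize(mk_env(35), ev35)
  expect_equal(ncol(out35$values), 6000L)
  expect_equal(out35$n_cycles, 30L)

  ev21 <- gait_cycle_times(0:20, rep(0.6, 21))
  out21 <- time_normalize(mk_env(21), ev21)
  expect_equal(ncol(out21$values), 4200L)

  short <- gait_cycle_times(0, 0.6)
  expect_error(time_normalize(mk_env(2), short), "fewer than 2")
})

test_that("time normalization preserves the range of slow envelopes", {
  fs <- 2000
  t <- (0:7999) / fs
  x <- 0.5 + 0.5 * sin(2 * pi * 1 * t)   # 1 Hz, band-limited
  env <- structure(list(values = matrix(rep(x, each = 13), 13,
                                        byrow = FALSE),
                        fs = fs, meta = trial_meta()),
                   class = "envelope_matrix")
  ev <- gait_cycle_times(c(0, 1, 2, 3), rep(0.6, 4))
  nc <- time_normalize(env, ev)
  for (cyc in 1:3) {
    cols <- (cyc - 1) * 200 + 1:200
    orig <- x[(round((cyc - 1) * fs) + 1):round(cyc * fs)]
    expect_equal(max(nc$values[1, cols]), max(orig), tolerance = 0.01)
    expect_equal(min(nc$values[1, cols]), min(orig), tolerance = 0.01)
  }
})
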