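test_that("trials are bit-reproducible for a fixed seed", {
  a <- generate_trial(r = 4, n_cycles = 5, noise_sd = 0.05, seed = 7)
  b <- generate_trial(r = 4, n_cycles = 5, noise_sd = 0.05, seed = 7)
  expect_identical(a$raw$samples, b$raw$samples)
  expect_identical(a$envelopes, b$envelopes)
  expect_identical(a$events, b$events)
  c <- generate_trial(r = 4, n_cycles = 5, noise_sd = 0.05, seed = 8)
  expect_false(identical(a$envelopes, c$envelopes))
})

test_that("noiseless trials are exactly low rank with non-negative truth", {
  tr <- generate_trial(r = 4, n_cycles = 30, noise_sd = 0, jitter_sd = 0,
                       seed = 1)
  expect_equal(tr$envelopes,
               tr$truth$modules_true %*% tr$truth$primitives_true)
  expect_true(all(tr$envelopes >= 0))
  expect_equal(dim(tr$envelopes), c(13L, 6000L))
  expect_equal(unname(apply(tr$truth$modules_true, 2, max)), rep(1, 4))
  # each primitive cycle carries positive activation
  for (i in 1:4) {
    cyc <- matrix(tr$truth$primitives_true[i, ], 200)
    expect_true(all(colSums(cyc) > 0))
  }
})

test_that("envelope signal-to-noise decreases monotonically with noise_sd", {
  snr <- vapply(c(0.02, 0.05, 0.1, 0.2), function(ns) {
    tr <- generate_trial(r = 4, n_cycles = 10, noise_sd = ns, seed = 3)
    clean <- tr$truth$modules_true %*% tr$truth$primitives_true
    sum(clean^2) / sum((tr$envelopes - clean)^2)
  }, numeric(1))
  expect_true(all(diff(snr) < 0))
})

test_that("trial argument validation rejects impossible settings", {
  expect_error(generate_trial(r = 0), "r must")
  expect_error(generate_trial(r = 13), "r must")
  expect_error(generate_trial(n_cycles = 1), "n_cycles")
  expect_error(generate_trial(noise_sd = -0.1), "noise_sd")
})

test_that("fGn generator matches the theory of fractional Gaussian noise", {
  n <- 6000
  # H = 0.5 is white noise: lag-1 autocorrelation ~ 0
  x <- generate_fgn(0.5, n, seed = 1)
  expect_lt(abs(cor(x[-1], x[-n])), 3 / sqrt(n))
  # persistence: positive lag-1 autocorrelation for H > 0.5
  y <- generate_fgn(0.7, n, seed = 2)
  expect_gt(cor(y[-1], y[-n]), 0.2)
  # anti-persistence for H < 0.5
  z <- generate_fgn(0.3, n, seed = 3)
  expect_lt(cor(z[-1], z[-n]), -0.1)
  # unit marginal variance
  expect_equal(var(x), 1, tolerance = 0.1)
  expect_error(generate_fgn(1.2, 1000), "h_true")
  expect_identical(generate_fgn(0.6, 512, seed = 9),
                   generate_fgn(0.6, 512, seed = 9))
})

test_that("fGn aggregated variance scales as m^(2H)", {
  # variance of block sums of size m grows as m^(2H); check the log-log
  # slope at n = 2^14 for two Hurst values
  n <- 2^14
  for (h in c(0.3, 0.7)) {
    x <- generate_fgn(h, n, seed = 4)
    m <- 2^(0:6)
    v <- vapply(m, function(mm) {
      var(colSums(matrix(x[seq_len((n %/% mm) * mm)], mm)))
    }, numeric(1))
    slope <- unname(coef(lm(log(v) ~ log(m)))[2])
    expect_equal(slope, 2 * h, tolerance = 0.1)
  }
})

test_that("cycle-time generator recovers the requested variability", {
  ev <- generate_cycle_times(30, 0.6, 0, 1.0, 0, seed = 1)
  g <- gait_summary(ev)
  expect_equal(g$stance_cv, 0)
  expect_equal(g$cadence_cv, 0)
  expect_equal(g$stance_mean, 0.6)

  ev2 <- generate_cycle_times(2, 0.6, 0, 1.0, 0, seed = 1)
  expect_equal(nrow(ev2), 2L)
  expect_equal(ev2$touchdown, c(0, 1))

  # stance CV ~ 5% within sampling error (pooled over several draws)
  cvs <- vapply(1:20, function(s) {
    gait_summary(generate_cycle_times(30, 0.6, 5, 1.0, 2, seed = s))$stance_cv
  }, numeric(1))
  expect_equal(mean(cvs), 5, tolerance = 0.75)

  expect_error(generate_cycle_times(30, 1.2, 0, 1.0, 0), "stance_mean")
  expect_error(generate_cycle_times(1, 0.6, 0, 1.0, 0), "n_cycles")
})
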