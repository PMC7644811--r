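test_that("exact rank-1 input is reconstructed essentially perfectly", {
  set.seed(1)
  m <- runif(13)
  p <- runif(400)
  V <- outer(m, p)
  fit <- nmf_factorize(V, 1, seed = 3)
  expect_gte(fit$r2, 0.9999)
  expect_true(all(fit$M >= 0) && all(fit$P >= 0))
})

test_that("the R2 sequence is non-decreasing across iterations", {
  tr <- generate_trial(r = 4, n_cycles = 10, noise_sd = 0.05, seed = 21)
  for (s in 1:3) {
    fit <- nmf_factorize(tr$envelopes, 4, seed = s, trace = TRUE)
    expect_gte(min(diff(fit$r2_trace)), -1e-12)
  }
})

test_that("the compiled updates agree with a plain-R implementation", {
  tr <- generate_trial(r = 3, n_cycles = 3, noise_sd = 0.05, seed = 31)
  V <- tr$envelopes
  seed <- 11
  n_iter <- 60
  # same initial matrices as nmf_factorize draws internally
  set.seed(seed)
  M0 <- matrix(runif(nrow(V) * 3), nrow(V), 3)
  P0 <- matrix(runif(3 * ncol(V)), 3, ncol(V))
  ref <- nmf_mu_ref(V, M0, P0, n_iter)
  # disable early convergence so both run exactly n_iter iterations
  fit <- nmf_factorize(V, 3, seed = seed, max_iter = n_iter, tol = -1,
                       trace = TRUE)
  expect_equal(fit$iterations, n_iter)
  expect_equal(unname(fit$M), unname(ref$M), tolerance = 1e-8)
  expect_equal(fit$P, ref$P, tolerance = 1e-8)
  expect_equal(fit$r2_trace, ref$r2, tolerance = 1e-10)
})

test_that("noiseless rank-4 trials give high-similarity modules", {
  tr <- generate_trial(r = 4, n_cycles = 30, noise_sd = 0, jitter_sd = 0,
                       seed = 41)
  best <- NULL
  for (s in 1:10) {
    fit <- nmf_factorize(tr$envelopes, 4, seed = 400 + s)
    if (is.null(best) || fit$r2 > best$r2) best <- fit
  }
  mm <- match_modules(best$M, tr$truth$modules_true)
  expect_true(all(mm$cosine > 0.95))
  expect_gte(best$r2, 0.999)
})

test_that("noisy rank-4 trials still recover matched modules", {
  tr <- generate_trial(r = 4, noise_sd = 0.05, seed = 3)
  fit <- extract_synergies(tr$envelopes, ranks = 4, n_restarts = 5,
                           seed = 3)
  mm <- match_modules(fit$models[[1]]$M, tr$truth$modules_true)
  expect_true(all(mm$cosine > 0.9))
})

test_that("multi-rank extraction is deterministic and restarts only help", {
  tr <- generate_trial(r = 4, n_cycles = 5, noise_sd = 0.05, seed = 51)
  fit1 <- extract_synergies(tr$envelopes, ranks = 1:6, n_restarts = 3,
                            seed = 9)
  fit2 <- extract_synergies(tr$envelopes, ranks = 1:6, n_restarts = 3,
                            seed = 9)
  expect_identical(fit1$curve, fit2$curve)
  # best-of-restarts at least as good as any single restart
  single <- nmf_factorize(tr$envelopes, 4, seed = 9 + 400 + 1)
  expect_gte(fit1$curve[["4"]], single$r2)
  # R2 non-decreasing in rank after best-of-restarts
  expect_gte(min(diff(fit1$curve)), -1e-3)
  # visible knee at the true rank
  expect_gt(fit1$curve[["4"]] - fit1$curve[["3"]],
            5 * (fit1$curve[["5"]] - fit1$curve[["4"]]))
})

test_that("rank selection steps the drop-and-refit loop correctly", {
  # exactly linear curve: MSE = 0 on the full curve -> rank 1
  lin <- 0.5 + 0.03 * (1:10)
  names(lin) <- 1:10
  expect_equal(select_rank(lin), 1L)
  # curvy example: equality with an independent step-through oracle
  curve <- c(0.55, 0.70, 0.80, 0.86, 0.88, 0.895, 0.905, 0.912, 0.918,
             0.923)
  names(curve) <- 1:10
  expect_equal(select_rank(curve), select_rank_ref(curve))
  expect_equal(select_rank(curve), 4L)
  # a curve that never linearizes walks down to the last pair
  set.seed(2)
  jag <- cumsum(runif(10, 0, 0.1))
  names(jag) <- 1:10
  expect_equal(select_rank(jag, mse_threshold = 1e-12), 9L)
})

test_that("invalid factorization inputs are rejected", {
  expect_error(nmf_factorize(matrix(-1, 13, 10), 2), "non-negative")
  expect_error(nmf_factorize(matrix(0, 13, 10), 2), "all zero")
  expect_error(nmf_factorize(matrix(1, 13, 10), 11), "rank")
})

test_that("synergy models serialize in the SYNS field layout", {
  tr <- generate_trial(r = 4, n_cycles = 2, noise_sd = 0.05, seed = 61)
  fit <- nmf_factorize(tr$envelopes, 2, seed = 1)
  path <- file.path(tempdir(), "syns.json")
  write_syns_json(list(SYNS_P0001_OW_01 = fit), path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  entry <- js$SYNS_P0001_OW_01
  expect_setequal(names(entry), c("synsR2", "M", "P", "iterations", "R2"))
  expect_equal(entry$synsR2, 2)
  expect_equal(dim(entry$M), c(13L, 2L))
  expect_equal(ncol(entry$P), 3L)   # time + one column per synergy
  expect_equal(entry$R2, fit$r2, tolerance = 1e-12)
  unlink(path)
})
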