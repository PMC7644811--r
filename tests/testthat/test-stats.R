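test_that("identical conditions give F = 0 and p = 1 for all effects", {
  set.seed(20)
  base <- rnorm(12)
  df <- data.frame(participant = rep(1:12, 4),
                   environment = rep(c("O", "O", "T", "T"), each = 12),
                   type = rep(c("W", "R", "W", "R"), each = 12),
                   value = rep(base, 4))
  a <- scalar_anova(df)
  for (e in a$effects) {
    expect_equal(e$F, 0)
    expect_equal(e$p, 1)
  }
  expect_true(all(a$posthoc$p == 1))
})

test_that("the parametric path reproduces the reference RM-ANOVA", {
  df <- make_anova_df(30, means = c(1, 1, 0, 0), seed = 21)  # env effect d~1
  a <- scalar_anova(df)
  expect_equal(a$method, "parametric")
  ref <- summary(stats::aov(
    value ~ environment * type + Error(factor(participant) /
                                         (environment * type)),
    data = df))
  f_env <- ref[["Error: factor(participant):environment"]][[1]]["environment",
                                                               "F value"]
  f_typ <- ref[["Error: factor(participant):type"]][[1]]["type", "F value"]
  f_int <- ref[["Error: factor(participant):environment:type"]][[1]][
    "environment:type", "F value"]
  expect_equal(a$effects$environment$F, f_env, tolerance = 1e-8)
  expect_equal(a$effects$type$F, f_typ, tolerance = 1e-8)
  expect_equal(a$effects$interaction$F, f_int, tolerance = 1e-8)
  expect_lt(a$effects$environment$p, 0.001)
})

test_that("non-normal residuals route to the rank-based fallback", {
  set.seed(22)
  n <- 25
  df <- data.frame(participant = rep(1:n, 4),
                   environment = rep(c("O", "O", "T", "T"), each = n),
                   type = rep(c("W", "R", "W", "R"), each = n),
                   value = exp(rnorm(4 * n, sd = 2)))  # heavy-tailed
  a <- scalar_anova(df)
  expect_equal(a$method, "rank_based")
  for (e in a$effects) {
    expect_gte(e$p, 0)
    expect_lte(e$p, 1)
  }
})

test_that("post hoc p-values are BH-adjusted monotonically", {
  df <- make_anova_df(20, means = c(1.2, 0.3, 0, 0), seed = 23)
  a <- scalar_anova(df)
  expect_true(all(a$posthoc$p_adj >= a$posthoc$p - 1e-15))
  expect_equal(nrow(a$posthoc), 6L)
})

test_that("type-I error of the scalar ANOVA is near nominal", {
  set.seed(24)
  hits <- matrix(FALSE, 400, 3)
  for (i in seq_len(400)) {
    df <- make_anova_df(30, seed = 3000 + i)
    a <- scalar_anova(df, posthoc = FALSE)
    hits[i, ] <- c(a$effects$environment$p, a$effects$type$p,
                   a$effects$interaction$p) <= 0.05
  }
  rates <- colMeans(hits)
  expect_true(all(rates > 0.01 & rates < 0.10))
})

test_that("SPM on identical environments finds no significant clusters", {
  set.seed(25)
  n_p <- 10
  half <- array(rnorm(n_p * 8 * 200), c(n_p, 1, 8, 200))
  Y <- array(0, c(n_p, 2, 8, 200))
  Y[, 1, , ] <- half[, 1, , ]
  Y[, 2, , ] <- half[, 1, , ]   # exact null: both environments identical
  res <- spm_rm_anova(Y, n_resamples = 20, seed = 1, n_perm = 200)
  expect_equal(nrow(res$clusters), 0L)
  expect_true(all(res$f_curve == 0))
})

test_that("an injected offset is detected as an overlapping cluster", {
  set.seed(26)
  n_p <- 12
  Y <- array(rnorm(n_p * 2 * 10 * 200), c(n_p, 2, 10, 200))
  Y[, 1, , 30:50] <- Y[, 1, , 30:50] + 3
  res <- spm_rm_anova(Y, n_resamples = 20, seed = 2, n_perm = 300)
  sig <- res$clusters[res$clusters$p <= 0.05, ]
  expect_gte(nrow(sig), 1)
  overlap <- any(sig$start <= 50 & sig$end >= 30)
  expect_true(overlap)
})

test_that("the SPM F curve is invariant to participant order", {
  set.seed(27)
  n_p <- 9
  Y <- array(rnorm(n_p * 2 * 6 * 200), c(n_p, 2, 6, 200))
  Y[, 1, , 100:120] <- Y[, 1, , 100:120] + 2
  r1 <- spm_rm_anova(Y, n_resamples = 5, seed = 3, n_perm = 100)
  r2 <- spm_rm_anova(Y[n_p:1, , , ], n_resamples = 5, seed = 3,
                     n_perm = 100)
  expect_equal(r1$f_curve, r2$f_curve, tolerance = 1e-12)
})

test_that("permutation p-values are valid under the null", {
  # label-exchange validity at reduced resamples: the rate of p <= alpha
  # may not exceed alpha by more than Monte-Carlo error
  set.seed(28)
  n_p <- 10
  hits <- 0
  n_rep <- 60
  for (i in seq_len(n_rep)) {
    Y <- array(rnorm(n_p * 2 * 4 * 200), c(n_p, 2, 4, 200))
    res <- spm_rm_anova(Y, n_resamples = 5, seed = i, n_perm = 200)
    if (nrow(res$clusters) > 0 && any(res$clusters$p <= 0.05)) {
      hits <- hits + 1
    }
  }
  expect_lte(hits / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})
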