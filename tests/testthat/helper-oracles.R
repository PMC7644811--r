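# Independent reference implementations used as oracles. These deliberately
# share no code with the package: filters are derived from the analog
# Butterworth prototype by bilinear transform and applied with a hand-written
# difference-equation loop; NMF updates are plain R matrix algebra.

# 2nd-order Butterworth coefficients via bilinear transform with prewarping
butter2_ref <- function(fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- 2 * fs * tan(pi * fc / fs)   # prewarped analog cut-off
  k <- 2 * fs
  # analog prototype H(s) = 1 / (s^2 + sqrt(2) s + 1), s -> s/wc
  a2 <- 1 / wc^2; a1 <- sqrt(2) / wc; a0 <- 1
  # substitute s = k (1 - z^-1) / (1 + z^-1)
  d0 <- a2 * k^2 + a1 * k + a0
  a <- c(1,
         (2 * a0 - 2 * a2 * k^2) / d0,
         (a2 * k^2 - a1 * k + a0) / d0)
  if (type == "low") {
    b <- a0 * c(1, 2, 1) / d0
  } else {
    b <- a2 * k^2 * c(1, -2, 1) / d0
  }
  list(b = b, a = a)
}

# direct-form difference equation, plain R loop
iir_ref <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  nb <- length(b); na <- length(a)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nb)) if (i - j + 1 >= 1) acc <- acc + b[j] * x[i - j + 1]
    for (j in 2:na) if (i - j + 1 >= 1) acc <- acc - a[j] * y[i - j + 1]
    y[i] <- acc
  }
  y
}

# zero-phase application: zero-pad, forward, reverse, forward, reverse
filtfilt_ref <- function(b, a, x) {
  y <- iir_ref(b, a, c(x, numeric(2 * max(length(a), length(b)))))
  rev(iir_ref(b, a, rev(y)))[seq_along(x)]
}

envelope_ref <- function(x, fs, hp = 50, lp = 20) {
  h <- butter2_ref(hp, fs, "high")
  l <- butter2_ref(lp, fs, "low")
  pmax(filtfilt_ref(l$b, l$a, abs(filtfilt_ref(h$b, h$a, x))), 0)
}

# plain-R multiplicative updates, fixed iteration count, no convergence test
nmf_mu_ref <- function(V, M, P, n_iter, eps = 1e-12) {
  ss_tot <- sum((V - mean(V))^2)
  r2 <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    P <- P * (t(M) %*% V) / (t(M) %*% M %*% P + eps)
    M <- M * (V %*% t(P)) / (M %*% P %*% t(P) + eps)
    r2[i] <- 1 - sum((V - M %*% P)^2) / ss_tot
  }
  list(M = M, P = P, r2 = r2)
}

# resultant-vector center of activity via complex arithmetic
coa_ref <- function(cycle) {
  p <- length(cycle)
  z <- sum(cycle * exp(2i * pi * (seq_len(p) - 1) / p))
  Arg(z) %% (2 * pi)
}

# textbook rescaled range
rs_ref <- function(x) {
  y <- cumsum(x - mean(x))
  (max(y) - min(y)) / sqrt(mean((x - mean(x))^2))
}

# drop-first-point linear-fit rank stepping, written independently
select_rank_ref <- function(r2, thr = 1e-4) {
  ranks <- seq_along(r2)
  repeat {
    if (length(r2) == 2) return(ranks[1])
    co <- stats::coef(stats::lm(r2 ~ ranks))
    mse <- mean((r2 - (co[1] + co[2] * ranks))^2)
    if (mse < thr) return(ranks[1])
    r2 <- r2[-1]; ranks <- ranks[-1]
  }
}

# wrapped Gaussian bell on the 200-point cycle (test fixture construction)
test_bell <- function(peak, sigma = 8, p = 200) {
  t <- 0:(p - 1)
  d <- ((t - peak + p / 2) %% p) - p / 2
  exp(-d^2 / (2 * sigma^2))
}

# balanced 2x2 within-participant data frame
make_anova_df <- function(n, means = c(0, 0, 0, 0), sd = 1, seed = 1) {
  set.seed(seed)
  data.frame(
    participant = rep(seq_len(n), 4),
    environment = rep(c("O", "O", "T", "T"), each = n),
    type = rep(c("W", "R", "W", "R"), each = n),
    value = rnorm(4 * n, rep(means, each = n), sd) +
      rep(rnorm(n, 0, 0.5), 4))  # participant random intercept
}
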