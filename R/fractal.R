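#' Rescaled range of a segment
#'
#' Classical R/S statistic: the segment is mean-centered, its cumulative sum
#' taken, R is the range (max minus min) of that cumulative sum, and S the
#' standard deviation of the original segment (population form, divisor n,
#' by default). Returns R/S.
#'
#' @param segment numeric vector (length >= 2).
#' @param sd_type "population" (default) or "sample".
#' @return R/S value; `NA` for a constant segment (S = 0), which callers
#'   exclude.
#' @export
rescaled_range <- function(segment, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  n <- length(segment)
  centered <- segment - mean(segment)
  y <- cumsum(centered)
  r <- max(y) - min(y)
  s <- if (sd_type == "population") sqrt(mean(centered^2))
       else sd(segment)
  if (s == 0) return(NA_real_)
  r / s
}

#' Hurst exponent by rescaled-range analysis
#'
#' Estimates the Hurst exponent H of a series by window-halving R/S
#' analysis: the R/S statistic is computed for the full series (window
#' N = n), then for windows N = n/2, n/4, n/8, ... (integer floor), stopping
#' before any window would fall below `min_window` (200 points, the
#' normalized gait-cycle period, by default). For each window size the
#' series is split into consecutive non-overlapping segments of that length
#' (trailing remainder discarded), R/S averaged across segments, and H
#' taken as the OLS slope of log(R/S) on log(N). H ~ 0.5 indicates a
#' memoryless series, H > 0.5 persistence, H < 0.5 anti-persistence.
#'
#' @param series numeric vector, length >= 2 * `min_window`.
#' @param min_window smallest admissible window (default 200).
#' @param sd_type passed to \code{\link{rescaled_range}}.
#' @return A `hurst_result` list: `h`, `window_sizes`, `rs_values`,
#'   `fit_intercept`, `fit_r2`. A fit R2 below 0.9 triggers a warning.
#' @export
hurst_rs <- function(series, min_window = 200L, sd_type = "population") {
  n <- length(series)
  sizes <- integer(0)
  N <- n
  while (N >= min_window) {
    sizes <- c(sizes, N)
    N <- N %/% 2L
  }
  if (length(sizes) < 2) {
    stop("series too short for at least two window sizes")
  }
  rs <- vapply(sizes, function(N) {
    k <- n %/% N
    vals <- vapply(seq_len(k), function(i) {
      rescaled_range(series[((i - 1) * N + 1):(i * N)], sd_type)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs)
  if (sum(ok) < 2) stop("too few valid window sizes (constant segments?)")
  fit <- lm(log(rs[ok]) ~ log(sizes[ok]))
  h <- unname(coef(fit)[2])
  fit_r2 <- summary(fit)$r.squared
  if (fit_r2 < 0.9) {
    warning(sprintf("log(R/S) vs log(N) fit is weak (R2 = %.3f)", fit_r2))
  }
  structure(list(h = h, window_sizes = sizes[ok], rs_values = rs[ok],
                 fit_intercept = unname(coef(fit)[1]), fit_r2 = fit_r2),
            class = "hurst_result")
}

#' Trial-level Hurst exponent of motor primitives
#'
#' Computes H for every motor primitive of a synergy model (each row of P,
#' full-trial length) and averages them to one value per trial. All
#' primitives enter the average by default, including those of combined
#' synergies; pass labels and `fundamental_only = TRUE` to restrict.
#'
#' @param model a `synergy_model` (or a bare primitive matrix, rows =
#'   primitives).
#' @param labels optional character vector of per-primitive labels
#'   ("combined" or a fundamental label).
#' @param fundamental_only restrict the average to fundamental synergies.
#' @param ... passed to \code{\link{hurst_rs}}.
#' @return A list: `h_mean` (trial average), `h` (per-primitive values).
#' @export
trial_hurst <- function(model, labels = NULL, fundamental_only = FALSE,
                        ...) {
  P <- if (inherits(model, "synergy_model")) model$P else as.matrix(model)
  keep <- seq_len(nrow(P))
  if (fundamental_only && !is.null(labels)) {
    keep <- which(labels != "combined")
  }
  h <- vapply(keep, function(i)
    suppressWarnings(hurst_rs(P[i, ], ...)$h), numeric(1))
  list(h_mean = mean(h), h = h)
}
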