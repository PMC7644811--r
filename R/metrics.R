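#' Center of activity of a primitive cycle
#'
#' Circular mean phase of a 200-point motor primitive cycle: the cycle is
#' mapped onto the unit circle with theta_t = 2*pi*(t-1)/p for t = 1..p
#' (p = 200), and the CoA is the quadrant-correct angle of the activation's
#' resultant vector, A = sum(cos(theta_t) * P_t),
#' B = sum(sin(theta_t) * P_t), CoA = atan2(B, A) wrapped into [0, 2*pi).
#'
#' @param cycle non-negative numeric vector (one cycle, typically 200
#'   points).
#' @return Angle in radians in [0, 2*pi); `NA` with a warning for a uniform
#'   cycle (undefined CoA: zero resultant).
#' @export
center_of_activity <- function(cycle) {
  p <- length(cycle)
  theta <- 2 * pi * (seq_len(p) - 1) / p
  a <- sum(cos(theta) * cycle)
  b <- sum(sin(theta) * cycle)
  if (abs(a) < 1e-12 && abs(b) < 1e-12) {
    warning("uniform cycle: center of activity undefined")
    return(NA_real_)
  }
  atan2(b, a) %% (2 * pi)
}

#' Convert a CoA angle to normalized cycle points
#'
#' @param angle angle in radians.
#' @param p points per cycle (default 200).
#' @return Position on the 0..p scale (0-based: an impulse at the t-th
#'   1-based point maps to t - 1).
#' @export
coa_points <- function(angle, p = 200L) (angle / (2 * pi) * p) %% p

#' Circular mean of angles
#'
#' Resultant-vector mean of a set of angles (radians), used to aggregate
#' per-cycle CoA values to trial level while respecting wrap-around at the
#' cycle boundary.
#'
#' @param angles numeric vector of angles in radians (NA dropped).
#' @return Mean angle in [0, 2*pi), or NA if no finite angles.
#' @export
circular_mean <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) == 0) return(NA_real_)
  atan2(mean(sin(angles)), mean(cos(angles))) %% (2 * pi)
}

#' Full width at half maximum of a primitive cycle
#'
#' After subtracting the cycle's minimum, counts the number of points
#' strictly exceeding half the resulting maximum. A constant cycle yields 0.
#'
#' @param cycle numeric vector (one cycle).
#' @return Integer count of points above half maximum.
#' @export
fwhm <- function(cycle) {
  q <- cycle - min(cycle)
  mx <- max(q)
  if (mx == 0) return(0L)
  sum(q > mx / 2)
}

#' Per-cycle geometrics of a full-trial primitive
#'
#' Computes the CoA and FWHM cycle by cycle over a full-trial primitive
#' (200 points per cycle) and aggregates to trial level: the trial CoA is
#' the circular mean of per-cycle CoAs, the trial FWHM the arithmetic mean
#' of per-cycle counts.
#'
#' @param primitive numeric vector of length 200 * n_cycles.
#' @return A list: `coa_cycles` (radians per cycle), `fwhm_cycles`,
#'   `coa` (trial circular mean, radians), `coa_points` (same on the 0..200
#'   scale), `fwhm` (trial mean).
#' @export
primitive_geometrics <- function(primitive) {
  mat <- matrix(primitive, 200L)
  coa_c <- suppressWarnings(apply(mat, 2, center_of_activity))
  fwhm_c <- apply(mat, 2, fwhm)
  coa <- circular_mean(coa_c)
  list(coa_cycles = coa_c, fwhm_cycles = fwhm_c, coa = coa,
       coa_points = coa_points(coa), fwhm = mean(fwhm_c))
}

#' Half-maximum exceedance heat map of a primitive
#'
#' For each of the 200 normalized time points, the fraction of gait cycles
#' in which the (min-subtracted) primitive strictly exceeds that cycle's
#' half maximum. Summing the 200 values equals the trial's mean FWHM.
#'
#' @param primitive numeric vector of length 200 * n_cycles.
#' @return Numeric vector of 200 values in [0, 1].
#' @export
halfmax_heatmap <- function(primitive) {
  mat <- matrix(primitive, 200L)
  exceed <- apply(mat, 2, function(cyc) {
    q <- cyc - min(cyc)
    mx <- max(q)
    if (mx == 0) rep(FALSE, length(q)) else q > mx / 2
  })
  rowMeans(exceed)
}
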