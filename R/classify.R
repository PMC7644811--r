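# R2 between two equal-length activation curves, each normalized to unit
# area so only the distribution of activation over the cycle is compared;
# can be negative when the shape fits worse than a flat line
.curve_r2 <- function(p, s) {
  p <- p / sum(p)
  s <- s / sum(s)
  1 - sum((p - s)^2) / sum((p - mean(p))^2)
}

.minmax <- function(x) {
  x <- x - min(x)
  mx <- max(x)
  if (mx > 0) x / mx else x
}

#' Cluster motor primitives into principal shapes
#'
#' Clusters per-trial mean-cycle motor primitives (200 points each) by
#' factorizing the stacked primitive matrix with the same NMF engine used
#' for synergy extraction, with the number of shapes set to
#' `max_rank + 1`. A primitive is provisionally assigned to the principal
#' shape holding its largest clustering weight, provided that weight is at
#' least the mean of the full weight matrix. The assignment is confirmed by
#' shape agreement: the R2 between the primitive and its shape (both taken
#' as unit-area activation distributions over the cycle, so only shape is
#' compared and multi-peak blends are penalized) must reach at least 25% of
#' the average R2 of the remaining assigned primitives against their own
#' shapes (or four times that average when the average is negative).
#' Confirmed primitives are fundamental; the rest are combined.
#'
#' @param primitives matrix of mean-cycle primitives, one row per primitive
#'   (n x 200), rows optionally named.
#' @param max_rank maximum factorization rank observed among the clustered
#'   trials; the number of principal shapes is `max_rank + 1`.
#' @param seed seed for the clustering factorization.
#' @param r2_fraction confirmation fraction of the average R2 (default 0.25).
#' @return A `primitive_clusters` list: `shapes` (k x 200 principal shapes,
#'   min-max normalized), `labels` (data frame: primitive, shape, label,
#'   match_weight, match_r2), `functions` (functional label per shape),
#'   `k`.
#' @export
cluster_primitives <- function(primitives, max_rank = 4L, seed = 1L,
                               r2_fraction = 0.25) {
  primitives <- as.matrix(primitives)
  if (nrow(primitives) < 2) stop("need at least 2 primitives to cluster")
  if (ncol(primitives) != 200L) stop("primitives must have 200 points")
  k <- as.integer(max_rank) + 1L
  # deterministic, order-invariant initialization: evenly spaced bell
  # shapes and constant weights. The multiplicative updates are then
  # exactly equivariant under row (primitive) permutation, so labels do
  # not depend on trial order.
  p <- 200L
  peaks <- (p / k) * (seq_len(k) - 0.5)
  init_P <- t(vapply(peaks, function(pk) {
    d <- ((0:(p - 1) - pk + p / 2) %% p) - p / 2
    exp(-d^2 / (2 * (p / (2 * k))^2)) + 0.1
  }, numeric(p)))
  init_M <- matrix(mean(primitives), nrow(primitives), k)
  fit <- nmf_factorize(primitives, r = k, seed = seed,
                       init_M = init_M, init_P = init_P)
  W <- fit$M                                   # n x k clustering weights
  shapes <- t(apply(fit$P, 1, .minmax))        # k x 200

  n <- nrow(primitives)
  w_mean <- mean(W)
  assigned <- integer(n)
  for (i in seq_len(n)) {
    j <- which.max(W[i, ])
    assigned[i] <- if (W[i, j] >= w_mean) j else NA_integer_
  }
  r2 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!is.na(assigned[i])) {
      r2[i] <- .curve_r2(.minmax(primitives[i, ]), shapes[assigned[i], ])
    }
  }
  fundamental <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(assigned[i])) next
    others <- r2[setdiff(which(!is.na(assigned)), i)]
    if (length(others) == 0) {
      fundamental[i] <- TRUE
      next
    }
    avg <- mean(others)
    thr <- if (avg >= 0) r2_fraction * avg else 4 * avg
    fundamental[i] <- r2[i] >= thr
  }

  funs <- assign_function(shapes)
  label <- ifelse(fundamental, funs[assigned], "combined")
  labels <- data.frame(
    primitive = rownames(primitives) %||% seq_len(n),
    shape = ifelse(fundamental, assigned, NA_integer_),
    label = label,
    match_weight = vapply(seq_len(n), function(i)
      if (is.na(assigned[i])) NA_real_ else W[i, assigned[i]], numeric(1)),
    match_r2 = r2,
    stringsAsFactors = FALSE)
  structure(list(shapes = shapes, labels = labels, functions = funs, k = k),
            class = "primitive_clusters")
}

#' Functional label of principal shapes from peak timing
#'
#' Labels each principal shape by the position of its main peak within the
#' 200-point gait cycle (100 stance + 100 swing points): peaks in early
#' stance are weight acceptance, late stance propulsion, early swing
#' early_swing, late swing late_swing. Window boundaries (0-based points)
#' are [0, 50), [50, 100), [100, 150), [150, 200).
#'
#' @param shapes matrix of shapes, one row per shape (k x 200).
#' @param boundaries the three inner window boundaries (default 50, 100,
#'   150).
#' @return Character vector of labels, one per shape. Duplicate labels are
#'   reported with a warning, not an error.
#' @export
assign_function <- function(shapes, boundaries = c(50, 100, 150)) {
  shapes <- as.matrix(shapes)
  labs <- c("weight_acceptance", "propulsion", "early_swing", "late_swing")
  peak0 <- apply(shapes, 1, which.max) - 1L
  out <- labs[findInterval(peak0, boundaries) + 1L]
  dup <- out[duplicated(out)]
  if (length(dup) > 0) {
    warning("multiple shapes claim label(s): ",
            paste(unique(dup), collapse = ", "))
  }
  out
}

#' Per-trial mean cycle of a primitive
#'
#' Averages a full-trial primitive (200 points per cycle) across its cycles.
#'
#' @param primitive numeric vector of length 200 * n_cycles.
#' @return Numeric vector of length 200.
#' @export
mean_cycle <- function(primitive) {
  n <- length(primitive)
  if (n %% 200L != 0L) stop("primitive length must be a multiple of 200")
  rowMeans(matrix(primitive, 200L))
}
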