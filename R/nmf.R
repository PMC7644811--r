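#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix V (muscles x time) as V ~ M P with
#' alternating multiplicative updates under the Frobenius (Gaussian)
#' objective: each iteration updates the motor primitives
#' P <- P * (M'V) / (M'M P) and then the motor modules
#' M <- M * (V P') / (M P P'), elementwise, with denominators guarded by a
#' small epsilon. Initial M and P entries are i.i.d. uniform on (0, 1).
#' Reconstruction quality is the coefficient of determination
#' R2 = 1 - SS_res / SS_tot, with SS_tot about the grand mean of V, computed
#' every iteration; the algorithm stops when the change in R2 over the last
#' `window` iterations is below `tol` (relative change by default, i.e.
#' 0.01% when `tol = 1e-4`) or at `max_iter`.
#'
#' @param V non-negative matrix (or a `normalized_cycles` object).
#' @param r factorization rank, 1-10.
#' @param seed integer seed for the random initialization.
#' @param max_iter iteration cap (default 2000).
#' @param tol convergence tolerance on the R2 change over the window
#'   (default 1e-4).
#' @param window convergence window in iterations (default 20).
#' @param eps division guard added to update denominators (default 1e-12).
#' @param conv how the R2 change is measured: "relative" (default) or
#'   "absolute".
#' @param trace if TRUE, the per-iteration R2 sequence is returned as
#'   `r2_trace`.
#' @param init_M,init_P optional explicit initial matrices (13 x r and
#'   r x n); when supplied the random initialization (and `seed`) is
#'   bypassed.
#' @return A `synergy_model` list: `M` (13 x r), `P` (r x n), `r`, `r2`,
#'   `iterations`, `seed` (and `r2_trace` when requested).
#' @export
nmf_factorize <- function(V, r, seed = 1L, max_iter = 2000L, tol = 1e-4,
                          window = 20L, eps = 1e-12,
                          conv = c("relative", "absolute"), trace = FALSE,
                          init_M = NULL, init_P = NULL) {
  conv <- match.arg(conv)
  if (inherits(V, "normalized_cycles")) V <- V$values
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (all(V == 0)) stop("V is all zero")
  if (r < 1 || r > 10) stop("rank must lie in [1, 10]")
  if (is.null(init_M) || is.null(init_P)) {
    set.seed(seed)
    M0 <- matrix(runif(nrow(V) * r), nrow(V), r)
    P0 <- matrix(runif(r * ncol(V)), r, ncol(V))
  } else {
    M0 <- init_M
    P0 <- init_P
    stopifnot(dim(M0) == c(nrow(V), r), dim(P0) == c(r, ncol(V)))
  }
  fit <- nmf_mu_cpp(V, M0, P0, as.integer(max_iter), tol, eps,
                    as.integer(window), conv == "relative", trace)
  rownames(fit$M) <- rownames(V)
  out <- list(M = fit$M, P = fit$P, r = r, r2 = fit$r2,
              iterations = fit$iterations, seed = seed)
  if (trace) out$r2_trace <- fit$r2_trace
  structure(out, class = "synergy_model")
}

#' Extract muscle synergies across ranks with restarts
#'
#' Runs the factorization at every rank in `ranks`, repeating each rank
#' `n_restarts` times from fresh random initial matrices and keeping the
#' best-R2 solution, then assembles the R2-vs-rank curve used for rank
#' selection. Restart seeds are derived deterministically from the master
#' seed as `seed + rank * 100 + restart`.
#'
#' @param V non-negative matrix or `normalized_cycles`.
#' @param ranks ranks to factorize (default 1:10).
#' @param n_restarts restarts per rank (default 10).
#' @param seed master seed.
#' @param ... passed to \code{\link{nmf_factorize}}.
#' @return A `synergy_fit` list: `curve` (named R2 vector, one per rank),
#'   `models` (best `synergy_model` per rank), `seed`.
#' @export
extract_synergies <- function(V, ranks = 1:10, n_restarts = 10L, seed = 1L,
                              ...) {
  models <- vector("list", length(ranks))
  curve <- numeric(length(ranks))
  for (i in seq_along(ranks)) {
    best <- NULL
    for (s in seq_len(n_restarts)) {
      fit <- nmf_factorize(V, ranks[i], seed = seed + ranks[i] * 100L + s,
                           ...)
      if (is.null(best) || fit$r2 > best$r2) best <- fit
    }
    models[[i]] <- best
    curve[i] <- best$r2
  }
  names(curve) <- ranks
  structure(list(curve = curve, models = models, ranks = ranks, seed = seed),
            class = "synergy_fit")
}

#' Select the factorization rank from the R2-vs-rank curve
#'
#' Searches for the most linear tail of the R2-vs-rank curve: a simple
#' linear regression is fitted to the current curve; if its mean squared
#' error falls below `mse_threshold`, the rank at the tail's first point is
#' returned; otherwise the first point is dropped and the fit repeated.
#' When only two points remain, the first of those ranks is returned.
#'
#' @param curve numeric R2 values by rank (a `synergy_fit` is accepted);
#'   names, if present, give the ranks, otherwise ranks are 1..length.
#' @param mse_threshold linearity threshold on the regression MSE, in raw
#'   R2 units (default 1e-4).
#' @return The selected rank (integer).
#' @export
select_rank <- function(curve, mse_threshold = 1e-4) {
  if (inherits(curve, "synergy_fit")) curve <- curve$curve
  ranks <- if (!is.null(names(curve))) as.integer(names(curve))
           else seq_along(curve)
  while (length(curve) > 2) {
    fit <- lm(curve ~ ranks)
    if (mean(fit$residuals^2) < mse_threshold) return(ranks[1])
    curve <- curve[-1]
    ranks <- ranks[-1]
  }
  ranks[1]
}

#' Match two module sets by greedy cosine similarity
#'
#' Pairs the columns of two module matrices greedily on cosine similarity
#' (best match first, without replacement); used to compare extracted
#' modules against ground truth despite the factorization's permutation and
#' scale ambiguity.
#'
#' @param M estimated module matrix (muscles x r).
#' @param M_true reference module matrix (muscles x r).
#' @return Data frame with columns `est`, `ref`, `cosine`.
#' @export
match_modules <- function(M, M_true) {
  r <- ncol(M)
  cs <- matrix(0, r, ncol(M_true))
  for (i in seq_len(r)) for (j in seq_len(ncol(M_true))) {
    cs[i, j] <- sum(M[, i] * M_true[, j]) /
      (sqrt(sum(M[, i]^2)) * sqrt(sum(M_true[, j]^2)))
  }
  out <- data.frame(est = integer(0), ref = integer(0), cosine = numeric(0))
  avail_i <- seq_len(r); avail_j <- seq_len(ncol(M_true))
  while (length(avail_i) > 0 && length(avail_j) > 0) {
    sub <- cs[avail_i, avail_j, drop = FALSE]
    k <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(est = avail_i[k[1]], ref = avail_j[k[2]],
                                 cosine = sub[k[1], k[2]]))
    avail_i <- avail_i[-k[1]]
    avail_j <- avail_j[-k[2]]
  }
  out
}

#' Serialize synergy models in the deposit's SYNS layout
#'
#' Writes one JSON object per trial with the field names used by the
#' published synergy deposits: `synsR2` (the chosen factorization rank),
#' `M` (motor modules, muscles x synergies), `P` (motor primitives,
#' transposed to time x synergies with a leading `time` column),
#' `iterations`, `R2`, and optionally the reconstructed envelopes `Vr`.
#'
#' @param models named list of `synergy_model` objects (one per trial).
#' @param path output JSON file.
#' @param include_vr include the reconstructed matrix `Vr = M P` (large;
#'   default FALSE).
#' @return `path`, invisibly.
#' @export
write_syns_json <- function(models, path, include_vr = FALSE) {
  out <- lapply(models, function(m) {
    stopifnot(inherits(m, "synergy_model"))
    P_t <- cbind(time = seq_len(ncol(m$P)), t(m$P))
    colnames(P_t) <- c("time", paste0("Syn", seq_len(m$r)))
    entry <- list(synsR2 = m$r, M = m$M, P = P_t,
                  iterations = m$iterations, R2 = m$r2)
    if (include_vr) entry$Vr <- m$M %*% m$P
    entry
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("synergy_model: rank %d, R2 = %.4f, %d iterations\n",
              x$r, x$r2, x$iterations))
  invisible(x)
}
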