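# paired within-participant contrast -> (F, df2, p) with df = (1, n-1);
# for a 2x2 fully within design each RM-ANOVA effect reduces to the squared
# paired t statistic of its contrast, identical under type I/II/III sums of
# squares because the design is balanced
.contrast_f <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) return(list(F = 0, df = c(1, n - 1), p = 1))
    return(list(F = Inf, df = c(1, n - 1), p = 0))
  }
  f <- n * m^2 / s^2
  list(F = f, df = c(1, n - 1), p = pf(f, 1, n - 1, lower.tail = FALSE))
}

#' Two-way repeated-measures ANOVA for a 2x2 locomotion design
#'
#' Scalar statistics for one dependent variable measured in every
#' participant under the four conditions (environment overground/treadmill
#' x locomotion type walking/running). Homogeneity of variances is checked
#' with Levene's test; residuals of the Gaussian linear model
#' `value ~ environment * type` are checked for normality with Shapiro-Wilk.
#' When residuals look normal the parametric two-way repeated-measures
#' ANOVA (type II sums of squares; for this balanced 2x2 within design all
#' SS types coincide) is used; otherwise a rank-transform fallback runs the
#' same engine on the pooled ranks of the data. Post hoc comparisons are
#' least-significant-difference paired tests across the six condition
#' pairs, Benjamini-Hochberg adjusted.
#'
#' @param data data frame with columns `participant`, `environment`
#'   ("O"/"T"), `type` ("W"/"R"), `value`. Participants missing any cell
#'   are dropped (listwise deletion); duplicate cells are averaged.
#' @param alpha significance level used only for the normality gate
#'   (default 0.05).
#' @param posthoc compute the pairwise post hoc table (default TRUE).
#' @return A `scalar_anova` list: `effects` (environment, type,
#'   interaction; each F, df, p), `levene_p`, `shapiro_p`, `method`
#'   ("parametric" or "rank_based"), `posthoc` (data frame with BH-adjusted
#'   p), `n` (participants analyzed).
#' @export
scalar_anova <- function(data, alpha = 0.05, posthoc = TRUE) {
  stopifnot(all(c("participant", "environment", "type", "value") %in%
                  names(data)))
  cells <- c("O.W", "O.R", "T.W", "T.R")
  data$cell <- paste(data$environment, data$type, sep = ".")
  agg <- tapply(data$value, list(data$participant, data$cell), mean)
  agg <- agg[, cells, drop = FALSE]
  agg <- agg[stats::complete.cases(agg), , drop = FALSE]
  n <- nrow(agg)
  if (n < 3) stop("need at least 3 complete participants")

  long <- data.frame(
    value = as.vector(agg),
    environment = factor(rep(substr(cells, 1, 1), each = n)),
    type = factor(rep(substr(cells, 3, 3), each = n)))
  levene_p <- tryCatch(
    car::leveneTest(value ~ environment * type, data = long)[1, "Pr(>F)"],
    error = function(e) NA_real_)
  res <- stats::residuals(lm(value ~ environment * type, data = long))
  shapiro_p <- tryCatch(shapiro.test(res)$p.value,
                        error = function(e) 1)  # zero-variance residuals
  method <- if (is.na(shapiro_p) || shapiro_p >= alpha) "parametric"
            else "rank_based"

  Y <- agg
  if (method == "rank_based") Y <- matrix(rank(agg), n, 4,
                                          dimnames = dimnames(agg))
  d_env <- (Y[, "O.W"] + Y[, "O.R"] - Y[, "T.W"] - Y[, "T.R"]) / 2
  d_type <- (Y[, "O.W"] - Y[, "O.R"] + Y[, "T.W"] - Y[, "T.R"]) / 2
  d_int <- Y[, "O.W"] - Y[, "O.R"] - Y[, "T.W"] + Y[, "T.R"]
  effects <- list(environment = .contrast_f(d_env),
                  type = .contrast_f(d_type),
                  interaction = .contrast_f(d_int))

  ph <- NULL
  if (posthoc) {
    pairs <- utils::combn(cells, 2)
    praw <- apply(pairs, 2, function(pr) {
      d <- Y[, pr[1]] - Y[, pr[2]]
      .contrast_f(d)$p
    })
    ph <- data.frame(a = pairs[1, ], b = pairs[2, ], p = praw,
                     p_adj = p.adjust(praw, method = "BH"))
  }

  structure(list(effects = effects, levene_p = levene_p,
                 shapiro_p = shapiro_p, method = method, posthoc = ph,
                 n = n),
            class = "scalar_anova")
}

#' One-dimensional SPM repeated-measures ANOVA with permutation inference
#'
#' Pointwise repeated-measures test of the environment effect along
#' 200-point motor-primitive curves, with nonparametric cluster inference.
#' For every normalized time point the environment F statistic is computed
#' from the participant x environment cell means (cycles averaged within
#' cell), the repeated-measures F for a two-level within factor. To account
#' for gait-cycle ordering, cycle order is re-randomized within every
#' participant and environment `n_resamples` times and the F curve averaged
#' across resamples. The critical F is the (1 - alpha) quantile of the
#' permutation distribution of the curve-wide maximum F obtained by flipping
#' environment labels within participants (`n_perm` sign flips);
#' suprathreshold clusters get a permutation p-value from the same maximum
#' distribution.
#'
#' @param curves numeric array `[participant, environment(2), cycle,
#'   point]`; a 3-d array `[participant, environment, point]` is treated as
#'   a single cycle.
#' @param n_resamples cycle-order resamples (default 10000).
#' @param alpha significance level for the cluster threshold (default
#'   0.05).
#' @param seed integer seed for resampling and permutations.
#' @param n_perm environment-label permutations for the max-F null
#'   (default 1000).
#' @return An `spm_result` list: `f_curve` (mean F per point), `threshold`
#'   (critical F), `clusters` (data frame: start, end, p), `n_resamples`,
#'   `n_perm`, `alpha`.
#' @export
spm_rm_anova <- function(curves, n_resamples = 10000L, alpha = 0.05,
                         seed = 1L, n_perm = 1000L) {
  if (length(dim(curves)) == 3L) {
    dim(curves) <- c(dim(curves)[1:2], 1L, dim(curves)[3])
  }
  stopifnot(length(dim(curves)) == 4L)
  n_p <- dim(curves)[1]
  if (dim(curves)[2] != 2L) stop("need exactly two environments")
  n_c <- dim(curves)[3]
  n_t <- dim(curves)[4]
  if (n_p < 3) stop("need at least 3 participants")
  set.seed(seed)

  # per participant x environment cycle-by-point blocks, extracted once
  blocks <- vector("list", n_p * 2)
  for (p in seq_len(n_p)) for (e in 1:2) {
    blocks[[(p - 1) * 2 + e]] <- matrix(curves[p, e, , ], n_c, n_t)
  }
  cell_diff <- function() {
    # participant x point matrix of environment differences of cell means,
    # cycles taken in freshly randomized order within each cell
    D <- matrix(0, n_p, n_t)
    for (p in seq_len(n_p)) {
      m1 <- colMeans(blocks[[(p - 1) * 2 + 1]][sample(n_c), , drop = FALSE])
      m2 <- colMeans(blocks[[(p - 1) * 2 + 2]][sample(n_c), , drop = FALSE])
      D[p, ] <- m1 - m2
    }
    D
  }
  f_of <- function(D) {
    m <- colMeans(D)
    v <- (colSums(D * D) - n_p * m^2) / (n_p - 1)
    f <- n_p * m^2 / v
    f[v <= 0] <- 0
    f
  }

  f_sum <- numeric(n_t)
  D_last <- NULL
  for (b in seq_len(n_resamples)) {
    D_last <- cell_diff()
    f_sum <- f_sum + f_of(D_last)
  }
  f_curve <- f_sum / n_resamples

  # max-F permutation null: flip environment labels within participants
  D <- D_last
  max_f <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n_p, replace = TRUE)
    max_f[b] <- max(f_of(D * s))
  }
  threshold <- unname(quantile(max_f, 1 - alpha))

  above <- f_curve > threshold
  clusters <- data.frame(start = integer(0), end = integer(0),
                         p = numeric(0))
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      cmax <- max(f_curve[starts[k]:ends[k]])
      pval <- (1 + sum(max_f >= cmax)) / (n_perm + 1)
      clusters <- rbind(clusters,
                        data.frame(start = starts[k], end = ends[k],
                                   p = pval))
    }
  }
  structure(list(f_curve = f_curve, threshold = threshold,
                 clusters = clusters, n_resamples = n_resamples,
                 n_perm = n_perm, alpha = alpha),
            class = "spm_result")
}
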