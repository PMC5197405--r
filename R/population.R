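# Population-level comparison of natural-scene and square
# border-ownership signals: orthogonal regression through the origin,
# cell-bootstrap confidence intervals, and sign-consistency summaries.

#' Orthogonal least-squares slope through the origin
#'
#' The direction minimizing the total squared orthogonal distance of the
#' points to a line through the origin: the leading eigenvector of the
#' uncentered second-moment matrix. Because each point enters through
#' its outer product, the slope is invariant to reflecting any subset of
#' points through the origin - the required symmetry, since the sign of
#' a cell's border-ownership preference is an arbitrary labelling.
#'
#' @param x,y numeric vectors (per-cell normalized effects).
#' @return list with `slope` (Inf with `vertical = TRUE` if the optimum
#'   is vertical), `angle` (radians), and `degenerate` (TRUE for an
#'   isotropic moment matrix, where the slope is reported as 1).
#' @export
orthogonal_slope_through_origin <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) stop("need at least 2 points")
  if (all(x == 0 & y == 0)) stop("all points at the origin")
  M <- matrix(c(sum(x * x), sum(x * y), sum(x * y), sum(y * y)), 2, 2)
  e <- eigen(M, symmetric = TRUE)
  degenerate <- isTRUE(all.equal(e$values[1], e$values[2]))
  if (degenerate) {
    return(list(slope = 1, angle = pi / 4, vertical = FALSE,
                degenerate = TRUE))
  }
  v <- e$vectors[, 1]
  if (abs(v[1]) < .Machine$double.eps^0.75) {
    return(list(slope = Inf, angle = pi / 2, vertical = TRUE,
                degenerate = FALSE))
  }
  list(slope = v[2] / v[1], angle = atan2(v[2], v[1]) %% pi,
       vertical = FALSE, degenerate = FALSE)
}

#' Orthogonal through-origin slope minimizing absolute deviations
#'
#' An alternative fit minimizing the summed absolute orthogonal
#' distances (by golden-section-refined angle scan); provided as a
#' robustness check on the squared-deviation slope.
#'
#' @inheritParams orthogonal_slope_through_origin
#' @return slope (numeric).
#' @export
orthogonal_slope_absolute <- function(x, y) {
  obj <- function(theta) sum(abs(-sin(theta) * x + cos(theta) * y))
  opt <- stats::optimize(obj, c(-pi / 2, pi / 2), tol = 1e-8)
  # angle scan guards against local minima of the absolute loss
  grid <- seq(-pi / 2, pi / 2, length.out = 2001)
  gv <- vapply(grid, obj, numeric(1))
  if (min(gv) < opt$objective) {
    i <- which.min(gv)
    opt <- stats::optimize(obj, c(grid[max(1L, i - 1L)],
                                  grid[min(length(grid), i + 1L)]),
                           tol = 1e-8)
  }
  tan(opt$minimum)
}

#' Canonicalize a population scatter to non-negative x
#'
#' Reflects (x, y) pairs jointly through the origin so that x >= 0, the
#' presentation convention for population scatter plots. Purely
#' cosmetic: the through-origin orthogonal slope is unchanged.
#'
#' @param x,y numeric vectors.
#' @return data frame with reflected `x`, `y`.
#' @export
canonicalize_scatter <- function(x, y) {
  s <- ifelse(x < 0, -1, 1)
  data.frame(x = s * x, y = s * y)
}

#' Bootstrap confidence interval for the through-origin slope
#'
#' Percentile interval over B resamples of cells with replacement.
#'
#' @param x,y per-cell normalized effects.
#' @param B number of bootstrap resamples.
#' @param level confidence level.
#' @param seed optional integer seed.
#' @return list with `slope`, `ci` (length 2), `B`, `n`.
#' @export
bootstrap_slope_ci <- function(x, y, B = 1000, level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  est <- orthogonal_slope_through_origin(x, y)$slope
  reps <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    orthogonal_slope_through_origin(x[i], y[i])$slope
  }, numeric(1))
  a <- (1 - level) / 2
  list(slope = est,
       ci = unname(stats::quantile(reps, c(a, 1 - a), na.rm = TRUE)),
       B = B, n = n)
}

#' Side-of-object preference consistency between two tests
#'
#' Among cells significant in both tests, the fraction whose effects
#' have the same sign.
#'
#' @param eff_a,eff_b per-cell effects in the two tests.
#' @param sig_a,sig_b logical significance flags.
#' @return list with `proportion`, `n_both` (cells significant in both),
#'   and `n_same`.
#' @export
preference_consistency <- function(eff_a, eff_b, sig_a, sig_b) {
  both <- which(sig_a & sig_b)
  same <- sum(sign(eff_a[both]) == sign(eff_b[both]))
  list(proportion = if (length(both)) same / length(both) else NA_real_,
       n_both = length(both), n_same = same)
}

#' Check that 180-degree rotation leaves mean responses unchanged
#'
#' Paired two-sided Wilcoxon signed-rank test on per-cell mean
#' transformed counts, upright versus rotated presentations. A large p
#' licenses pooling the two rotation schemes.
#'
#' @param upright,rotated per-cell mean transformed counts.
#' @return the `htest` object from [stats::wilcox.test].
#' @export
rotation_invariance_check <- function(upright, rotated) {
  stats::wilcox.test(upright, rotated, paired = TRUE,
                     alternative = "two.sided", exact = FALSE)
}
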