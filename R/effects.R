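# Per-cell spike-count statistics: the 40-300 ms counting window, the
# Anscombe variance-stabilizing transform, orientation-selectivity
# screening, factorial models with Type II tests (as in the original
# analysis, via lm + car::Anova), and border-ownership effect
# extraction.

#' Count spikes in the analysis window
#'
#' @param train numeric vector of spike times (ms).
#' @param lo,hi window bounds, ms; the window is closed-open \[lo, hi).
#' @return integer count.
#' @export
count_window <- function(train, lo = 40, hi = 300) {
  sum(train >= lo & train < hi)
}

#' Anscombe transform
#'
#' sqrt(x + 3/8), approximately variance-stabilizing for Poisson counts
#' (variance ~ 1/4 for moderate rates).
#'
#' @param x non-negative counts.
#' @return transformed values.
#' @export
anscombe <- function(x) {
  if (any(x < 0)) stop("counts must be non-negative")
  sqrt(x + 3 / 8)
}

#' Orientation modulation index
#'
#' OMI = (R_pref - R_orth) / (R_pref + R_orth), the normalized
#' difference between the mean responses to the preferred and orthogonal
#' orientations.
#'
#' @param r_pref,r_orth mean responses (>= 0, not both zero).
#' @return OMI in \[-1, 1\].
#' @export
omi <- function(r_pref, r_orth) {
  if (any(r_pref < 0 | r_orth < 0)) stop("responses must be non-negative")
  if (any(r_pref + r_orth == 0)) stop("responses must not both be zero")
  (r_pref - r_orth) / (r_pref + r_orth)
}

#' Screen cells for orientation selectivity
#'
#' Keeps cells with OMI >= threshold (study criterion: at least 0.20).
#'
#' @param cells data frame with columns `r_pref` and `r_orth` (or a
#'   precomputed `omi` column).
#' @param threshold minimum OMI for inclusion.
#' @return the selected rows of `cells`, with an `omi` column.
#' @export
filter_orientation_selective <- function(cells, threshold = 0.20) {
  if (is.null(cells$omi)) cells$omi <- omi(cells$r_pref, cells$r_orth)
  cells[cells$omi >= threshold, , drop = FALSE]
}

#' Fit a fully crossed factorial model with Type II tests
#'
#' Ordinary least squares on transformed counts with all interactions
#' (sum-to-zero factor coding) and marginality-respecting Type II sums
#' of squares per term; F and p use the full model's residual variance.
#' This is the three-way model for the square test (side x polarity x
#' size) and the four-way model for the natural scenes (side x polarity
#' x extent x scene).
#'
#' @param data data frame containing the response and factor columns.
#' @param factors character vector of factor column names.
#' @param response response column name (transformed counts).
#' @return object of class `factorial_fit`: list with the `lm` fit, the
#'   Type II `anova` table, residual variance `sigma2`, residual df,
#'   and the factor names.
#' @export
fit_factorial <- function(data, factors, response = "y") {
  stopifnot(all(c(response, factors) %in% names(data)))
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  form <- stats::reformulate(paste(factors, collapse = "*"), response)
  fit <- stats::lm(form, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design; aliased terms: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  if (fit$df.residual <= 0)
    stop("no residual degrees of freedom (need replicates)")
  an <- car::Anova(fit, type = 2)
  structure(list(fit = fit, anova = an,
                 sigma2 = sum(fit$residuals^2) / fit$df.residual,
                 df_residual = fit$df.residual, factors = factors,
                 data = data, response = response),
            class = "factorial_fit")
}

#' @export
print.factorial_fit <- function(x, ...) {
  cat("Factorial fit:", deparse(stats::formula(x$fit)), "\n")
  print(x$anova)
  invisible(x)
}

#' Type II p-value for a model term
#'
#' @param ffit a [fit_factorial] result.
#' @param term term label as it appears in the ANOVA table, e.g.
#'   `"side"` or `"side:extent"`.
#' @return the p-value.
#' @export
term_p <- function(ffit, term) {
  tab <- ffit$anova
  if (!term %in% rownames(tab)) {
    # interaction labels are order-sensitive; try a permutation match
    want <- sort(strsplit(term, ":")[[1]])
    hit <- which(vapply(rownames(tab),
                        function(r) identical(sort(strsplit(r, ":")[[1]]),
                                              want), logical(1)))
    if (length(hit) != 1L) stop("term not found: ", term)
    term <- rownames(tab)[hit]
  }
  tab[term, "Pr(>F)"]
}

# Model-implied cell means on the complete factor grid, with the weight
# machinery needed for marginal-mean contrasts and their SEs.
grid_means <- function(ffit) {
  dat <- ffit$data
  grid <- expand.grid(lapply(ffit$factors, function(f) levels(dat[[f]])),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- ffit$factors
  for (f in ffit$factors) {
    grid[[f]] <- factor(grid[[f]], levels = levels(dat[[f]]))
    stats::contrasts(grid[[f]]) <- stats::contrasts(dat[[f]])
  }
  X <- stats::model.matrix(stats::delete.response(stats::terms(ffit$fit)),
                           grid)
  list(grid = grid, X = X, mu = drop(X %*% stats::coef(ffit$fit)))
}

# Estimate and SE of a weighted contrast of grid-cell means.
grid_contrast <- function(ffit, gm, w) {
  lvec <- drop(crossprod(gm$X, w))
  est <- sum(w * gm$mu)
  se <- sqrt(drop(t(lvec) %*% stats::vcov(ffit$fit) %*% lvec))
  c(est = est, se = se)
}

# Marginal (pref - nonpref) difference over a subset of the grid.
side_contrast <- function(ffit, gm, pref_level, subset = TRUE) {
  g <- gm$grid
  keep <- rep_len(subset, nrow(g))
  wp <- as.numeric(keep & g$side == pref_level)
  wn <- as.numeric(keep & g$side != pref_level)
  grid_contrast(ffit, gm, wp / sum(wp) - wn / sum(wn))
}

#' Extract per-cell border-ownership effects
#'
#' Fits the three-way square model and the four-way scene model to the
#' Anscombe-transformed 40-300 ms spike counts of one cell, anchors the
#' preferred side to the square test, and returns the border-ownership
#' effects (marginal preferred-minus-nonpreferred differences of the
#' model-implied cell means, on the transformed scale): the square
#' effect (simple mean of the two size-specific contrasts), the
#' full-image and patch effects, and the context effect (full minus
#' patch, identically the side x extent interaction). Normalized
#' effects divide by the square-model residual SD, which reflects only
#' trial-to-trial response variability.
#'
#' @param cell a `cell_dataset` (from [simulate_cell]) or a trial data
#'   frame with columns `stim`, `scene`, `size`, `side`, `polarity`,
#'   `extent` and a `spikes` list-column.
#' @param alpha significance threshold for the selectivity flags.
#' @param square_effect "mean" (default; simple mean of the two
#'   size-specific contrasts) or "pooled" (the pooled-model marginal
#'   contrast).
#' @return object of class `effect_estimate`: a list of effects, SEs,
#'   normalized effects, p-values, significance flags, the preferred
#'   side, and the two fits.
#' @export
extract_effects <- function(cell, alpha = 0.01,
                            square_effect = c("mean", "pooled")) {
  square_effect <- match.arg(square_effect)
  trials <- if (inherits(cell, "cell_dataset")) cell$trials else cell
  trials$y <- anscombe(vapply(trials$spikes, count_window, numeric(1)))
  sq <- trials[trials$stim == "square", ]
  sc <- trials[trials$stim == "scene", ]
  if (nrow(sq) == 0L) stop("no square-test trials")
  if (nrow(sc) == 0L) stop("no natural-scene trials")
  fit_sq <- fit_factorial(sq, c("side", "polarity", "size"))
  fit_sc <- fit_factorial(sc, c("side", "polarity", "extent", "scene"))
  gm_sq <- grid_means(fit_sq)
  gm_sc <- grid_means(fit_sc)

  # preferred side: the side with the larger square-test marginal mean
  raw_sq <- side_contrast(fit_sq, gm_sq, pref_level = "s1")
  pref_side <- if (raw_sq[["est"]] >= 0) "s1" else "s2"

  by_size <- lapply(levels(gm_sq$grid$size), function(sz)
    side_contrast(fit_sq, gm_sq, pref_side, gm_sq$grid$size == sz))
  eff_square <- if (square_effect == "mean") {
    mean(vapply(by_size, `[[`, numeric(1), "est"))
  } else {
    side_contrast(fit_sq, gm_sq, pref_side)[["est"]]
  }
  se_square <- sqrt(mean(vapply(by_size, `[[`, numeric(1), "se")^2) /
                      length(by_size))

  full <- side_contrast(fit_sc, gm_sc, pref_side, gm_sc$grid$extent == "full")
  patch <- side_contrast(fit_sc, gm_sc, pref_side, gm_sc$grid$extent == "patch")
  sigma_sq <- sqrt(fit_sq$sigma2)

  p <- c(square = term_p(fit_sq, "side"),
         scene = term_p(fit_sc, "side"),
         context = term_p(fit_sc, "side:extent"))
  eff <- c(square = eff_square, full = full[["est"]],
           patch = patch[["est"]],
           context = full[["est"]] - patch[["est"]])
  se <- c(square = se_square, full = full[["se"]], patch = patch[["se"]],
          context = sqrt(full[["se"]]^2 + patch[["se"]]^2))
  cell_id <- if (inherits(cell, "cell_dataset")) cell$cell
             else if (!is.null(trials$cell)) unique(trials$cell)[1] else NA
  structure(list(cell = cell_id,
                 pref_side = pref_side,
                 effects = eff, se = se,
                 normalized = eff / sigma_sq,
                 sigma_square = sigma_sq,
                 p = p,
                 significant = p < alpha,
                 alpha = alpha,
                 fit_square = fit_sq, fit_scene = fit_sc),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("Cell", x$cell, "- preferred side:", x$pref_side, "\n")
  tab <- data.frame(effect = x$effects, se = x$se,
                    normalized = x$normalized,
                    p = c(x$p["square"], x$p["scene"], NA, x$p["context"]))
  print(round(tab, 4))
  invisible(x)
}

#' Significance flags for border-ownership selectivity
#'
#' @param est an [extract_effects] result.
#' @param alpha significance threshold (study value 0.01).
#' @return named logical vector: square, scene, context.
#' @export
classify_significance <- function(est, alpha = 0.01) {
  est$p < alpha
}

#' Tabulate effects across a population
#'
#' @param estimates list of [extract_effects] results.
#' @return data frame with one row per cell.
#' @export
effect_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(cell = e$cell, pref_side = e$pref_side,
               eff_square = e$effects[["square"]],
               eff_full = e$effects[["full"]],
               eff_patch = e$effects[["patch"]],
               eff_context = e$effects[["context"]],
               norm_square = e$normalized[["square"]],
               norm_full = e$normalized[["full"]],
               norm_patch = e$normalized[["patch"]],
               norm_context = e$normalized[["context"]],
               p_square = e$p[["square"]], p_scene = e$p[["scene"]],
               p_context = e$p[["context"]])
  }))
}
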