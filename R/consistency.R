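# Cross-scene consistency of the border-ownership signal: per-scene
# effects, surrogate null ensembles simulated from the fitted linear
# model with the side-of-object terms zeroed, sorted-profile envelopes,
# and the deconvolution-corrected consistency index.

#' Per-scene border-ownership effects
#'
#' For each scene, the preferred-minus-nonpreferred difference of mean
#' transformed counts, for the full-image and patch conditions and for
#' the context (full minus patch). Signs are anchored to the cell's
#' square-test preference.
#'
#' @param cell a `cell_dataset` or a trial data frame (scene trials with
#'   columns `scene`, `side`, `polarity`, `extent`, `spikes`).
#' @param pref_side the cell's preferred side ("s1"/"s2"), typically
#'   from [extract_effects]; defaults to the generator's ground truth
#'   when `cell` is a `cell_dataset`.
#' @return data frame with columns `scene`, `full`, `patch`, `context`,
#'   of class `scene_effect_profile`.
#' @export
per_scene_effects <- function(cell, pref_side = NULL) {
  trials <- if (inherits(cell, "cell_dataset")) cell$trials else cell
  if (is.null(pref_side)) {
    if (inherits(cell, "cell_dataset")) pref_side <- cell$params$pref_side
    else stop("pref_side is required for a raw trial table")
  }
  sc <- trials[trials$stim == "scene", ]
  if (nrow(sc) == 0L) stop("no natural-scene trials")
  if (is.null(sc$y))
    sc$y <- anscombe(vapply(sc$spikes, count_window, numeric(1)))
  eff_one <- function(d) {
    mean(d$y[d$side == pref_side]) - mean(d$y[d$side != pref_side])
  }
  scenes <- sort(unique(sc$scene))
  out <- data.frame(scene = scenes)
  for (ext in c("full", "patch")) {
    out[[ext]] <- vapply(scenes, function(s)
      eff_one(sc[sc$scene == s & sc$extent == ext, ]), numeric(1))
  }
  out$context <- out$full - out$patch
  class(out) <- c("scene_effect_profile", class(out))
  out
}

#' Sort a per-scene effect profile
#'
#' @param effects numeric per-scene effects.
#' @return effects in decreasing order.
#' @export
sort_profile <- function(effects) sort(effects, decreasing = TRUE)

# Indicator/averaging matrix turning trial responses into per-scene
# pref-minus-nonpref mean differences for one extent.
scene_effect_weights <- function(data, pref_side, extent) {
  scenes <- sort(unique(data$scene))
  W <- matrix(0, length(scenes), nrow(data))
  for (i in seq_along(scenes)) {
    p <- which(data$scene == scenes[i] & data$extent == extent &
                 data$side == pref_side)
    n <- which(data$scene == scenes[i] & data$extent == extent &
                 data$side != pref_side)
    W[i, p] <- 1 / length(p)
    W[i, n] <- -1 / length(n)
  }
  rownames(W) <- scenes
  W
}

#' Simulate a surrogate null ensemble from a fitted cell model
#'
#' Generates surrogate response sets from the cell's four-way linear
#' model with the coefficients of side-of-object and all its
#' interactions set to 0, adding Gaussian noise with the model's
#' residual variance, then recomputes the per-scene border-ownership
#' effects of each surrogate. The ensemble calibrates what sorting pure
#' noise looks like and supplies the noise distribution for the
#' deconvolution correction.
#'
#' @param ffit the scene-model [fit_factorial] result (factors side,
#'   polarity, extent, scene).
#' @param pref_side the cell's preferred side.
#' @param n_surrogates ensemble size.
#' @param seed optional integer seed.
#' @return object of class `null_ensemble`: list of per-extent effect
#'   matrices (`n_surrogates` x scenes), their sorted versions, the
#'   pooled null effects, and the per-extent null SD `sigma0`.
#' @export
simulate_null_ensemble <- function(ffit, pref_side, n_surrogates = 1000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(inherits(ffit, "factorial_fit"))
  X <- stats::model.matrix(ffit$fit)
  beta <- stats::coef(ffit$fit)
  labels <- attr(stats::terms(ffit$fit), "term.labels")
  asg <- attr(X, "assign")
  side_terms <- which(vapply(labels, function(l)
    "side" %in% strsplit(l, ":")[[1]], logical(1)))
  beta[asg %in% side_terms] <- 0
  mu0 <- drop(X %*% beta)
  sigma <- sqrt(ffit$sigma2)
  nr <- nrow(X)
  Y <- matrix(stats::rnorm(nr * n_surrogates, 0, sigma), nr) + mu0
  dat <- ffit$data
  out <- list(n_surrogates = n_surrogates)
  for (ext in c("full", "patch")) {
    W <- scene_effect_weights(dat, pref_side, ext)
    out[[ext]] <- t(W %*% Y)   # n_surrogates x scenes
  }
  out$context <- out$full - out$patch
  out$sorted <- lapply(out[c("full", "patch", "context")], function(E)
    t(apply(E, 1, sort, decreasing = TRUE)))
  out$sigma0 <- vapply(out[c("full", "patch", "context")],
                       function(E) stats::sd(as.vector(E)), numeric(1))
  class(out) <- "null_ensemble"
  out
}

#' Envelope of the sorted null-hypothesis profile
#'
#' Per-rank percentile band of the sorted surrogate profiles (default
#' 95%), with the mean sorted profile as the null line. With
#' `method = "scene_bootstrap"` the band is instead computed by
#' resampling scenes with replacement within each surrogate profile.
#'
#' @param ensemble a [simulate_null_ensemble] result.
#' @param extent "full", "patch" or "context".
#' @param probs envelope quantiles.
#' @param method "ensemble" or "scene_bootstrap".
#' @param B scene-bootstrap resamples (scene_bootstrap method only).
#' @param seed optional integer seed (scene_bootstrap method only).
#' @return data frame with columns `rank`, `lo`, `mid`, `hi`.
#' @export
null_envelope <- function(ensemble, extent = "full",
                          probs = c(0.025, 0.975),
                          method = c("ensemble", "scene_bootstrap"),
                          B = 1000, seed = NULL) {
  method <- match.arg(method)
  S <- ensemble$sorted[[extent]]
  if (method == "ensemble") {
    qs <- apply(S, 2, stats::quantile, probs = probs)
    data.frame(rank = seq_len(ncol(S)), lo = qs[1, ],
               mid = colMeans(S), hi = qs[2, ])
  } else {
    if (!is.null(seed)) set.seed(seed)
    E <- ensemble[[extent]]
    ns <- ncol(E)
    reps <- matrix(NA_real_, B, ns)
    for (b in seq_len(B)) {
      i <- sample.int(nrow(E), 1L)
      reps[b, ] <- sort(E[i, sample.int(ns, ns, replace = TRUE)],
                        decreasing = TRUE)
    }
    qs <- apply(reps, 2, stats::quantile, probs = probs)
    data.frame(rank = seq_len(ns), lo = qs[1, ], mid = colMeans(reps),
               hi = qs[2, ])
  }
}

#' Raw cross-scene consistency
#'
#' The fraction of scenes whose border-ownership effect is positive
#' (i.e. agrees with the square-test preference). Attenuated toward 0.5
#' by trial noise; see [corrected_consistency].
#'
#' @param effects per-scene effects.
#' @return proportion in \[0, 1\].
#' @export
raw_consistency <- function(effects) mean(effects > 0)

#' Deconvolution-corrected cross-scene consistency
#'
#' The measured distribution of per-scene effects is the convolution of
#' the true effect distribution with the trial-noise distribution (the
#' null-surrogate effects). Both are approximated by Gaussians - the
#' observed effects by N(m, s^2), the null effects by N(0, sigma0^2) -
#' so the deconvolved law is N(m, s^2 - sigma0^2) and the corrected
#' consistency is its mass above 0. When s^2 <= sigma0^2 the variance
#' is floored at (floor_frac * sigma0)^2 and flagged.
#'
#' @param effects per-scene effects of the cell.
#' @param null_effects pooled surrogate effects (or a
#'   [simulate_null_ensemble] result, in which case `extent` selects the
#'   pooled null distribution).
#' @param extent which condition's null to use when `null_effects` is an
#'   ensemble.
#' @param floor_frac variance floor as a fraction of sigma0.
#' @return list: `corrected`, `raw`, `m`, `s`, `sigma0`, `floored`.
#' @export
corrected_consistency <- function(effects, null_effects, extent = "full",
                                  floor_frac = 0.05) {
  sigma0 <- if (inherits(null_effects, "null_ensemble"))
    null_effects$sigma0[[extent]] else stats::sd(null_effects)
  m <- mean(effects)
  s <- stats::sd(effects)
  v <- s^2 - sigma0^2
  floored <- v <= (floor_frac * sigma0)^2
  if (floored) {
    warning("observed variance barely exceeds the null variance; ",
            "deconvolved variance floored")
    v <- (floor_frac * sigma0)^2
  }
  list(corrected = stats::pnorm(m / sqrt(v)),
       raw = raw_consistency(effects),
       m = m, s = s, sigma0 = sigma0, floored = floored)
}

#' One-tailed proportion test against chance
#'
#' P(X >= k) for X ~ Binomial(n, 1/2), exact or by the
#' continuity-corrected normal approximation, optionally Bonferroni
#' multiplied (capped at 1).
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param correction_factor Bonferroni multiplier (number of tests).
#' @param method "exact" or "normal".
#' @return the (corrected) one-tailed p-value.
#' @export
proportion_test <- function(k, n, correction_factor = 1,
                            method = c("exact", "normal")) {
  method <- match.arg(method)
  stopifnot(k >= 0, k <= n, correction_factor >= 1)
  p <- if (method == "exact") {
    stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  } else {
    z <- (k - 0.5 - n / 2) / sqrt(n / 4)
    stats::pnorm(z, lower.tail = FALSE)
  }
  min(1, p * correction_factor)
}
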