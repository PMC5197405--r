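# Independent oracles and small fixture builders used across tests.

# Brute-force Type II sums of squares: SS(term | all terms that do not
# contain it), by explicit residual-sum-of-squares comparison of nested
# lm fits; F uses the full model's residual variance. Independent of the
# package's fit_factorial (which delegates to car::Anova).
oracle_type2 <- function(data, factors, response = "y") {
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    contrasts(data[[f]]) <- contr.sum(nlevels(data[[f]]))
  }
  full_terms <- attr(terms(reformulate(paste(factors, collapse = "*"))),
                     "term.labels")
  rss <- function(term_set) {
    rhs <- if (length(term_set)) paste(term_set, collapse = "+") else "1"
    sum(lm(reformulate(rhs, response), data = data)$residuals^2)
  }
  full_fit <- lm(reformulate(paste(full_terms, collapse = "+"), response),
                 data = data)
  sigma2 <- sum(full_fit$residuals^2) / full_fit$df.residual
  out <- lapply(full_terms, function(tm) {
    fs <- strsplit(tm, ":")[[1]]
    contains <- vapply(full_terms, function(u)
      all(fs %in% strsplit(u, ":")[[1]]), logical(1))
    reduced <- full_terms[!contains]
    ss <- rss(reduced) - rss(c(reduced, tm))
    df <- prod(vapply(fs, function(f) nlevels(data[[f]]) - 1L, integer(1)))
    Fv <- (ss / df) / sigma2
    c(ss = ss, df = df, F = Fv,
      p = pf(Fv, df, full_fit$df.residual, lower.tail = FALSE))
  })
  names(out) <- full_terms
  out
}

# Angle-grid-search oracle for the through-origin orthogonal fit.
oracle_angle_scan <- function(x, y, step = 0.001) {
  angles <- seq(0, pi, by = step)
  obj <- vapply(angles, function(a)
    sum((-sin(a) * x + cos(a) * y)^2), numeric(1))
  angles[which.min(obj)]
}

# Per-pixel loop oracle for the patch blend.
oracle_patch_blend <- function(scene, point, k, bg) {
  px <- scene$pixels
  out <- px
  for (i in seq_len(dim(px)[1])) {
    for (j in seq_len(dim(px)[2])) {
      d <- sqrt((i - point$center[1])^2 + (j - point$center[2])^2)
      a <- if (d < point$radius_px) 1 else
        2 * pnorm(sqrt(2) * k * (d - point$radius_px), lower.tail = FALSE)
      out[i, j, ] <- a * px[i, j, ] + (1 - a) * bg
    }
  }
  out
}

# Event-list accumulation oracle for cumulative curves.
oracle_cumulative <- function(trials, w, tt) {
  y <- numeric(length(tt))
  for (i in seq_len(nrow(trials))) {
    for (sp in trials$spikes[[i]]) {
      y <- y + w[i] * (sp < tt)
    }
  }
  y
}

# A small piecewise-constant annotated scene: side 1 (columns left of
# center) uniform c1, side 2 uniform c2.
make_split_scene <- function(c1 = c(0.2, 0.4, 0.6), c2 = c(0.6, 0.2, 0.2),
                             n = 21L, radius = 6) {
  center <- c((n + 1) / 2, (n + 1) / 2)
  px <- array(0, dim = c(n, n, 3))
  for (ch in 1:3) {
    px[, , ch] <- matrix(ifelse(rep(seq_len(n), each = n) < center[2],
                                c1[ch], c2[ch]), n, n)
  }
  disc <- (row(px[, , 1]) - center[1])^2 + (col(px[, , 1]) - center[2])^2 <=
    radius^2
  mask1 <- disc & col(px[, , 1]) < center[2]
  mask2 <- disc & col(px[, , 1]) > center[2]
  list(scene = scene_image(px, 0.05),
       point = scene_point(center, 90, c(0, -1), radius, mask1, mask2))
}

# Balanced synthetic trial table with spike trains that carry exact
# counts (spikes evenly placed inside the counting window).
spikes_with_count <- function(k) {
  if (k == 0) return(numeric(0))
  seq(41, 299, length.out = k)
}
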