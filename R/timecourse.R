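# Time course of the border-ownership signal: population PSTHs,
# cumulative spike-count curves at 1-ms resolution, two-phase-regression
# latency estimation, and presentation-bootstrap latency SDs.

#' Label trials with side preference
#'
#' Adds a `side_rel` column ("pref"/"nonpref") to a trial table, given
#' each cell's preferred side.
#'
#' @param trials trial data frame with columns `cell` and `side`.
#' @param prefs named character vector mapping cell id to preferred side
#'   ("s1"/"s2"), or a single value applied to all cells.
#' @return the trial table with `side_rel`.
#' @export
label_preferred <- function(trials, prefs) {
  pref <- if (length(prefs) == 1L && is.null(names(prefs)))
    rep(prefs, nrow(trials)) else unname(prefs[as.character(trials$cell)])
  if (anyNA(pref)) stop("missing preferred side for some cells")
  trials$side_rel <- ifelse(trials$side == pref, "pref", "nonpref")
  trials
}

#' Population peristimulus time histogram
#'
#' Pools spikes across the supplied trials into 1-ms bins over
#' \[0, duration) and converts to rate (Hz) per presentation.
#'
#' @param trials trial data frame with a `spikes` list-column.
#' @param duration_ms presentation duration.
#' @return data frame of class `psth` with columns `t` (bin left edge,
#'   ms) and `rate` (Hz).
#' @export
population_psth <- function(trials, duration_ms = 300) {
  n <- nrow(trials)
  if (n == 0L) stop("no trials")
  sp <- unlist(trials$spikes, use.names = FALSE)
  counts <- tabulate(pmin(floor(sp), duration_ms - 1) + 1L, duration_ms)
  out <- data.frame(t = 0:(duration_ms - 1), rate = counts / n * 1000)
  class(out) <- c("psth", class(out))
  out
}

#' Lowess-smooth a PSTH
#'
#' Locally weighted regression with the given span fraction (the
#' "tension" of the original analysis, 0.12 by default).
#'
#' @param psth a [population_psth] result (or any data frame with `t`
#'   and `rate`).
#' @param span lowess span fraction.
#' @return the PSTH with `rate` replaced by its smoothed values.
#' @export
lowess_smooth <- function(psth, span = 0.12) {
  sm <- stats::lowess(psth$t, psth$rate, f = span)
  psth$rate <- sm$y[match(psth$t, sm$x)]
  psth
}

#' Cumulative spike-count curve
#'
#' Pooled cumulative counts at 1-ms resolution over the analysis window
#' of the given curve kind:
#' * `overall`: preferred + nonpreferred counts, window \[0, 80\] ms
#'   (response-onset estimation);
#' * `differential`: preferred - nonpreferred counts, window
#'   \[30, 150\] ms (border-ownership signal);
#' * `context`: the full-image differential minus the patch
#'   differential, window \[30, 150\] ms (context component; requires an
#'   `extent` column with both extents present).
#'
#' The value at time t is the signed count of spikes earlier than t.
#'
#' @param trials trial table with `side_rel` (see [label_preferred]) and
#'   a `spikes` list-column; for `kind = "context"` also `extent`.
#' @param kind curve kind.
#' @param window integer window \[lo, hi\] in ms; defaults as above.
#' @return data frame of class `cumulative_curve` with columns `t`, `y`.
#' @export
cumulative_curve <- function(trials,
                             kind = c("overall", "differential", "context"),
                             window = NULL) {
  kind <- match.arg(kind)
  if (is.null(window)) window <- if (kind == "overall") c(0, 80) else c(30, 150)
  if (is.null(trials$side_rel)) stop("trials need a side_rel column")
  w <- switch(kind,
    overall = rep(1, nrow(trials)),
    differential = ifelse(trials$side_rel == "pref", 1, -1),
    context = ifelse(trials$side_rel == "pref", 1, -1) *
              ifelse(trials$extent == "full", 1, -1))
  tt <- seq(window[1], window[2])
  ns <- lengths(trials$spikes)
  sp <- unlist(trials$spikes, use.names = FALSE)
  if (length(sp)) {
    ws <- rep(w, ns)
    o <- order(sp)
    cw <- cumsum(ws[o])
    idx <- findInterval(tt - 1e-9, sp[o])   # spikes strictly before t
    y <- ifelse(idx > 0, cw[pmax(idx, 1L)], 0)
  } else {
    y <- numeric(length(tt))
  }
  out <- data.frame(t = tt, y = y)
  class(out) <- c("cumulative_curve", class(out))
  out
}

fit_line <- function(t, y) {
  tb <- mean(t); yb <- mean(y)
  st <- sum((t - tb)^2)
  b <- if (st == 0) 0 else sum((t - tb) * (y - yb)) / st
  a <- yb - b * tb
  c(a = a, b = b, ss = sum((y - (a + b * t))^2))
}

#' Two-phase regression on a cumulative curve
#'
#' Grid search over integer-ms breakpoints: the first leg is a free
#' line (or identically zero if `force_zero_first_leg`, appropriate for
#' differential signals that cancel before onset), the second leg a
#' free line, chosen to minimize the total sum of squares. The legs are
#' not constrained to meet at the breakpoint; the latency is defined by
#' the intersection of the two lines (for a forced-zero first leg, the
#' point where the second leg crosses zero). If no breakpoint improves
#' on a single line by more than `min_improve`, the curve is flagged
#' `no_onset`.
#'
#' @param curve a [cumulative_curve] (or data frame with `t`, `y`).
#' @param force_zero_first_leg force the first leg to the zero line.
#' @param min_improve minimum fractional SS improvement over the
#'   single-line fit.
#' @return object of class `two_phase_fit`: list with `latency` (ms),
#'   `breakpoint`, `leg1`, `leg2`, `ss`, `ss_single`, `no_onset`.
#' @export
two_phase_fit <- function(curve, force_zero_first_leg = FALSE,
                          min_improve = 0.01) {
  t <- curve$t; y <- curve$y
  n <- length(t)
  if (n < 10L) stop("window too short for two-phase regression")
  best <- list(ss = Inf)
  for (k in 2:(n - 2)) {
    left <- 1:k; right <- (k + 1):n
    if (force_zero_first_leg) {
      l1 <- c(a = 0, b = 0, ss = sum(y[left]^2))
    } else {
      l1 <- fit_line(t[left], y[left])
    }
    l2 <- fit_line(t[right], y[right])
    ss <- l1[["ss"]] + l2[["ss"]]
    if (ss < best$ss) best <- list(k = k, leg1 = l1, leg2 = l2, ss = ss)
  }
  single <- fit_line(t, y)
  # a curve that a single line already fits (to numerical precision)
  # has no detectable onset
  tss <- sum((y - mean(y))^2)
  no_onset <- best$ss > (1 - min_improve) * single[["ss"]] ||
    single[["ss"]] <= 1e-12 * max(tss, 1)
  db <- best$leg2[["b"]] - best$leg1[["b"]]
  latency <- if (abs(db) < .Machine$double.eps^0.5) NA_real_
             else (best$leg1[["a"]] - best$leg2[["a"]]) / db
  structure(list(latency = latency, breakpoint = t[best$k],
                 leg1 = best$leg1[c("a", "b")],
                 leg2 = best$leg2[c("a", "b")],
                 ss = best$ss, ss_single = single[["ss"]],
                 no_onset = no_onset,
                 force_zero = force_zero_first_leg),
            class = "two_phase_fit")
}

#' @export
print.two_phase_fit <- function(x, ...) {
  cat(sprintf("Two-phase fit: latency %.1f ms (breakpoint %d ms%s)%s\n",
              x$latency, x$breakpoint,
              if (x$force_zero) ", first leg forced to zero" else "",
              if (x$no_onset) " [no-onset]" else ""))
  invisible(x)
}

#' Bootstrap SD of a two-phase-regression latency
#'
#' Resamples stimulus presentations with replacement within cell and
#' condition (keeping the presentation counts fixed), recomputes the
#' pooled cumulative curve and its two-phase latency for each resample,
#' and reports the SD across resamples.
#'
#' @param trials labelled trial table (see [cumulative_curve]).
#' @param kind curve kind.
#' @param window analysis window (ms); default per kind.
#' @param force_zero_first_leg forwarded to [two_phase_fit]; default
#'   TRUE for differential/context curves, FALSE for overall.
#' @param B number of bootstrap resamples.
#' @param seed optional integer seed.
#' @return object of class `latency_estimate`: list with `latency` (the
#'   point estimate), `sd`, `B`, and the bootstrap `latencies`.
#' @export
latency_bootstrap_sd <- function(trials, kind = "differential",
                                 window = NULL,
                                 force_zero_first_leg = kind != "overall",
                                 B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cond_cols <- intersect(c("cell", "stim", "scene", "size", "side",
                           "polarity", "extent"), names(trials))
  key <- do.call(paste, c(trials[cond_cols], sep = "\r"))
  groups <- split(seq_len(nrow(trials)), key)
  point <- two_phase_fit(cumulative_curve(trials, kind, window),
                         force_zero_first_leg)
  lat <- vapply(seq_len(B), function(b) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]),
      use.names = FALSE)
    fit <- two_phase_fit(cumulative_curve(trials[idx, ], kind, window),
                         force_zero_first_leg)
    fit$latency
  }, numeric(1))
  structure(list(latency = point$latency,
                 sd = stats::sd(lat, na.rm = TRUE), B = B,
                 latencies = lat, no_onset = point$no_onset),
            class = "latency_estimate")
}
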