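test_that("rate function reduces to a baseline-evoked step when amplitudes are zero", {
  p <- neuron_params(local_amp_hz = 0, context_amp_hz = 0,
                     square_amp_hz = 0, polarity_gain = 1)
  cond <- list(stim = "scene", extent = "full", side = "pref",
               polarity = "pref")
  tt <- c(0, 10, 43.9, 44, 100, 299)
  expect_equal(rate_function(p, cond, 1, tt),
               ifelse(tt < 44, 5, 40))
  # identical for the non-preferred side (no difference components)
  cond$side <- "nonpref"
  expect_equal(rate_function(p, cond, 1, tt), ifelse(tt < 44, 5, 40))
  expect_error(rate_function(p, cond, 1, 300), "must lie")
  expect_error(rate_function(p, cond, 1, -1), "must lie")
})

test_that("the preferred/nonpreferred rate difference respects the component windows", {
  p <- preset_paper_calibrated()
  dr <- function(cond, tt)
    rate_function(p, cond, 1, tt) -
      rate_function(p, utils::modifyList(cond, list(side = "nonpref")), 1, tt)
  full <- list(stim = "scene", extent = "full", side = "pref",
               polarity = "pref")
  patch <- utils::modifyList(full, list(extent = "patch"))
  # before the context onset and outside the local window: no difference
  expect_equal(dr(full, c(0, 20, 41.5)), rep(0, 3))
  expect_equal(dr(patch, c(0, 44.5, 95, 200)), rep(0, 4))
  # the patch difference is the transient local component only
  expect_equal(dr(patch, 60), p$local_amp_hz)
  # the context component ramps linearly to its peak
  expect_equal(dr(full, 139.5),
               p$context_amp_hz * (139.5 - 42) / (140 - 42))
  expect_equal(dr(full, 60),
               p$local_amp_hz + p$context_amp_hz * (60 - 42) / 98)
  # rates are truncated at zero for extreme multipliers
  big <- rate_function(p, utils::modifyList(full, list(side = "nonpref")),
                       scene_multiplier = 50, t = 150)
  expect_equal(big, 0)
})

test_that("mean simulated count matches the rate integral", {
  p <- preset_paper_calibrated()
  cond <- list(stim = "scene", extent = "full", side = "pref",
               polarity = "pref")
  tm <- seq(0, 299) + 0.5
  lambda <- sum(rate_function(p, cond, 1, tm)[tm >= 40]) / 1000
  set.seed(31)
  counts <- replicate(400, count_window(simulate_trial(p, cond, 1)))
  expect_lt(abs(mean(counts) - lambda), 3 * sd(counts) / sqrt(400))
})

test_that("spike trains behave like a Poisson process", {
  p <- neuron_params(baseline_hz = 20, evoked_hz = 20, local_amp_hz = 0,
                     context_amp_hz = 0, square_amp_hz = 0,
                     polarity_gain = 1)
  cond <- list(stim = "scene", extent = "full", side = "pref",
               polarity = "pref")
  set.seed(5)
  counts <- replicate(2000, length(simulate_trial(p, cond, 1)))
  expect_gt(var(counts) / mean(counts), 0.88)   # 1-ms Bernoulli bins:
  expect_lt(var(counts) / mean(counts), 1.08)   # ratio 1 - p ~ 0.98
  # doubling the rate doubles the expected count
  p2 <- neuron_params(baseline_hz = 40, evoked_hz = 40, local_amp_hz = 0,
                      context_amp_hz = 0, square_amp_hz = 0,
                      polarity_gain = 1)
  set.seed(6)
  counts2 <- replicate(1000, length(simulate_trial(p2, cond, 1)))
  expect_equal(mean(counts2) / mean(counts), 2, tolerance = 0.1)
  # zero rate: empty train
  p0 <- neuron_params(baseline_hz = 0, evoked_hz = 0, local_amp_hz = 0,
                      context_amp_hz = 0, square_amp_hz = 0)
  expect_length(simulate_trial(p0, cond, 1, seed = 1), 0)
  # times sorted strictly increasing, inside [0, 300)
  tr <- simulate_trial(p, cond, 1, seed = 9)
  expect_true(all(diff(tr) > 0))
  expect_true(all(tr >= 0 & tr < 300))
})

test_that("scene-effect multipliers have the stated Normal law", {
  p <- neuron_params(sigma_scene = 0)
  expect_equal(draw_scene_effects(p, 10, seed = 1), rep(1, 10))
  p2 <- neuron_params(sigma_scene = 2)
  m <- draw_scene_effects(p2, 20000, seed = 2)
  # the implied consistency is the Normal mass above zero
  expect_equal(mean(m > 0), pnorm(1 / 2), tolerance = 0.01)
  expect_identical(draw_scene_effects(p2, 50, seed = 3),
                   draw_scene_effects(p2, 50, seed = 3))
})

test_that("a simulated cell covers the full factorial design", {
  p <- preset_paper_calibrated(n_reps = 3, n_reps_square = 4)
  cl <- simulate_cell(p, n_scenes = 5, seed = 21)
  tr <- cl$trials
  sc <- tr[tr$stim == "scene", ]
  expect_equal(nrow(sc), 5 * 2 * 2 * 2 * 3)
  counts <- table(sc$scene, paste(sc$side, sc$polarity, sc$extent))
  expect_true(all(counts == 3))         # balanced: all 8 conditions x reps
  sq <- tr[tr$stim == "square", ]
  expect_equal(nrow(sq), 2 * 2 * 2 * 4)
  expect_length(cl$multipliers, 5)
  # reproducible under the same seed
  cl2 <- simulate_cell(p, n_scenes = 5, seed = 21)
  expect_identical(cl$trials$spikes, cl2$trials$spikes)
})

test_that("scene fixtures carry exact annotation", {
  for (shape in c("disk", "halfplane")) {
    for (ori in c(0, 30, 120)) {
      fx <- generate_scene_fixture(seed = 13, object_shape = shape,
                                   orientation_deg = ori)
      pt <- fx$point
      expect_false(any(pt$mask1 & pt$mask2))
      expect_true(any(pt$mask1) && any(pt$mask2))
      rr <- row(pt$mask1) - pt$center[1]; cc <- col(pt$mask1) - pt$center[2]
      expect_true(all((rr^2 + cc^2)[pt$mask1 | pt$mask2] <= pt$radius_px^2))
      # the two sides differ by the configured contrast
      m <- region_means(fx$scene, fx$point)
      expect_gt(abs(mean(m$side1) - mean(m$side2)), 0.15)
      # annotated orientation vs rendered boundary tangent (PCA of the
      # object-side boundary pixels within the CRF disc)
      b <- pt$mask1 &
        (rbind(pt$mask2[-1, ], FALSE) | rbind(FALSE, pt$mask2[-nrow(pt$mask2), ]) |
         cbind(pt$mask2[, -1], FALSE) | cbind(FALSE, pt$mask2[, -ncol(pt$mask2)]))
      idx <- which(b, arr.ind = TRUE)
      ctr <- colMeans(idx)
      sv <- svd(sweep(idx, 2, ctr))
      ang <- atan2(-sv$v[1, 1], sv$v[2, 1]) * 180 / pi  # row axis points down
      dev <- abs((ang - ori + 90) %% 180 - 90)
      expect_lt(dev, 5)
    }
  }
})

test_that("the relative-strength sampler injects the exact count-ratio", {
  set.seed(77)
  pf <- relative_strength_sampler(0.44)
  p <- pf(1)
  expect_equal(p$context_amp_hz / p$square_amp_hz, 0.44)
  expect_equal(p$context_onset_ms, 42)
  expect_true(p$pref_side %in% c("s1", "s2"))
  expect_true(p$local_sign %in% c(-1L, 1L))
})
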