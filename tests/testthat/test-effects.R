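test_that("the counting window is closed-open [40, 300)", {
  expect_equal(count_window(numeric(0)), 0)
  expect_equal(count_window(c(10, 39.9)), 0)
  expect_equal(count_window(c(40, 150, 299.9, 300)), 3)
})

test_that("the Anscombe transform stabilizes Poisson variance near 1/4", {
  expect_equal(anscombe(0), sqrt(0.375))
  expect_equal(anscombe(1), sqrt(1.375))
  expect_error(anscombe(-1), "non-negative")
  set.seed(17)
  v <- var(anscombe(rpois(20000, 20)))
  expect_equal(v, 0.25, tolerance = 0.1)
})

test_that("OMI screening keeps cells at the 0.20 boundary", {
  expect_equal(omi(10, 10), 0)
  expect_equal(omi(10, 0), 1)
  expect_error(omi(0, 0), "both")
  cells <- data.frame(cell = 1:3,
                      r_pref = c(11.9, 12, 30),
                      r_orth = c(8.1, 8, 10))
  # OMIs: 0.19, 0.20, 0.50
  kept <- filter_orientation_selective(cells)
  expect_equal(kept$cell, c(2L, 3L))
  expect_equal(round(omi(11.9, 8.1), 4), 0.19)
})

test_that("balanced noiseless factorial fits recover pure effects", {
  d <- expand.grid(side = c("s1", "s2"), polarity = c("p1", "p2"),
                   rep = 1:3, stringsAsFactors = FALSE)
  delta <- 0.8
  set.seed(1)
  d$y <- 2 + ifelse(d$side == "s1", delta / 2, -delta / 2) +
    rnorm(nrow(d), 0, 1e-4)    # numerically negligible noise
  f <- fit_factorial(d, c("side", "polarity"))
  co <- coef(f$fit)
  expect_equal(unname(co["side1"]), delta / 2, tolerance = 1e-3)
  tab <- f$anova
  expect_equal(tab["polarity", "Sum Sq"], 0, tolerance = 1e-6)
  expect_equal(tab["side:polarity", "Sum Sq"], 0, tolerance = 1e-6)
  expect_gt(tab["side", "Sum Sq"], 0)
  # adding a constant changes no factor sum of squares
  d2 <- d; d2$y <- d$y + 5
  f2 <- fit_factorial(d2, c("side", "polarity"))
  expect_equal(f2$anova[, "Sum Sq"], tab[, "Sum Sq"])
})

test_that("Type II sums of squares match the nested-model-comparison oracle", {
  set.seed(23)
  d <- expand.grid(side = c("s1", "s2"), polarity = c("p1", "p2"),
                   extent = c("full", "patch"), scene = c("a", "b", "c"),
                   rep = 1:3, stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d), 3, 0.5)
  # unbalance the design while keeping every factor cell populated
  d <- d[-sample(which(d$rep == 3), 15), ]
  f <- fit_factorial(d, c("side", "polarity", "extent", "scene"))
  ora <- oracle_type2(d, c("side", "polarity", "extent", "scene"))
  for (tm in names(ora)) {
    row <- which(vapply(rownames(f$anova), function(r)
      setequal(strsplit(r, ":")[[1]], strsplit(tm, ":")[[1]]), logical(1)))
    expect_equal(f$anova[row, "Sum Sq"], ora[[tm]][["ss"]],
                 tolerance = 1e-8, info = tm)
    expect_equal(f$anova[row, "Pr(>F)"], ora[[tm]][["p"]],
                 tolerance = 1e-8, info = tm)
  }
})

test_that("rank-deficient designs are rejected with the aliased terms named", {
  d <- expand.grid(side = c("s1", "s2"), polarity = c("p1", "p2"),
                   rep = 1:2, stringsAsFactors = FALSE)
  d <- d[d$side == "s1" | d$polarity == "p1", ]   # lose one cell entirely
  d$y <- rnorm(nrow(d))
  expect_error(fit_factorial(d, c("side", "polarity")), "aliased")
})

test_that("extracted effects recover the generator's injected differences", {
  p <- preset_paper_calibrated(sigma_scene = 0.3)
  cl <- simulate_cell(p, n_scenes = 12, seed = 41)
  est <- extract_effects(cl)
  expect_equal(est$pref_side, "s1")
  # ground truth on the transformed scale, from the rate integrals and
  # the cell's drawn multipliers
  tm <- seq(0, 299) + 0.5
  lam <- function(ext, side, pol, mult) {
    r <- rate_function(p, list(stim = "scene", extent = ext, side = side,
                               polarity = pol), mult, tm)
    sum(r[tm >= 40]) / 1000
  }
  truth_ext <- function(ext) {
    mean(sapply(cl$multipliers, function(m) {
      mean(sapply(c("pref", "nonpref"), function(pol)
        anscombe(lam(ext, "pref", pol, m)) -
          anscombe(lam(ext, "nonpref", pol, m))))
    }))
  }
  expect_lt(abs(est$effects[["full"]] - truth_ext("full")),
            3 * est$se[["full"]])
  expect_lt(abs(est$effects[["patch"]] - truth_ext("patch")),
            3 * est$se[["patch"]])
  expect_equal(est$effects[["context"]],
               est$effects[["full"]] - est$effects[["patch"]])
  # strong injected effects are flagged significant at alpha = 0.01
  expect_true(all(classify_significance(est)[c("square", "scene")]))
})

test_that("identical full and patch data give a context effect of exactly zero", {
  p <- preset_paper_calibrated()
  cl <- simulate_cell(p, n_scenes = 6, seed = 43)
  tr <- cl$trials
  sc <- tr[tr$stim == "scene", ]
  full <- sc[sc$extent == "full", ]
  patch_copy <- full; patch_copy$extent <- "patch"
  cl$trials <- rbind(tr[tr$stim == "square", ], full, patch_copy)
  est <- extract_effects(cl)
  expect_equal(est$effects[["context"]], 0, tolerance = 1e-12)
  expect_equal(est$effects[["full"]], est$effects[["patch"]])
})

test_that("null cells yield small normalized effects centred on zero", {
  p0 <- preset_paper_calibrated(local_amp_hz = 0, context_amp_hz = 0,
                                square_amp_hz = 0, sigma_scene = 0)
  vals <- sapply(1:8, function(i) {
    cl <- simulate_cell(p0, n_scenes = 8, seed = 600 + i)
    extract_effects(cl)$normalized[["full"]]
  })
  expect_lt(max(abs(vals)), 1)
  expect_lt(abs(mean(vals)), 0.25)
})

test_that("a cell preferring the other physical side is anchored correctly", {
  p <- preset_paper_calibrated(pref_side = "s2")
  cl <- simulate_cell(p, n_scenes = 8, seed = 45)
  est <- extract_effects(cl)
  expect_equal(est$pref_side, "s2")
  expect_gt(est$effects[["square"]], 0)   # anchored: square effect >= 0
  expect_gt(est$effects[["full"]], 0)
})
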