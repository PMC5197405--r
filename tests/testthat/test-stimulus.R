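test_that("region means recover side colors exactly on piecewise-constant scenes", {
  sp <- make_split_scene()
  m <- region_means(sp$scene, sp$point)
  expect_equal(m$side1, c(0.2, 0.4, 0.6))
  expect_equal(m$side2, c(0.6, 0.2, 0.2))
  # uniform image: both sides equal the constant
  u <- sp
  u$scene$pixels[] <- 0.3
  mu <- region_means(u$scene, u$point)
  expect_equal(mu$side1, rep(0.3, 3))
  expect_equal(mu$side2, rep(0.3, 3))
})

test_that("region means on a textured fixture match per-pixel summation", {
  fx <- generate_scene_fixture(seed = 5)
  m <- region_means(fx$scene, fx$point)
  for (side in 1:2) {
    mask <- if (side == 1) fx$point$mask1 else fx$point$mask2
    manual <- sapply(1:3, function(ch) {
      acc <- 0; nn <- 0
      for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask)))
        if (mask[i, j]) { acc <- acc + fx$scene$pixels[i, j, ch]; nn <- nn + 1 }
      acc / nn
    })
    expect_equal(unname(m[[side]]), manual)
  }
})

test_that("empty region masks are rejected with the side named", {
  sp <- make_split_scene()
  expect_error(scene_point(sp$point$center, 90, c(0, -1), sp$point$radius_px,
                           sp$point$mask1 & FALSE, sp$point$mask2),
               "side 1")
})

test_that("color inversion swaps the side means and fixes their midpoint", {
  sp <- make_split_scene()
  m <- region_means(sp$scene, sp$point)
  inv <- invert_colors(sp$scene, sp$point)
  mi <- region_means(inv, sp$point)
  expect_equal(mi$side1, m$side2)
  expect_equal(mi$side2, m$side1)
  # T(x) for a specific pixel: (0.8, 0.6, 0.8) - (0.1, 0.1, 0.1)
  px <- sp$scene
  px$pixels[1, 1, ] <- c(0.1, 0.1, 0.1)
  expect_equal(invert_colors(px, sp$point)$pixels[1, 1, ], c(0.7, 0.5, 0.7))
  # the mean color is a fixed point of T
  mid <- (m$side1 + m$side2) / 2
  px$pixels[1, 1, ] <- mid
  expect_equal(invert_colors(px, sp$point)$pixels[1, 1, ], unname(mid))
})

test_that("color inversion is an involution where nothing clips", {
  fx <- generate_scene_fixture(seed = 7)
  inv <- invert_colors(fx$scene, fx$point)
  if (attr(inv, "clipped") == 0) {
    back <- invert_colors(inv, fx$point,
                          means = region_means(fx$scene, fx$point))
    expect_equal(back$pixels, fx$scene$pixels)
  }
  # forced clipping is counted
  hot <- fx$scene
  hot$pixels[1:3, 1:3, ] <- 1
  hot$pixels[4:6, 4:6, ] <- 0
  inv2 <- invert_colors(hot, fx$point)
  expect_true(all(inv2$pixels >= 0 & inv2$pixels <= 1))
  expect_true(attr(inv2, "clipped") >= 0)
})

test_that("180-degree rotation reverses a 3x3 grid about its center", {
  px <- array(0, dim = c(3, 3, 3))
  px[, , 1] <- matrix(1:9 / 10, 3, 3)
  px[, , 2] <- px[, , 1]; px[, , 3] <- px[, , 1]
  disc <- matrix(TRUE, 3, 3)
  pt <- scene_point(c(2, 2), 0, c(1, 0), 2,
                    disc & row(px[, , 1]) < 2, disc & row(px[, , 1]) > 2)
  rot <- rotate_180(scene_image(px, 0.05), pt, background = c(0, 0, 0))
  # index-arithmetic oracle: out[i, j] = in[4 - i, 4 - j]
  for (i in 1:3) for (j in 1:3)
    expect_equal(rot$pixels[i, j, 1], px[4 - i, 4 - j, 1])
  expect_equal(rot$pixels[2, 2, ], px[2, 2, ])   # center is a fixed point
})

test_that("rotating twice restores the original image (odd dims, central point)", {
  fx <- generate_scene_fixture(seed = 3)
  r1 <- rotate_180(fx$scene, fx$point, background = c(0, 0, 0))
  r2 <- rotate_180(r1, fx$point, background = c(0, 0, 0))
  expect_equal(r2$pixels, fx$scene$pixels)
})

test_that("rotation swaps the roles of the two region masks", {
  sp <- make_split_scene()
  rot <- rotate_180(sp$scene, sp$point)
  m <- region_means(rot, sp$point)
  expect_equal(m$side1, c(0.6, 0.2, 0.2))
  expect_equal(m$side2, c(0.2, 0.4, 0.6))
})

test_that("patch fading weight follows the erfc profile", {
  expect_equal(patch_alpha(5, 5, 1.8), 1)              # continuous at d = r
  expect_equal(patch_alpha(6, 5, 1.8), 0.0109095, tolerance = 1e-5)
  expect_equal(patch_alpha(0, 5, 1.8), 1)
  d <- seq(0, 30, by = 0.25)
  a <- patch_alpha(d, 5, 1.8)
  expect_true(all(diff(a) <= 1e-12))                   # non-increasing
  expect_lt(patch_alpha(30, 5, 1.8), 1e-12)            # -> 0 far away
  expect_error(patch_alpha(1, -1, 1.8), "r must be")
  expect_error(patch_alpha(1, 5, 0), "k must be")
})

test_that("patch blending matches the per-pixel loop oracle", {
  fx <- generate_scene_fixture(seed = 9, dims = c(33L, 33L), radius_px = 5)
  bg <- background_color(fx$scene, fx$point)
  got <- make_patch(fx$scene, fx$point, k = 1.8, background = bg)
  expect_equal(got$pixels, oracle_patch_blend(fx$scene, fx$point, 1.8, bg))
  # identity inside r
  ctr <- fx$point$center
  expect_equal(got$pixels[ctr[1], ctr[2], ], fx$scene$pixels[ctr[1], ctr[2], ])
  # equals background far from the center
  expect_equal(got$pixels[1, 1, ], unname(bg), tolerance = 1e-9)
})

test_that("background color is the midpoint of the side means", {
  sp <- make_split_scene()
  expect_equal(unname(background_color(sp$scene, sp$point)), c(0.4, 0.3, 0.4))
})

test_that("the factorial variant set has 8 keyed displays with a fixed local stimulus", {
  fx <- generate_scene_fixture(seed = 11)
  vs <- build_variant_set(fx$scene, fx$point, k = 1.8, scene_id = 7L)
  expect_length(vs, 8L)
  keys <- sapply(vs, function(v)
    paste(v$key$side, v$key$polarity, v$key$extent))
  expect_equal(sort(keys), sort(apply(expand.grid(
    c("original", "rotated"), c("original", "inverted"),
    c("full", "patch")), 1, paste, collapse = " ")))
  expect_true(all(sapply(vs, function(v) v$key$scene_id == 7L)))
  # all variants share one background
  bgs <- t(sapply(vs, function(v) v$background))
  expect_equal(max(apply(bgs, 2, function(col) diff(range(col)))), 0)
  # within radius r, full and patch are pixel-identical per (side, polarity)
  r <- fx$point$radius_px; ctr <- fx$point$center
  px1 <- fx$scene$pixels[, , 1]
  inside <- (row(px1) - ctr[1])^2 + (col(px1) - ctr[2])^2 < r^2
  for (side in c("original", "rotated")) {
    for (pol in c("original", "inverted")) {
      pair <- Filter(function(v)
        v$key$side == side && v$key$polarity == pol, vs)
      for (ch in 1:3) {
        expect_equal(pair[[1]]$image$pixels[, , ch][inside],
                     pair[[2]]$image$pixels[, , ch][inside])
      }
    }
  }
})

test_that("the square test is counterbalanced within the swept region", {
  pitch <- 0.05
  sq <- build_square_test_set(sizes_deg = c(1, 2), pitch = pitch,
                              dims = c(201L, 201L))
  expect_length(sq, 8L)
  ctr <- c(101, 101)
  for (size in c(1, 2)) {
    w <- size / pitch
    of <- function(side, pol) Filter(function(v)
      v$key$size_deg == size && v$key$side == side &&
        v$key$polarity == pol, sq)[[1]]
    # displays with opposite side and opposite polarity are identical
    # within the 2w x w strip swept by the two square placements
    rr <- row(matrix(0, 201, 201)) - ctr[1]
    cc <- col(matrix(0, 201, 201)) - ctr[2]
    # swept region: the union of the two square placements,
    # un = -rr in [-w, w), ut = cc in [-w/2, w/2)
    strip <- -rr >= -w & -rr < w & abs(cc) <= w / 2 - 1
    for (ch in 1:3) {
      expect_equal(of("left", "A")$image$pixels[, , ch][strip],
                   of("right", "B")$image$pixels[, , ch][strip])
      expect_equal(of("left", "B")$image$pixels[, , ch][strip],
                   of("right", "A")$image$pixels[, , ch][strip])
    }
    # the square covers exactly (size / pitch)^2 pixels
    img <- of("left", "A")$image$pixels
    is_pref <- img[, , 1] == 1 & img[, , 2] == 0.2
    expect_equal(sum(is_pref), w^2)
  }
})

test_that("gamma encode/decode is the display power law and a round trip", {
  expect_equal(gamma_encode(0), 0)
  expect_equal(gamma_encode(1), 1)
  expect_equal(gamma_encode(0.5), 0.5^2.2)
  x <- seq(0, 1, by = 0.05)
  expect_equal(gamma_decode(gamma_encode(x)), x, tolerance = 1e-9)
  expect_error(gamma_encode(1.5), "must lie")
})
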