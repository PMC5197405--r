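# Stimulus construction: factorial natural-scene variants and the
# counterbalanced square test. All image processing happens in linear RGB
# with channel values in [0, 1]; gamma applies only at display
# import/export (see gamma_encode / gamma_decode).

#' Create a scene image
#'
#' A scene image is a height x width x 3 array of linear-light RGB values
#' in \[0, 1\] together with the pixel pitch (degrees of visual angle per
#' pixel).
#'
#' @param pixels numeric array \[rows, cols, 3\], values in \[0, 1\].
#' @param pitch degrees of visual angle per pixel (> 0).
#' @return An object of class `scene_image`.
#' @export
scene_image <- function(pixels, pitch = 0.05) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!all(is.finite(pixels))) stop("pixel values must be finite")
  if (!(is.numeric(pitch) && length(pitch) == 1L && pitch > 0))
    stop("pitch must be a single positive number")
  structure(list(pixels = pixels, pitch = pitch), class = "scene_image")
}

#' Annotated contour point on a scene
#'
#' Describes one test point on an occluding contour: the pixel at the
#' center of the classical receptive field (CRF), the local contour
#' orientation, which side the occluding object is on, the approximate
#' CRF radius, and two hand-segmented region masks (the two sides of the
#' border restricted to the CRF disc).
#'
#' @param center integer (row, col), 1-based pixel coordinates.
#' @param orientation_deg contour orientation in degrees,
#'   counterclockwise from horizontal, in \[0, 180).
#' @param object_side unit 2-vector (drow, dcol) pointing from the
#'   contour toward the occluding object.
#' @param radius_px CRF radius in pixels (> 0).
#' @param mask1,mask2 logical matrices (same rows/cols as the scene);
#'   TRUE marks pixels belonging to side 1 / side 2. Both must be
#'   non-empty, disjoint, and lie within the CRF disc.
#' @param dims integer (rows, cols) of the scene the masks refer to.
#' @return An object of class `scene_point`.
#' @export
scene_point <- function(center, orientation_deg, object_side, radius_px,
                        mask1, mask2, dims = dim(mask1)) {
  stopifnot(length(center) == 2L, radius_px > 0,
            is.logical(mask1), is.logical(mask2),
            all(dim(mask1) == dims), all(dim(mask2) == dims))
  if (orientation_deg < 0 || orientation_deg >= 180)
    stop("orientation_deg must lie in [0, 180)")
  if (!any(mask1)) stop("region mask for side 1 is empty")
  if (!any(mask2)) stop("region mask for side 2 is empty")
  if (any(mask1 & mask2)) stop("region masks must be disjoint")
  rr <- row(mask1) - center[1]; cc <- col(mask1) - center[2]
  inside <- (rr^2 + cc^2) <= radius_px^2
  if (any((mask1 | mask2) & !inside))
    stop("region masks must lie within the CRF disc")
  ns <- sqrt(sum(object_side^2))
  if (ns == 0) stop("object_side must be a nonzero vector")
  structure(list(center = as.numeric(center),
                 orientation_deg = orientation_deg,
                 object_side = as.numeric(object_side) / ns,
                 radius_px = radius_px,
                 mask1 = mask1, mask2 = mask2),
            class = "scene_point")
}

#' Complementary error function
#'
#' @param x numeric vector.
#' @return erfc(x) = 2 * pnorm(-sqrt(2) * x).
#' @export
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Mean colors on the two sides of the border
#'
#' Channelwise mean of the pixels under each region mask (the two sides
#' of the contour within the CRF disc).
#'
#' @param scene a [scene_image].
#' @param point a [scene_point].
#' @return list with components `side1` and `side2`, each an RGB triple.
#' @export
region_means <- function(scene, point) {
  px <- scene$pixels
  mean_under <- function(mask, label) {
    if (!any(mask)) stop("region mask for ", label, " is empty")
    vapply(1:3, function(ch) mean(px[, , ch][mask]), numeric(1))
  }
  list(side1 = mean_under(point$mask1, "side 1"),
       side2 = mean_under(point$mask2, "side 2"))
}

#' Background color for a scene point
#'
#' The uniform background shown around the stimuli and during
#' interstimulus intervals: the average color within the CRF, i.e. the
#' midpoint of the two region means.
#'
#' @inheritParams region_means
#' @return RGB triple.
#' @export
background_color <- function(scene, point) {
  m <- region_means(scene, point)
  (m$side1 + m$side2) / 2
}

#' Invert edge-contrast polarity about the local mean colors
#'
#' Applies T(x) = (m1 + m2) - x to every pixel, where m1 and m2 are the
#' mean colors on the two sides of the border within the CRF (computed
#' from the *original*, unrotated scene). This swaps the two local mean
#' colors, reversing the edge contrast polarity inside the CRF while
#' keeping the mean color fixed. Out-of-gamut values are clipped to
#' \[0, 1\] and the number of clipped pixel-channels is reported in the
#' `clipped` attribute.
#'
#' @inheritParams region_means
#' @param means optional precomputed [region_means] result (so that
#'   means from the original scene can be reused on derived images).
#' @return A [scene_image] with attribute `clipped`.
#' @export
invert_colors <- function(scene, point, means = region_means(scene, point)) {
  s <- means$side1 + means$side2
  px <- scene$pixels
  for (ch in 1:3) px[, , ch] <- s[ch] - px[, , ch]
  nclip <- sum(px < 0 | px > 1)
  px[px < 0] <- 0; px[px > 1] <- 1
  out <- scene_image(px, scene$pitch)
  attr(out, "clipped") <- nclip
  out
}

#' Rotate a scene 180 degrees about the CRF center
#'
#' Reverses the side of the occluding object while keeping the contour
#' centered in the CRF at the same orientation. Display regions not
#' covered by the rotated image are filled with `background`.
#'
#' @inheritParams region_means
#' @param background RGB triple used to fill uncovered display area
#'   (default: [background_color]).
#' @return A [scene_image] of the same dimensions.
#' @export
rotate_180 <- function(scene, point,
                       background = background_color(scene, point)) {
  px <- scene$pixels
  nr <- dim(px)[1]; nc <- dim(px)[2]
  r0 <- round(point$center[1]); c0 <- round(point$center[2])
  out <- array(rep(background, each = nr * nc), dim = dim(px))
  src_r <- 2L * r0 - seq_len(nr)
  src_c <- 2L * c0 - seq_len(nc)
  ok_r <- which(src_r >= 1L & src_r <= nr)
  ok_c <- which(src_c >= 1L & src_c <= nc)
  out[ok_r, ok_c, ] <- px[src_r[ok_r], src_c[ok_c], , drop = FALSE]
  scene_image(out, scene$pitch)
}

#' Patch fading weight
#'
#' The opacity profile of the patch condition: 1 inside the CRF radius,
#' erfc\[k (d - r)\] outside, continuous at d = r.
#'
#' @param d distance from the CRF center, pixels (>= 0).
#' @param r CRF radius, pixels (> 0).
#' @param k fading steepness per pixel (> 0); the study value is 1.8.
#' @return weights in (0, 1\].
#' @export
patch_alpha <- function(d, r, k = 1.8) {
  if (!(r > 0)) stop("r must be positive")
  if (!(k > 0)) stop("k must be positive")
  if (any(d < 0)) stop("d must be non-negative")
  ifelse(d < r, 1, erfc(k * (d - r)))
}

#' Fade a scene into the background outside the CRF
#'
#' Builds the patch condition: per-pixel blend alpha * image +
#' (1 - alpha) * background with alpha from [patch_alpha]. Inside the
#' CRF radius the patch is pixel-identical to the input.
#'
#' @inheritParams region_means
#' @param k fading steepness per pixel.
#' @param background RGB triple (default: [background_color]).
#' @return A [scene_image].
#' @export
make_patch <- function(scene, point, k = 1.8,
                       background = background_color(scene, point)) {
  px <- scene$pixels
  nr <- dim(px)[1]; nc <- dim(px)[2]
  d <- sqrt((row(px[, , 1]) - point$center[1])^2 +
            (col(px[, , 1]) - point$center[2])^2)
  a <- patch_alpha(d, point$radius_px, k)
  out <- px
  for (ch in 1:3) out[, , ch] <- a * px[, , ch] + (1 - a) * background[ch]
  scene_image(out, scene$pitch)
}

#' Build the eight factorial variants of a scene
#'
#' Crosses object side (original / rotated 180 degrees about the CRF
#' center), edge-contrast polarity (original / locally color-inverted),
#' and extent (full image / erfc-faded patch). Region means and the
#' background color are computed once from the original scene, so all
#' eight variants share the same background, and within the CRF radius
#' the full and patch variants of the same (side, polarity) are
#' pixel-identical.
#'
#' @inheritParams make_patch
#' @param scene_id identifier carried in each variant's condition key.
#' @return list of 8 `stimulus_variant` objects, each with fields
#'   `key` (side, polarity, extent, scene_id), `image`, `background`.
#' @export
build_variant_set <- function(scene, point, k = 1.8, scene_id = 1L) {
  means <- region_means(scene, point)
  bg <- (means$side1 + means$side2) / 2
  variants <- list()
  for (side in c("original", "rotated")) {
    for (polarity in c("original", "inverted")) {
      img <- scene
      if (polarity == "inverted") img <- invert_colors(img, point, means)
      if (side == "rotated") img <- rotate_180(img, point, bg)
      for (extent in c("full", "patch")) {
        out <- if (extent == "patch") make_patch(img, point, k, bg) else img
        variants[[length(variants) + 1L]] <- structure(
          list(key = list(side = side, polarity = polarity,
                          extent = extent, scene_id = scene_id),
               image = out, background = bg),
          class = "stimulus_variant")
      }
    }
  }
  variants
}

#' Build the standard square border-ownership test set
#'
#' Eight displays: 2 square sizes x 2 sides x 2 edge-contrast
#' polarities. Each display shows a uniform square on one side of an
#' edge that passes through the CRF center at the preferred orientation;
#' the two colors (the cell's preferred color and gray) are
#' counterbalanced between square and background, so that displays with
#' opposite side and opposite polarity are pixel-identical within the
#' 2w x w region swept by the two square placements.
#'
#' @param sizes_deg square side lengths in degrees (default 3 and 8).
#' @param color_pref RGB triple, the cell's preferred color.
#' @param color_gray RGB triple, the gray used for counterbalancing.
#' @param orientation_deg edge orientation, degrees counterclockwise
#'   from horizontal.
#' @param pitch degrees per pixel.
#' @param dims display size in pixels (rows, cols).
#' @param center CRF center (row, col), 1-based; default display center.
#' @return list of 8 `stimulus_variant` objects with keys
#'   (size_deg, side in left/right of edge normal, polarity in A/B).
#' @export
build_square_test_set <- function(sizes_deg = c(3, 8),
                                  color_pref = c(1, 0.2, 0.2),
                                  color_gray = c(0.5, 0.5, 0.5),
                                  orientation_deg = 0,
                                  pitch = 0.05,
                                  dims = c(401L, 401L),
                                  center = (dims + 1) / 2) {
  stopifnot(length(sizes_deg) == 2L)
  theta <- orientation_deg * pi / 180
  u <- c(-sin(theta), cos(theta))       # along-edge direction (row, col)
  nvec <- c(-cos(theta), -sin(theta))   # edge normal ("left" of the edge)
  rr <- matrix(seq_len(dims[1]), dims[1], dims[2]) - center[1]
  cc <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE) - center[2]
  un <- rr * nvec[1] + cc * nvec[2]
  ut <- rr * u[1] + cc * u[2]
  bg_mid <- (color_pref + color_gray) / 2
  fill <- function(mask, col_sq, col_bg) {
    px <- array(rep(col_bg, each = prod(dims)), dim = c(dims, 3L))
    for (ch in 1:3) { p <- px[, , ch]; p[mask] <- col_sq[ch]; px[, , ch] <- p }
    scene_image(px, pitch)
  }
  variants <- list()
  for (size in sizes_deg) {
    w <- size / pitch    # square side in pixels
    for (side in c("left", "right")) {
      tt <- ut >= -w / 2 & ut < w / 2
      mask <- if (side == "left") (un >= 0 & un < w & tt)
              else                (un >= -w & un < 0 & tt)
      for (polarity in c("A", "B")) {
        col_sq <- if (polarity == "A") color_pref else color_gray
        col_bg <- if (polarity == "A") color_gray else color_pref
        variants[[length(variants) + 1L]] <- structure(
          list(key = list(size_deg = size, side = side, polarity = polarity,
                          orientation_deg = orientation_deg),
               image = fill(mask, col_sq, col_bg),
               background = bg_mid),
          class = "stimulus_variant")
      }
    }
  }
  variants
}

#' Gamma encode / decode
#'
#' Display transfer: encode applies V^2.2 (the correction used for the
#' linearized displays); decode applies the inverse power. All pipeline
#' processing is in linear light; these apply only at import/export.
#'
#' @param x numeric array or vector in \[0, 1\].
#' @param gamma exponent (default 2.2).
#' @return transformed values.
#' @export
gamma_encode <- function(x, gamma = 2.2) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("values must lie in [0, 1]")
  x^gamma
}

#' @rdname gamma_encode
#' @export
gamma_decode <- function(x, gamma = 2.2) {
  if (any(x < 0 | x > 1, na.rm = TRUE)) stop("values must lie in [0, 1]")
  x^(1 / gamma)
}
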