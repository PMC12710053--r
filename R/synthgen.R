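# Seeded generator of synthetic germination scenes with exact ground truth.
# Scenes emulate the imaging setup the pipeline assumes: elliptical seed
# coats on a near-black cloth, coat chromaticity following a 2-D Gaussian
# in (R-B, G-B) space, attached radicles of known centerline arc length in
# a colour far from the coat model, and an optional bright calibration
# square of known physical size.

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene parameters
#'
#' Defaults describe a germination tray photographed on non-reflective
#' black cloth: brownish-yellow elliptical seed coats whose (R-B, G-B)
#' chromaticity is Gaussian, pale radicles rendered as constant-colour
#' tubes of known centerline length, and mild sensor noise.
#'
#' @param image_size `(rows, cols)` of the scene raster.
#' @param n_seeds Number of seeds to place.
#' @param coat_axes_px Range of coat semi-axes (major sampled from the
#'   upper half, minor from the lower half), px.
#' @param coat_mean,coat_cov True mean (2-vector) and covariance (2x2 SPD)
#'   of the coat chromaticity in (R-B, G-B) feature units.
#' @param coat_blue Blue channel level of the coat; R and G are blue plus
#'   the sampled features.
#' @param radicle_rgb Constant radicle colour; the default lies far from
#'   the coat model (Mahalanobis distance >> 6) so classification
#'   difficulty is controlled by `coat_cov` alone.
#' @param radicle_len_px Range of radicle centerline arc lengths, px.
#' @param radicle_width_px Radicle tube width, px (odd).
#' @param radicle_curvature `"straight_axis_aligned"` (exact integer
#'   geometry) or `"bezier"` (gently curved).
#' @param background_rgb Background colour (near-black cloth).
#' @param germinated_frac Fraction of seeds carrying a radicle.
#' @param adhesion_prob Probability that a seed is allowed to touch an
#'   already placed seed.
#' @param noise_sigma Additive Gaussian channel noise, 8-bit units.
#' @param box_radicle_frac Fraction of the radicle (nearest the coat)
#'   included in the ground-truth detection box, emulating detector boxes
#'   that truncate long radicles.
#' @param calibration `NULL`, or `list(side_px =, side_mm =)` to embed an
#'   axis-aligned bright calibration square in the top-left corner.
#' @param rng_seed Integer seed; scenes are bit-identical for equal seeds.
#' @return A `scene_params` list.
#' @export
scene_params <- function(image_size = c(200, 200),
                         n_seeds = 3,
                         coat_axes_px = c(9, 16),
                         coat_mean = c(85, 55),
                         coat_cov = matrix(c(36, 8, 8, 25), 2),
                         coat_blue = 70,
                         radicle_rgb = c(235, 235, 228),
                         radicle_len_px = c(20, 60),
                         radicle_width_px = 3,
                         radicle_curvature = c("straight_axis_aligned", "bezier"),
                         background_rgb = c(12, 12, 14),
                         germinated_frac = 1,
                         adhesion_prob = 0,
                         noise_sigma = 1,
                         box_radicle_frac = 0.25,
                         calibration = NULL,
                         rng_seed = 1L) {
  radicle_curvature <- match.arg(radicle_curvature)
  stopifnot(n_seeds >= 0, all(radicle_len_px > 0),
            radicle_width_px >= 1, radicle_width_px %% 2 == 1,
            isSymmetric(unname(coat_cov)), min(eigen(coat_cov)$values) > 0,
            box_radicle_frac >= 0, box_radicle_frac <= 1)
  structure(as.list(environment()), class = "scene_params")
}

#' Draw coat chromaticity features
#'
#' Samples `(R-B, G-B)` features from the generating Gaussian — the exact
#' continuous distribution the renderer quantizes onto the 8-bit raster.
#'
#' @param n Number of draws.
#' @param mean,cov Gaussian parameters (defaults as in [scene_params()]).
#' @return n x 2 numeric matrix.
#' @export
sample_coat_features <- function(n, mean = c(85, 55),
                                 cov = matrix(c(36, 8, 8, 25), 2)) {
  z <- matrix(rnorm(2 * n), n, 2)
  sweep(z %*% chol(cov), 2, mean, "+")
}

# integer-rounded polyline rasterization between two points
line_pixels <- function(p0, p1) {
  n <- max(abs(p1 - p0))
  if (n == 0) return(matrix(p0, 1))
  t <- seq(0, 1, length.out = n + 1)
  cbind(round_half_up(p0[1] + t * (p1[1] - p0[1])),
        round_half_up(p0[2] + t * (p1[2] - p0[2])))
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# pixels within `radius` (Euclidean) of a densely sampled centerline
tube_pixels <- function(samples, radius, rows, cols) {
  xr <- clamp(c(floor(min(samples[, 1]) - radius), ceiling(max(samples[, 1]) + radius)), 0, cols - 1)
  yr <- clamp(c(floor(min(samples[, 2]) - radius), ceiling(max(samples[, 2]) + radius)), 0, rows - 1)
  gx <- xr[1]:xr[2]; gy <- yr[1]:yr[2]
  px <- as.matrix(expand.grid(x = gx, y = gy))
  d2 <- matrix(Inf, nrow(px), 1)
  for (i in seq_len(nrow(samples)))
    d2 <- pmin(d2, (px[, 1] - samples[i, 1])^2 + (px[, 2] - samples[i, 2])^2)
  px[d2 <= radius^2 + 1e-9, , drop = FALSE]
}

mask_from_pixels <- function(px, rows, cols) {
  m <- matrix(FALSE, rows, cols)
  ok <- px[, 1] >= 0 & px[, 1] < cols & px[, 2] >= 0 & px[, 2] < rows
  m[cbind(px[ok, 2] + 1L, px[ok, 1] + 1L)] <- TRUE
  m
}

# Build one seed's geometry.  The radicle centerline is anchored 2 px
# inside the coat boundary (so skeletons stay attached) but the stored
# ground-truth arc length covers only the boundary-to-tip polyline.
make_seed_geometry <- function(center, a, b, dir_angle, germinated, L,
                               curvature, width, rows, cols) {
  ct <- cos(dir_angle); st <- sin(dir_angle)
  # coat ellipse, major axis along dir_angle
  xr <- clamp(c(floor(center[1] - a - 1), ceiling(center[1] + a + 1)), 0, cols - 1)
  yr <- clamp(c(floor(center[2] - a - 1), ceiling(center[2] + a + 1)), 0, rows - 1)
  grid <- as.matrix(expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2]))
  dx <- grid[, 1] - center[1]; dy <- grid[, 2] - center[2]
  u <- dx * ct + dy * st; v <- -dx * st + dy * ct
  coat_px <- grid[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
  coat <- mask_from_pixels(coat_px, rows, cols)

  if (!germinated)
    return(list(coat = coat, radicle = coat & FALSE, arc_length = NA_real_,
                centerline = NULL, stub = coat & FALSE))

  dirv <- c(ct, st)
  pb <- center + a * dirv               # boundary point
  anchor <- center + (a - 2) * dirv     # 2 px inside the coat
  if (curvature == "straight_axis_aligned") {
    tip <- pb + L * dirv
    centerline <- rbind(pb, tip)
    samples_out <- cbind(pb[1] + seq(0, L, by = 0.25) * dirv[1],
                         pb[2] + seq(0, L, by = 0.25) * dirv[2])
    arc <- L
  } else {
    # quadratic Bezier from the boundary, rescaled so the arc length is L
    perp <- c(-dirv[2], dirv[1])
    chord <- 0.9 * L; bulge <- 0.25 * L
    p0 <- pb; p1 <- pb + (chord / 2) * dirv + bulge * perp; p2 <- pb + chord * dirv
    t <- seq(0, 1, length.out = 200)
    bez <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
    len0 <- polyline_length(bez)
    sc <- L / len0
    bez <- sweep(sweep(bez, 2, p0), 2, rep(sc, 2), "*")
    bez <- sweep(bez, 2, p0, "+")
    samples_out <- bez
    centerline <- bez
    arc <- polyline_length(bez)
    tip <- bez[nrow(bez), ]
  }
  # include the in-coat anchor in the rendered tube but not the arc length
  anchor_samples <- cbind(seq(anchor[1], pb[1], length.out = 9),
                          seq(anchor[2], pb[2], length.out = 9))
  all_samples <- rbind(anchor_samples, samples_out)
  radius <- (width - 1) / 2
  tube <- mask_from_pixels(tube_pixels(all_samples, radius, rows, cols), rows, cols)
  # stub: portion of the radicle nearest the coat, for detection boxes
  keep <- max(2L, ceiling(nrow(samples_out) * 0.25))
  stub_samples <- rbind(anchor_samples, samples_out[seq_len(keep), , drop = FALSE])
  stub <- mask_from_pixels(tube_pixels(stub_samples, radius, rows, cols), rows, cols)
  list(coat = coat & !tube, radicle = tube, arc_length = arc,
       centerline = centerline, stub = stub)
}

#' Generate a synthetic germination scene
#'
#' Deterministic for a fixed `rng_seed`.  Each seed carries exact ground
#' truth: disjoint coat and radicle masks, the detection box (coat plus the
#' near-coat fraction of the radicle, reproducing detector boxes that
#' truncate long radicles), class, and the radicle centerline arc length.
#' Seeds that cannot be placed within 100 attempts are skipped with a
#' warning.
#'
#' @param params A `scene_params` object.
#' @return A `synthetic_scene`: list with `image` (a `seed_image`),
#'   `seeds` (per-seed ground truth), `detections` (data frame of boxes),
#'   `labels` (0/1/2 raster), `calibration` (vertices + true area, or
#'   NULL), `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  with_rng_seed(params$rng_seed, {
    rows <- params$image_size[1]; cols <- params$image_size[2]
    img <- array(0, c(rows, cols, 3))
    for (ch in 1:3) img[, , ch] <- params$background_rgb[ch]

    calib <- NULL
    occupied <- matrix(FALSE, rows, cols)
    if (!is.null(params$calibration)) {
      s <- params$calibration$side_px
      off <- c(6, 6)  # (x, y) corner offset
      verts <- rbind(c(off[1], off[2]), c(off[1] + s - 1, off[2]),
                     c(off[1] + s - 1, off[2] + s - 1), c(off[1], off[2] + s - 1))
      sq_rows <- (off[2] + 1):(off[2] + s); sq_cols <- (off[1] + 1):(off[1] + s)
      for (ch in 1:3) img[sq_rows, sq_cols, ch] <- 245
      occupied[sq_rows, sq_cols] <- TRUE
      occupied <- EBImage_dilate(occupied, 7)
      calib <- list(vertices = verts, side_px = s,
                    side_mm = params$calibration$side_mm,
                    true_area_mm2 = params$calibration$side_mm^2)
    }

    seeds <- list()
    dets <- empty_detections()
    labels <- matrix(0L, rows, cols)
    placed <- 0L
    for (i in seq_len(params$n_seeds)) {
      germinated <- runif(1) < params$germinated_frac
      axr <- params$coat_axes_px
      amid <- mean(axr)
      a <- round_half_up(runif(1, amid, axr[2]))
      b <- round_half_up(runif(1, axr[1], amid))
      L <- round_half_up(runif(1, params$radicle_len_px[1], params$radicle_len_px[2]))
      adhere <- runif(1) < params$adhesion_prob
      geom <- NULL
      for (attempt in 1:100) {
        if (params$radicle_curvature == "straight_axis_aligned") {
          dir_angle <- sample(c(0, pi / 2, pi, 3 * pi / 2), 1)
        } else {
          dir_angle <- runif(1, 0, 2 * pi)
        }
        ext <- a + (if (germinated) L else 0) + 3
        lo_x <- 2 + max(0, -cos(dir_angle)) * ext + b
        hi_x <- cols - 3 - max(0, cos(dir_angle)) * ext - b
        lo_y <- 2 + max(0, -sin(dir_angle)) * ext + b
        hi_y <- rows - 3 - max(0, sin(dir_angle)) * ext - b
        if (lo_x >= hi_x || lo_y >= hi_y) next
        center <- c(round_half_up(runif(1, lo_x, hi_x)),
                    round_half_up(runif(1, lo_y, hi_y)))
        g <- make_seed_geometry(center, a, b, dir_angle, germinated, L,
                                params$radicle_curvature,
                                params$radicle_width_px, rows, cols)
        foot <- g$coat | g$radicle
        clearance <- if (adhere) foot else EBImage_dilate(foot, 3)
        if (!any(clearance & occupied)) { geom <- g; break }
      }
      if (is.null(geom)) {
        warning("could not place seed ", i, " after 100 attempts; skipped")
        next
      }
      placed <- placed + 1L
      occupied <- occupied | geom$coat | geom$radicle
      # paint coat with Gaussian chromaticity, radicle with constant colour
      cidx <- which(geom$coat)
      f <- sample_coat_features(length(cidx), params$coat_mean, params$coat_cov)
      n <- rows * cols
      img[cidx] <- params$coat_blue + f[, 1]
      img[cidx + n] <- params$coat_blue + f[, 2]
      img[cidx + 2 * n] <- params$coat_blue
      ridx <- which(geom$radicle)
      img[ridx] <- params$radicle_rgb[1]
      img[ridx + n] <- params$radicle_rgb[2]
      img[ridx + 2 * n] <- params$radicle_rgb[3]
      labels[geom$coat] <- 1L
      labels[geom$radicle] <- 2L
      box <- mask_bbox(geom$coat | geom$stub)
      seeds[[placed]] <- list(seed_id = placed,
                              cls = if (germinated) "germinated" else "non_germinated",
                              box = box, coat = geom$coat, radicle = geom$radicle,
                              arc_length_px = geom$arc_length,
                              centerline = geom$centerline)
      dets <- rbind(dets, data.frame(x_min = box[1], y_min = box[2],
                                     x_max = box[3], y_max = box[4],
                                     cls = seeds[[placed]]$cls, score = 1.0))
    }
    if (params$noise_sigma > 0)
      img <- img + rnorm(length(img), 0, params$noise_sigma)
    img <- array(as.integer(round_half_up(clamp(img, 0, 255))), dim(img))
    structure(list(
      image = seed_image(img, image_id = sprintf("synth-%s",
                                                 params$rng_seed %||% "NA")),
      seeds = seeds, detections = dets, labels = labels,
      calibration = calib, params = params
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %dx%d, %d seeds%s>\n",
              nrow(x$labels), ncol(x$labels), length(x$seeds),
              if (!is.null(x$calibration)) ", calibration square" else ""))
  invisible(x)
}

# binary dilation with a box brush of given (odd) size
EBImage_dilate <- function(mask, size) {
  out <- EBImage::dilate(EBImage::Image(t(mask * 1)),
                         EBImage::makeBrush(size, shape = "box"))
  t(EBImage::imageData(out)) > 0.5
}

#' Render a standalone calibration image
#'
#' A bright square of side `side_px` (optionally rotated) centred in a
#' dark image, with the true corner coordinates and physical area returned
#' alongside — the fixture for calibration-detection tests and synthetic
#' mm-scale recovery.
#'
#' @param side_px Square side, px.
#' @param side_mm Declared physical side, mm.
#' @param image_size `(rows, cols)`.
#' @param angle_deg Rotation about the image centre.
#' @param noise_sigma Additive channel noise (8-bit units).
#' @param rng_seed RNG seed for the noise.
#' @return List with `image` (a `seed_image`), `corners` (4 x 2 true
#'   vertex coordinates), `true_area_mm2`.
#' @export
render_calibration_image <- function(side_px, side_mm,
                                     image_size = c(240, 240),
                                     angle_deg = 0, noise_sigma = 1,
                                     rng_seed = 1L) {
  with_rng_seed(rng_seed, {
    rows <- image_size[1]; cols <- image_size[2]
    cx <- (cols - 1) / 2; cy <- (rows - 1) / 2
    th <- angle_deg * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    h <- side_px / 2
    corners <- t(Rm %*% t(rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h))))
    corners <- sweep(corners, 2, c(cx, cy), "+")
    grid <- as.matrix(expand.grid(x = 0:(cols - 1), y = 0:(rows - 1)))
    rel <- sweep(grid, 2, c(cx, cy))
    loc <- rel %*% Rm          # rotate back into the square's frame
    inside <- abs(loc[, 1]) <= h & abs(loc[, 2]) <= h
    img <- array(10, c(rows, cols, 3))
    m <- mask_from_pixels(grid[inside, , drop = FALSE], rows, cols)
    for (ch in 1:3) { plane <- img[, , ch]; plane[m] <- 245; img[, , ch] <- plane }
    if (noise_sigma > 0) img <- img + rnorm(length(img), 0, noise_sigma)
    img <- array(as.integer(round_half_up(clamp(img, 0, 255))), dim(img))
    list(image = seed_image(img, image_id = "calibration"),
         corners = corners, true_area_mm2 = side_mm^2)
  })
}

#' Ground-truth-driven oracle segmenter backend
#'
#' A test double for a promptable segmenter, answering prompts from the
#' scene's ground truth.  For a box prompt it returns the union of the
#' best-overlapping seed's coat and radicle — clipped to the box when
#' `corruption = "box_clip"`, emulating the coarse stage's truncation of
#' radicles that exit the detection box.  For a point prompt it returns the
#' full union of the first seed containing any prompt point, or an empty
#' mask when no point hits a seed.  `"dilate1"` dilates the returned mask
#' by one pixel to emulate boundary error.
#'
#' @param scene A `synthetic_scene`.
#' @param corruption `"none"`, `"box_clip"`, or `"dilate1"`.
#' @return A `segmenter_backend` (see [segmenter_backend()]).
#' @export
oracle_backend <- function(scene, corruption = c("none", "box_clip", "dilate1")) {
  corruption <- match.arg(corruption)
  stopifnot(inherits(scene, "synthetic_scene"))
  unions <- lapply(scene$seeds, function(s) s$coat | s$radicle)
  rows <- nrow(scene$labels); cols <- ncol(scene$labels)
  predict_fn <- function(image, prompt) {
    out <- matrix(FALSE, rows, cols)
    if (length(unions) == 0L) return(out)
    if (prompt$kind == "box") {
      bm <- box_to_mask(prompt$box, rows, cols)
      ov <- vapply(unions, function(u) sum(u & bm), numeric(1))
      if (max(ov) == 0) return(out)
      out <- unions[[which.max(ov)]]
      if (corruption == "dilate1") out <- EBImage_dilate(out, 3)
      if (corruption == "box_clip") out <- out & bm
    } else {
      for (u in unions) {
        hit <- any(u[cbind(prompt$points[, 2] + 1L, prompt$points[, 1] + 1L)])
        if (hit) { out <- u; break }
      }
      if (corruption == "dilate1" && any(out)) out <- EBImage_dilate(out, 3)
    }
    out
  }
  segmenter_backend(name = paste0("oracle-", corruption),
                    supports = c("box", "points"), predict = predict_fn)
}
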