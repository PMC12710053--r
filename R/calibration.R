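# Pixel-to-millimetre calibration from a quadrilateral reference object of
# known physical area (by default one sixty-fourth of an A4 sheet,
# 210x297/64 = 974.53125 mm^2).

#' Default true area of the calibration object (mm^2)
#'
#' One sixty-fourth of an ISO 216 A4 sheet (210 mm x 297 mm).
#' @export
A4_64_AREA_MM2 <- 210 * 297 / 64

# --- Canny edge detection -------------------------------------------------
# Gaussian smoothing, Sobel gradients, 4-direction non-maximum suppression,
# double-threshold hysteresis.  Thresholds are fractions of the maximum
# gradient magnitude.
canny_edges <- function(gray, sigma = 1.4, low = 0.1, high = 0.25) {
  g <- EBImage::gblur(EBImage::Image(t(gray)), sigma = sigma)
  g <- t(EBImage::imageData(g))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  conv3 <- function(m, k) {
    out <- matrix(0, nrow(m), ncol(m))
    for (i in -1:1) for (j in -1:1)
      out <- out + k[i + 2, j + 2] * shift_mat(m, -i, -j, fill = 0)
    out
  }
  gx <- conv3(g, kx)            # horizontal gradient (columns)
  gy <- conv3(g, t(kx))         # vertical gradient (rows)
  mag <- sqrt(gx^2 + gy^2)
  # suppress the zero-padding artefact along the image border
  nr <- nrow(mag); nc <- ncol(mag)
  mag[c(1:2, nr - 1, nr), ] <- 0
  mag[, c(1:2, nc - 1, nc)] <- 0
  if (max(mag) == 0) return(matrix(FALSE, nrow(gray), ncol(gray)))
  ang <- atan2(gy, gx)                     # quantize to 4 directions
  sector <- floor(((ang + pi) / (pi / 4) + 0.5)) %% 4
  n1 <- matrix(0, nrow(g), ncol(g)); n2 <- n1
  pick <- function(sec, dr, dc) {
    sel <- sector == sec
    n1[sel] <<- shift_mat(mag, dr, dc)[sel]
    n2[sel] <<- shift_mat(mag, -dr, -dc)[sel]
  }
  pick(0, 0, 1)     # 0 deg: compare east/west
  pick(1, -1, -1)   # 45 deg (rows grow downward): (r+1, c+1)/(r-1, c-1)
  pick(2, 1, 0)     # 90 deg: north/south
  pick(3, 1, -1)    # 135 deg: (r-1, c+1)/(r+1, c-1)
  nms <- mag >= n1 & mag >= n2 & mag > 0
  strong <- nms & mag >= high * max(mag)
  weak <- nms & mag >= low * max(mag)
  # hysteresis: weak pixels connected (8-conn) to a strong pixel survive
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(EBImage::imageData(lab))
  keep <- unique(lab[strong & lab > 0])
  weak & lab %in% keep
}

# Smallest-area enclosing rotated rectangle of a point set (rotating
# calipers over convex-hull edge directions).  Points are n x 2 (x, y);
# returns the 4 rectangle corners.
min_area_rect <- function(pts) {
  hull <- pts[chull(pts[, 1], pts[, 2]), , drop = FALSE]
  n <- nrow(hull)
  if (n < 3L) stop("degenerate point set for min-area rectangle")
  best <- NULL; best_area <- Inf
  for (i in seq_len(n)) {
    e <- hull[(i %% n) + 1, ] - hull[i, ]
    len <- sqrt(sum(e^2)); if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (area < best_area) {
      best_area <- area
      best <- rbind(min(pu) * u + min(pv) * v, max(pu) * u + min(pv) * v,
                    max(pu) * u + max(pv) * v, min(pu) * u + max(pv) * v)
    }
  }
  best
}

# Order quad vertices counter-clockwise in standard (x up-right, y up)
# sense, starting from the vertex with smallest (y, x).
order_ccw <- function(q) {
  cx <- mean(q[, 1]); cy <- mean(q[, 2])
  ang <- atan2(q[, 2] - cy, q[, 1] - cx)
  q <- q[order(ang), , drop = FALSE]
  start <- which.min(q[, 2] * 1e9 + q[, 1])
  q[((seq_len(nrow(q)) + start - 2) %% nrow(q)) + 1, , drop = FALSE]
}

#' Detect the quadrilateral calibration object
#'
#' Locates a bright quadrilateral on a dark background: the image is
#' denoised with a morphological opening (erosion then dilation), edges are
#' extracted with a Canny detector, the largest closed contour is selected,
#' and its four vertices are taken as the contour points nearest the
#' corners of its minimum-area rotated bounding rectangle, ordered
#' counter-clockwise.
#'
#' @param image A `seed_image` containing one bright quadrilateral.
#' @param brush_size Diameter of the opening brush (odd, default 3).
#' @return 4 x 2 matrix of `(x, y)` vertex coordinates (0-based pixels).
#' @export
detect_calibration_quad <- function(image, brush_size = 3L) {
  stopifnot(inherits(image, "seed_image"))
  gray <- (image$pixels[, , 1] + image$pixels[, , 2] + image$pixels[, , 3]) / (3 * 255)
  kern <- EBImage::makeBrush(brush_size, shape = "box")
  opened <- EBImage::dilate(EBImage::erode(EBImage::Image(t(gray)), kern), kern)
  opened <- t(EBImage::imageData(opened))
  edges <- canny_edges(opened)
  if (!any(edges)) stop("calibration object not found: no edges detected")
  # closed contour = 8-connected edge component whose filled interior is
  # non-trivial; pick the one with the largest interior
  sg <- build_skeleton_graph(edges)
  memb <- igraph::components(sg$graph)$membership
  best_comp <- 0L; best_area <- 0
  for (k in seq_len(max(memb))) {
    cm <- mask_from_pixels(sg$coords[memb == k, , drop = FALSE],
                           nrow(edges), ncol(edges))
    filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(cm * 1)))))
    interior <- sum(filled > 0.5) - sum(cm)
    if (interior > best_area) { best_area <- interior; best_comp <- k }
  }
  if (best_comp == 0L || best_area < 9)
    stop("calibration object not found: no closed contour")
  pts <- sg$coords[memb == best_comp, , drop = FALSE]
  rect <- min_area_rect(pts)
  # contour point nearest each rectangle corner
  quad <- t(apply(rect, 1, function(corner) {
    d2 <- (pts[, 1] - corner[1])^2 + (pts[, 2] - corner[2])^2
    pts[which.min(d2), ]
  }))
  verts <- order_ccw(quad)
  if (nrow(unique(verts)) < 4L)
    stop("calibration object degenerate: fewer than 4 distinct vertices")
  colnames(verts) <- c("x", "y")
  verts
}

#' Polygon pixel area by the shoelace formula
#'
#' `S_p = 0.5 * |sum_i (x_i y_{i+1} - y_i x_{i+1})|` with cyclic
#' wraparound, for any simple polygon with n >= 3 vertices.
#'
#' @param quad n x 2 matrix of `(x, y)` vertices in boundary order.
#' @return Area in px^2.
#' @export
polygon_pixel_area <- function(quad) {
  quad <- as.matrix(quad)
  stopifnot(ncol(quad) == 2, nrow(quad) >= 3)
  x <- quad[, 1]; y <- quad[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * abs(sum(x * yn - y * xn))
}

#' Pixel-per-millimetre calibration scale
#'
#' `R = sqrt(S_p / S_r)` where `S_p` is the calibration object's pixel
#' area and `S_r` its true physical area.
#'
#' @param pixel_area `S_p` in px^2 (> 0).
#' @param true_area_mm2 `S_r` in mm^2 (> 0); defaults to 1/64 of an A4
#'   sheet.
#' @return A `calibration_scale` list with `pixel_area`, `true_area_mm2`,
#'   `ratio` (px per mm).
#' @export
length_ratio <- function(pixel_area, true_area_mm2 = A4_64_AREA_MM2) {
  if (!is.finite(pixel_area) || pixel_area <= 0)
    stop("length_ratio: pixel area must be positive")
  if (!is.finite(true_area_mm2) || true_area_mm2 <= 0)
    stop("length_ratio: true area must be positive")
  structure(list(pixel_area = pixel_area, true_area_mm2 = true_area_mm2,
                 ratio = sqrt(pixel_area / true_area_mm2)),
            class = "calibration_scale")
}

#' @export
print.calibration_scale <- function(x, ...) {
  cat(sprintf("<calibration_scale %.4f px/mm (S_p=%.1f px^2, S_r=%.3f mm^2)>\n",
              x$ratio, x$pixel_area, x$true_area_mm2))
  invisible(x)
}

#' Convert a pixel length to millimetres
#'
#' `l_r = l_p / R`, the inverse of the pixel-per-mm ratio.
#'
#' @param pixel_length Length in px (>= 0).
#' @param scale A `calibration_scale`.
#' @return Length in mm.
#' @export
to_true_length <- function(pixel_length, scale) {
  stopifnot(inherits(scale, "calibration_scale"), pixel_length >= 0)
  pixel_length / scale$ratio
}

#' Write / read a calibration scale as JSON
#'
#' @param scale A `calibration_scale`.
#' @param path JSON path.
#' @export
write_scale <- function(scale, path) {
  jsonlite::write_json(unclass(scale), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  x <- jsonlite::fromJSON(path)
  length_ratio(x$pixel_area, x$true_area_mm2)
}
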