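# Gaussian chromaticity model of the seed coat and coat/radicle pixel
# classification.  Features are the brightness-shift-invariant pair
# (R - B, G - B), kept as signed reals.

#' Centroid of a binary mask
#'
#' The arithmetic mean of the member pixel coordinates, snapped to the mask
#' pixel nearest the mean (ties broken by smallest (row, col)).  Snapping
#' matters for concave masks whose mean falls outside the mask — the
#' centroid is used as a segmentation prompt and as the centre of the
#' colour-model training patch, so it must be a real mask pixel.
#'
#' @param mask Logical matrix.
#' @return Integer vector `(x, y)`, 0-based (x = column, y = row).
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask_centroid: empty mask (degenerate segmentation)")
  my <- mean(idx[, 1]) - 1          # 0-based row
  mx <- mean(idx[, 2]) - 1          # 0-based col
  d2 <- (idx[, 1] - 1 - my)^2 + (idx[, 2] - 1 - mx)^2
  # nearest mask pixel; among ties the smallest (row, col)
  best <- min(d2)
  cand <- which(d2 <= best + 1e-12)
  ord <- order(idx[cand, 1], idx[cand, 2])
  pick <- cand[ord[1]]
  c(x = unname(idx[pick, 2]) - 1L, y = unname(idx[pick, 1]) - 1L)
}

#' Chromaticity features of an image patch
#'
#' Extracts the (R - B, G - B) features of the `size` x `size` window
#' centred on `center`, clipped to the image bounds (so a corner centre
#' yields 4 samples for size 3).
#'
#' @param image A `seed_image`.
#' @param center `(x, y)` pixel, 0-based, inside the image.
#' @param size Odd window size (default 3).
#' @return Numeric matrix with one row per pixel and columns `rb`, `gb`.
#' @export
sample_patch_features <- function(image, center, size = 3L) {
  stopifnot(inherits(image, "seed_image"), size >= 1L, size %% 2L == 1L)
  d <- dim(image$pixels)
  cx <- center[1]; cy <- center[2]
  if (cx < 0 || cy < 0 || cx >= d[2] || cy >= d[1])
    stop("patch centre outside image")
  h <- (size - 1L) / 2L
  rows <- max(0L, cy - h):min(d[1] - 1L, cy + h) + 1L
  cols <- max(0L, cx - h):min(d[2] - 1L, cx + h) + 1L
  r <- as.numeric(image$pixels[rows, cols, 1])
  g <- as.numeric(image$pixels[rows, cols, 2])
  b <- as.numeric(image$pixels[rows, cols, 3])
  cbind(rb = r - b, gb = g - b)
}

#' Fit the Gaussian coat model
#'
#' Sample mean and covariance (denominator n - 1) of chromaticity features.
#' When the covariance is (near-)singular — common for uniform patches — a
#' ridge `lambda = ridge_floor * max(trace(C), 1)` is added so the model
#' stays evaluable; the applied ridge is recorded on the model.
#'
#' @param features Feature matrix from [sample_patch_features()]; at least
#'   2 rows.
#' @param ridge_floor Relative ridge used for degenerate covariances.
#' @return A `gaussian_coat_model` with fields `m`, `C`, `lambda`, `C_inv`.
#' @export
fit_gaussian <- function(features, ridge_floor = 1e-6) {
  features <- as.matrix(features)
  if (nrow(features) < 2L) stop("fit_gaussian: need at least 2 samples")
  m <- colMeans(features)
  C <- cov(features)
  lambda <- 0
  if (det(C) < 1e-12) lambda <- ridge_floor * max(sum(diag(C)), 1)
  Creg <- C + diag(lambda, 2)
  structure(list(m = m, C = C, lambda = lambda, C_inv = solve(Creg)),
            class = "gaussian_coat_model")
}

#' @export
print.gaussian_coat_model <- function(x, ...) {
  cat(sprintf("<gaussian_coat_model m=(%.2f, %.2f) lambda=%g>\n",
              x$m[1], x$m[2], x$lambda))
  invisible(x)
}

#' Coat membership probability of chromaticity features
#'
#' `exp(-0.5 * (f - m)' (C + lambda I)^{-1} (f - m))`: the Gaussian density
#' kernel without its normalizing constant, so the value at the mean is
#' exactly 1.
#'
#' @param model A `gaussian_coat_model`.
#' @param features Feature matrix (rows are pixels) or a single 2-vector.
#' @return Numeric vector of probabilities in (0, 1\].
#' @export
coat_probability <- function(model, features) {
  stopifnot(inherits(model, "gaussian_coat_model"))
  f <- if (is.null(dim(features))) matrix(features, 1) else as.matrix(features)
  d <- sweep(f, 2, model$m)
  q <- rowSums((d %*% model$C_inv) * d)
  exp(-0.5 * pmax(q, 0))
}

#' Classify a seed mask into coat and radicle
#'
#' A mask pixel is seed coat iff its coat probability strictly exceeds the
#' threshold `T`; otherwise it is radicle.  The two output masks always
#' partition the input mask exactly.
#'
#' @param image A `seed_image`.
#' @param seed_mask Logical matrix, non-empty.
#' @param model A `gaussian_coat_model`.
#' @param threshold Classification threshold in (0, 1); default 0.006.
#' @param seed_id Identifier attached to the result.
#' @return A `component_masks` list with logical matrices `coat`,
#'   `radicle`, and `seed_id`.
#' @export
classify_mask <- function(image, seed_mask, model, threshold = 0.006,
                          seed_id = NA_integer_) {
  stopifnot(inherits(model, "gaussian_coat_model"),
            threshold > 0, threshold < 1, any(seed_mask))
  idx <- which(seed_mask)
  d <- dim(image$pixels)
  n <- d[1] * d[2]
  r <- as.numeric(image$pixels[idx])
  g <- as.numeric(image$pixels[idx + n])
  b <- as.numeric(image$pixels[idx + 2 * n])
  p <- coat_probability(model, cbind(r - b, g - b))
  coat <- matrix(FALSE, d[1], d[2])
  radicle <- matrix(FALSE, d[1], d[2])
  coat[idx[p > threshold]] <- TRUE
  radicle[idx[p <= threshold]] <- TRUE
  structure(list(coat = coat, radicle = radicle, seed_id = seed_id),
            class = "component_masks")
}
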