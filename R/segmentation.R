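# Prompt construction and coarse/fine segmentation orchestration over a
# pluggable promptable-segmenter contract.  The package never implements a
# neural segmenter itself: any backend satisfying the contract (one binary
# mask of image shape per prompt, deterministic for identical inputs) can
# be plugged in, and the oracle backend drives the test suite.

#' Promptable segmenter contract
#'
#' Wraps a segmentation backend: `predict(image, prompt)` must return one
#' binary mask of the image shape for one prompt, deterministically.
#'
#' @param name Backend name (used in the config registry).
#' @param supports Character subset of `c("box", "points")`.
#' @param predict Function `(seed_image, prompt) -> logical matrix`.
#' @return A `segmenter_backend` object.
#' @export
segmenter_backend <- function(name, supports, predict) {
  stopifnot(is.function(predict), all(supports %in% c("box", "points")),
            length(supports) >= 1)
  structure(list(name = name, supports = supports, predict = predict),
            class = "segmenter_backend")
}

#' @export
print.segmenter_backend <- function(x, ...) {
  cat(sprintf("<segmenter_backend '%s' [%s]>\n", x$name,
              paste(x$supports, collapse = ", ")))
  invisible(x)
}

#' Segmentation prompts
#'
#' @param box Half-open pixel box `(x_min, y_min, x_max, y_max)`, 0-based.
#' @return A `prompt` object of kind `"box"` or `"points"`.
#' @export
box_prompt <- function(box) {
  check_box(box)
  structure(list(kind = "box", box = as.numeric(box)), class = "prompt")
}

#' @rdname box_prompt
#' @param points n x 2 matrix (or single `(x, y)` vector) of foreground
#'   pixel coordinates, 0-based.
#' @export
point_prompt <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, 1)
  stopifnot(nrow(points) >= 1, ncol(points) == 2)
  structure(list(kind = "points", points = points), class = "prompt")
}

new_seed_mask <- function(seed_id, mask, source, flags = character(0)) {
  structure(list(seed_id = seed_id, mask = mask, source = source,
                 flags = flags), class = "seed_mask")
}

#' Coarse segmentation from detection boxes
#'
#' One box prompt per detection, in detection order.  Returned masks are
#' intersected with their prompting box: prompt-driven segmenters keep box
#' results inside the box, and enforcing it here makes that documented
#' coarse-stage behaviour backend-independent — which is exactly what lets
#' the fine stage later recover radicle portions the box truncated.
#' Backend failures and empty masks are flagged, never fatal.
#'
#' @param image A `seed_image`.
#' @param detections Detection data frame (see [load_detections()]).
#' @param backend A `segmenter_backend` accepting box prompts.
#' @return List of `seed_mask` objects (source `"coarse"`), one per
#'   detection, `seed_id` = detection index.
#' @export
coarse_segment <- function(image, detections, backend) {
  stopifnot(inherits(backend, "segmenter_backend"),
            "box" %in% backend$supports)
  d <- dim(image$pixels)
  lapply(seq_len(nrow(detections)), function(i) {
    box <- as.numeric(detections[i, c("x_min", "y_min", "x_max", "y_max")])
    mask <- tryCatch(backend$predict(image, box_prompt(box)),
                     error = function(e) NULL)
    if (is.null(mask))
      return(new_seed_mask(i, matrix(FALSE, d[1], d[2]), "coarse",
                           "backend_error"))
    mask <- mask & box_to_mask(box, d[1], d[2])
    flags <- if (!any(mask)) "empty_mask" else character(0)
    new_seed_mask(i, mask, "coarse", flags)
  })
}

#' Fine segmentation from centroid point prompts
#'
#' One point prompt per seed containing the coat centroid and, when the
#' seed has a classified radicle, the radicle centroid, both as foreground
#' points.  Unlike the coarse stage the result is not clipped to any box —
#' this is what completes radicles the detection box truncated.
#'
#' @param image A `seed_image`.
#' @param seed_components List of `list(seed_id, coat_centroid,
#'   radicle_centroid)` with 0-based `(x, y)` centroids
#'   (`radicle_centroid` NULL for non-germinated seeds).
#' @param backend A `segmenter_backend` accepting point prompts.
#' @return List of `seed_mask` objects (source `"fine"`), in input order.
#' @export
fine_segment <- function(image, seed_components, backend) {
  stopifnot(inherits(backend, "segmenter_backend"),
            "points" %in% backend$supports)
  d <- dim(image$pixels)
  lapply(seed_components, function(sc) {
    if (is.null(sc$coat_centroid))
      return(new_seed_mask(sc$seed_id, matrix(FALSE, d[1], d[2]), "fine",
                           "skeleton_disconnected"))
    pts <- rbind(sc$coat_centroid,
                 if (!is.null(sc$radicle_centroid)) sc$radicle_centroid)
    mask <- tryCatch(backend$predict(image, point_prompt(pts)),
                     error = function(e) NULL)
    if (is.null(mask))
      return(new_seed_mask(sc$seed_id, matrix(FALSE, d[1], d[2]), "fine",
                           "backend_error"))
    flags <- if (!any(mask)) "empty_mask" else character(0)
    new_seed_mask(sc$seed_id, mask, "fine", flags)
  })
}
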