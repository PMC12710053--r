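#' Load an RGB seed image
#'
#' Reads a PNG or JPEG image into a `seed_image`: an 8-bit RGB raster stored
#' as an integer array of dimension rows x cols x 3 with values in
#' \[0, 255\] and channel order R, G, B.  Grayscale inputs are replicated
#' across the three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a PNG or JPEG file.
#' @param image_id Identifier recorded with the image; defaults to the file
#'   name without extension.
#' @return A `seed_image` object with fields `pixels`, `image_id`, `path`.
#' @export
load_image <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stop("cannot decode image '", path, "': ",
                                           conditionMessage(e)))
  a <- EBImage::imageData(img)          # EBImage stores [x, y(, c)]
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  px <- aperm(a, c(2L, 1L, 3L))          # -> rows x cols x 3
  px <- array(as.integer(round_half_up(clamp(px, 0, 1) * 255)), dim(px))
  seed_image(px, image_id = image_id %||% sub("\\.[^.]*$", "", basename(path)),
             path = path)
}

#' Construct a seed_image from a pixel array
#'
#' @param pixels Integer array rows x cols x 3, values in \[0, 255\].
#' @param image_id,path Identity metadata.
#' @return A `seed_image` object.
#' @export
seed_image <- function(pixels, image_id = "image", path = NA_character_) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L,
            dim(pixels)[1] >= 1L, dim(pixels)[2] >= 1L)
  if (min(pixels) < 0L || max(pixels) > 255L)
    stop("pixel values must lie in [0, 255]")
  structure(list(pixels = pixels, image_id = image_id, path = path),
            class = "seed_image")
}

#' @export
print.seed_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<seed_image '%s' %dx%d RGB>\n", x$image_id, d[1], d[2]))
  invisible(x)
}

#' Write a seed_image to a PNG file
#'
#' @param image A `seed_image`.
#' @param path Output PNG path.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "seed_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Load seed detections
#'
#' Parses per-image seed detections in either the normalized YOLO text
#' dialect (`"cls cx cy w h"` per line, coordinates relative to the image)
#' or a JSON list of absolute-pixel boxes.  Boxes are returned 0-based and
#' half-open, clipped to the image bounds; boxes with zero area after
#' clipping are dropped with a warning.
#'
#' @param path Detection file path.
#' @param fmt `"yolo_txt"` or `"json"`.
#' @param image_shape `(rows, cols)` of the image the detections refer to.
#' @param class_map Named map from YOLO class index to class name; the
#'   default follows the convention 0 = non_germinated, 1 = germinated.
#' @return A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`,
#'   `cls`, `score`.
#' @export
load_detections <- function(path, fmt = c("yolo_txt", "json"), image_shape,
                            class_map = c(`0` = "non_germinated",
                                          `1` = "germinated")) {
  fmt <- match.arg(fmt)
  rows <- image_shape[1]; cols <- image_shape[2]
  if (fmt == "yolo_txt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    dets <- lapply(seq_along(lines), function(i) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      if (length(parts) < 5L || anyNA(suppressWarnings(as.numeric(parts[1:5]))))
        stop("malformed detection line ", i, " in ", path, ": '", lines[i], "'")
      v <- as.numeric(parts[1:5])
      cls <- class_map[[as.character(as.integer(v[1]))]]
      if (is.null(cls)) stop("unknown class index ", v[1], " at line ", i)
      data.frame(x_min = (v[2] - v[4] / 2) * cols, y_min = (v[3] - v[5] / 2) * rows,
                 x_max = (v[2] + v[4] / 2) * cols, y_max = (v[3] + v[5] / 2) * rows,
                 cls = cls,
                 score = if (length(parts) >= 6L) as.numeric(parts[6]) else 1.0)
    })
    det <- do.call(rbind, dets)
    if (is.null(det)) det <- empty_detections()
  } else {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    det <- if (length(raw) == 0L) empty_detections() else
      data.frame(x_min = raw$x_min, y_min = raw$y_min,
                 x_max = raw$x_max, y_max = raw$y_max,
                 cls = raw$cls,
                 score = if (!is.null(raw$score)) raw$score else 1.0)
  }
  clip_detections(det, rows, cols)
}

empty_detections <- function() {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), cls = character(0), score = numeric(0))
}

clip_detections <- function(det, rows, cols) {
  if (nrow(det) == 0L) return(det)
  det$x_min <- clamp(det$x_min, 0, cols); det$x_max <- clamp(det$x_max, 0, cols)
  det$y_min <- clamp(det$y_min, 0, rows); det$y_max <- clamp(det$y_max, 0, rows)
  ok <- det$x_max > det$x_min & det$y_max > det$y_min
  if (any(!ok))
    warning(sum(!ok), " detection(s) dropped: zero area after clipping")
  bad_cls <- !det$cls %in% c("germinated", "non_germinated")
  if (any(bad_cls)) stop("unknown detection class: ", det$cls[which(bad_cls)[1]])
  det <- det[ok, , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Write detections as JSON
#'
#' @param detections Data frame as returned by [load_detections()].
#' @param path Output path.
#' @export
write_detections <- function(detections, path) {
  jsonlite::write_json(detections, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read / write label masks
#'
#' Label masks code each pixel as 0 = background, 1 = seed coat,
#' 2 = radicle, serialized as an 8-bit grayscale PNG holding the raw label
#' values.
#'
#' @param labels Integer matrix with values in \{0, 1, 2\}.
#' @param path PNG path.
#' @return `load_mask` returns the integer label matrix.
#' @export
write_mask <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels %in% 0:2))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
load_mask <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  lab <- matrix(as.integer(round_half_up(m * 255)), nrow(m), ncol(m))
  if (!all(lab %in% 0:2)) stop("not a {0,1,2} label mask: ", path)
  lab
}

# Masks (coat, radicle) -> label raster and back.
masks_to_labels <- function(coat, radicle) {
  lab <- matrix(0L, nrow(coat), ncol(coat))
  lab[coat] <- 1L
  lab[radicle] <- 2L
  lab
}

labels_to_masks <- function(labels) {
  list(coat = labels == 1L, radicle = labels == 2L)
}

measurement_columns <- c("image_id", "seed_id", "class", "x_min", "y_min",
                         "x_max", "y_max", "pixel_length", "ratio",
                         "true_length_mm", "flags")

#' Write per-seed measurement records to CSV
#'
#' Columns: image_id, seed_id, class, x_min, y_min, x_max, y_max,
#' pixel_length, ratio, true_length_mm, flags.  Floats are printed with 4
#' decimal places; absent optionals (ratio, true_length_mm) are empty
#' strings; multiple flags are ";"-joined.
#'
#' @param records Data frame of seed records as returned by
#'   [measure_image()].
#' @param path Output CSV path.
#' @export
write_measurements <- function(records, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.4f", x))
  out <- data.frame(
    image_id = as.character(records$image_id),
    seed_id = records$seed_id,
    class = records$cls,
    x_min = fmt(records$x_min), y_min = fmt(records$y_min),
    x_max = fmt(records$x_max), y_max = fmt(records$y_max),
    pixel_length = fmt(records$pixel_length),
    ratio = fmt(records$ratio),
    true_length_mm = fmt(records$true_length_mm),
    flags = vapply(records$flags, flags_to_string, character(1)),
    stringsAsFactors = FALSE
  )
  if (nrow(records) == 0L)
    out <- setNames(data.frame(matrix(character(0), 0, length(measurement_columns))),
                    measurement_columns)
  names(out) <- measurement_columns
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return Data frame with numeric measurement columns and a list-column
#'   `flags`.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = setNames(rep("character", 11), measurement_columns))
  num <- function(x) suppressWarnings(ifelse(nzchar(x), as.numeric(x), NA_real_))
  data.frame(image_id = df$image_id, seed_id = as.integer(df$seed_id),
             cls = df$class,
             x_min = num(df$x_min), y_min = num(df$y_min),
             x_max = num(df$x_max), y_max = num(df$y_max),
             pixel_length = num(df$pixel_length), ratio = num(df$ratio),
             true_length_mm = num(df$true_length_mm),
             flags = I(lapply(df$flags, string_to_flags)),
             stringsAsFactors = FALSE)
}

#' Load a pipeline configuration from YAML
#'
#' Unspecified keys fall back to the package defaults; see
#' [pipeline_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` object.
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  pipeline_config(
    threshold = cfg$classify$threshold %||% 0.006,
    patch_size = cfg$classify$patch_size %||% 3L,
    ridge_floor = cfg$classify$ridge_floor %||% 1e-6,
    diagonal_weight = cfg$skeleton$diagonal_weight %||% 2,
    backend = cfg$backend %||% "oracle",
    seed = cfg$seed %||% 1L
  )
}
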