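# Five-step measurement pipeline: coarse segmentation -> coarse
# classification -> fine segmentation -> fine classification -> skeleton
# length, plus the pixel-to-mm conversion and the threshold sweep utility.

#' Pipeline configuration
#'
#' @param threshold Coat-probability classification threshold in (0, 1).
#' @param patch_size Odd side of the colour-model training patch, px.
#' @param ridge_floor Relative ridge for degenerate patch covariances.
#' @param diagonal_weight Skeleton-graph diagonal edge weight (2 by
#'   convention; `sqrt(2)` for Euclidean polyline lengths).
#' @param backend Backend registry key (`"oracle"` for the ground-truth
#'   test double; external adapters register their own keys).
#' @param seed RNG seed carried by the configuration.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(threshold = 0.006, patch_size = 3L,
                            ridge_floor = 1e-6, diagonal_weight = 2,
                            backend = "oracle", seed = 1L) {
  stopifnot(threshold > 0, threshold < 1, patch_size >= 3L,
            patch_size %% 2L == 1L, diagonal_weight > 0)
  structure(list(threshold = threshold, patch_size = patch_size,
                 ridge_floor = ridge_floor,
                 diagonal_weight = diagonal_weight, backend = backend,
                 seed = seed), class = "pipeline_config")
}

# Fit the coat colour model from the patch at a mask centroid.
fit_model_at_centroid <- function(image, mask, config) {
  ctr <- mask_centroid(mask)
  feats <- sample_patch_features(image, ctr, config$patch_size)
  list(model = fit_gaussian(feats, config$ridge_floor), centroid = ctr)
}

empty_record <- function(image_id, seed_id, cls, box) {
  data.frame(image_id = image_id, seed_id = seed_id, cls = cls,
             x_min = box[1], y_min = box[2], x_max = box[3], y_max = box[4],
             pixel_length = NA_real_, ratio = NA_real_,
             true_length_mm = NA_real_, flags = I(list(character(0))),
             stringsAsFactors = FALSE)
}

#' Measure every detected seed in an image
#'
#' Runs the five pipeline steps: box-prompted coarse segmentation of every
#' detection; coarse classification with a single per-image Gaussian coat
#' model trained on the pooled centroid patches of all coarse seed masks;
#' point-prompted fine segmentation of each germinated seed from its coat
#' and radicle centroids; fine classification with a model re-trained on
#' the pooled coat-centroid patches; and the skeleton-graph radicle
#' length, converted to millimetres when a calibration scale is supplied.
#' Pooling the 3x3 patches across seeds is what makes the 2x2 covariance
#' estimable — a single patch yields only 9 samples.  Non-germinated
#' detections are recorded with pixel length 0 and flag `no_radicle` after
#' coat segmentation only.  Per-seed failures are flagged in the record
#' and never abort the image.
#'
#' @param image A `seed_image`.
#' @param detections Detection data frame (see [load_detections()]).
#' @param backend A `segmenter_backend` supporting box and point prompts.
#' @param config A `pipeline_config`.
#' @param scale Optional `calibration_scale` for mm conversion.
#' @param keep_masks If TRUE, attach the per-seed component masks as the
#'   `masks` attribute of the result (used by evaluation utilities).
#' @return Data frame of seed records, one per detection, in detection
#'   order: `image_id`, `seed_id`, `cls`, box columns, `pixel_length`,
#'   `ratio`, `true_length_mm`, and a list-column `flags`.
#' @export
measure_image <- function(image, detections, backend, config = pipeline_config(),
                          scale = NULL, keep_masks = FALSE) {
  stopifnot(inherits(image, "seed_image"), inherits(config, "pipeline_config"))
  n_det <- nrow(detections)
  coarse <- coarse_segment(image, detections, backend)
  records <- vector("list", n_det)
  masks_out <- vector("list", n_det)

  # Step 2 model: one Gaussian per image, pooled over the centroid patches
  # of every non-empty coarse mask (coat area dominates, so centroids land
  # on the coat).
  ctr1 <- lapply(coarse, function(cm)
    if (any(cm$mask)) mask_centroid(cm$mask) else NULL)
  model1 <- pooled_patch_model(image, ctr1, config)

  # Steps 2-3 per seed: coarse classification, then fine segmentation
  cls1 <- vector("list", n_det)
  fine <- vector("list", n_det)
  ctr2 <- vector("list", n_det)
  for (i in seq_len(n_det)) {
    if (detections$cls[i] != "germinated" || !any(coarse[[i]]$mask) ||
        is.null(model1)) next
    cls1[[i]] <- tryCatch(
      classify_mask(image, coarse[[i]]$mask, model1, config$threshold, i),
      error = function(e) NULL)
    if (is.null(cls1[[i]])) next
    coat_ctr <- if (any(cls1[[i]]$coat)) mask_centroid(cls1[[i]]$coat) else ctr1[[i]]
    rad_ctr <- if (any(cls1[[i]]$radicle)) mask_centroid(cls1[[i]]$radicle) else NULL
    ctr2[[i]] <- coat_ctr
    fine[[i]] <- fine_segment(image, list(list(seed_id = i,
                                               coat_centroid = coat_ctr,
                                               radicle_centroid = rad_ctr)),
                              backend)[[1]]
  }

  # Step 4 model: re-trained on the pooled patches at the coat centroids
  model2 <- pooled_patch_model(image, ctr2, config) %||% model1

  for (i in seq_len(n_det)) {
    cls <- detections$cls[i]
    box <- as.numeric(detections[i, c("x_min", "y_min", "x_max", "y_max")])
    rec <- empty_record(image$image_id, i, cls, box)
    cmask <- coarse[[i]]
    if (!any(cmask$mask)) {
      rec$flags[[1]] <- union(cmask$flags, "no_radicle")
      rec$pixel_length <- 0
      records[[i]] <- rec
      next
    }
    if (cls == "non_germinated") {
      rec$pixel_length <- 0
      rec$flags[[1]] <- "no_radicle"
      if (!is.null(scale)) { rec$ratio <- scale$ratio; rec$true_length_mm <- 0 }
      records[[i]] <- rec
      if (keep_masks) masks_out[[i]] <- list(coat = cmask$mask,
                                             radicle = cmask$mask & FALSE)
      next
    }
    res <- tryCatch({
      fmask <- if (!is.null(fine[[i]]) && any(fine[[i]]$mask))
        fine[[i]]$mask else cmask$mask
      cls2 <- classify_mask(image, fmask, model2, config$threshold, i)
      # Step 5: radicle length on a crop padded for neighbourhood safety
      meas <- measure_components(cls2, config$diagonal_weight)
      list(meas = meas, comps = cls2,
           fine_flags = if (is.null(fine[[i]])) character(0) else fine[[i]]$flags)
    }, error = function(e) NULL)
    if (is.null(res)) {
      rec$pixel_length <- 0
      rec$flags[[1]] <- "no_radicle"
      records[[i]] <- rec
      next
    }
    rec$pixel_length <- res$meas$pixel_length
    rec$flags[[1]] <- sort(union(res$meas$flags, res$fine_flags))
    if (!is.null(scale)) {
      rec$ratio <- scale$ratio
      rec$true_length_mm <- to_true_length(res$meas$pixel_length, scale)
    }
    records[[i]] <- rec
    if (keep_masks) masks_out[[i]] <- list(coat = res$comps$coat,
                                           radicle = res$comps$radicle)
  }
  out <- if (n_det > 0) do.call(rbind, records) else
    empty_record("", 0L, "germinated", rep(NA_real_, 4))[0, ]
  rownames(out) <- NULL
  if (keep_masks) attr(out, "masks") <- masks_out
  out
}

# One Gaussian coat model from the pooled centroid patches; NULL when no
# centroids are available.
pooled_patch_model <- function(image, centroids, config) {
  centroids <- Filter(Negate(is.null), centroids)
  if (length(centroids) == 0L) return(NULL)
  feats <- do.call(rbind, lapply(centroids, function(ctr)
    sample_patch_features(image, ctr, config$patch_size)))
  fit_gaussian(feats, config$ridge_floor)
}

# Radicle length on a 2-px-padded crop around the seed, coordinates mapped
# back to the image frame.
measure_components <- function(comps, diagonal_weight = 2) {
  bb <- mask_bbox(comps$coat | comps$radicle)
  rows <- nrow(comps$coat); cols <- ncol(comps$coat)
  r0 <- max(1L, bb[2] - 1L); r1 <- min(rows, bb[4] + 2L)
  c0 <- max(1L, bb[1] - 1L); c1 <- min(cols, bb[3] + 2L)
  coat <- comps$coat[r0:r1, c0:c1, drop = FALSE]
  rad <- comps$radicle[r0:r1, c0:c1, drop = FALSE]
  if (!any(coat)) {
    # classification found no coat pixels: report the radicle as unmeasurable
    return(list(p_e = NULL, p_i = NULL, pixel_length = 0,
                flags = "no_radicle"))
  }
  m <- radicle_pixel_length(coat, rad, diagonal_weight)
  if (!is.null(m$p_e)) m$p_e <- m$p_e + c(c0 - 1L, r0 - 1L)
  if (!is.null(m$p_i)) m$p_i <- m$p_i + c(c0 - 1L, r0 - 1L)
  m
}

#' Classification threshold sweep on synthetic scenes
#'
#' Re-runs fine-stage classification of ground-truth seed masks at each
#' threshold and scores the radicle component against the generator's
#' ground truth (the combined coat+radicle region is prompt-determined and
#' threshold-invariant, so the radicle scores are what the threshold
#' moves).  Coat monotonicity — the coat mask can only grow as the
#' threshold decreases — is checked as a side effect.
#'
#' @param scenes List of `synthetic_scene` objects.
#' @param thresholds Thresholds to evaluate (default the 0.001..0.010
#'   decade in steps of 0.001).
#' @param config Base `pipeline_config`.
#' @return Data frame with one row per threshold: `threshold`, `dice`,
#'   `iou`, `pa` (means over seeds of the radicle-component scores).
#' @export
run_threshold_sweep <- function(scenes, thresholds = seq(0.001, 0.010, by = 0.001),
                                config = pipeline_config()) {
  rows <- lapply(thresholds, function(T) {
    scores <- list()
    for (scene in scenes) {
      for (s in scene$seeds) {
        if (s$cls != "germinated") next
        union_mask <- s$coat | s$radicle
        mfit <- fit_model_at_centroid(scene$image, s$coat, config)
        comps <- classify_mask(scene$image, union_mask, mfit$model, T, s$seed_id)
        pred <- masks_to_labels(comps$coat, comps$radicle)
        gt <- masks_to_labels(s$coat, s$radicle)
        sc <- segmentation_scores(pred, gt)
        scores[[length(scores) + 1]] <- c(dice = sc$iou_rd * 2 / (1 + sc$iou_rd),
                                          iou = sc$iou_rd,
                                          pa = sum(comps$radicle & s$radicle) /
                                            sum(s$radicle))
      }
    }
    m <- colMeans(do.call(rbind, scores))
    data.frame(threshold = T, dice = m["dice"], iou = m["iou"], pa = m["pa"])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
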