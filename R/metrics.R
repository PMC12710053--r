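# Segmentation evaluation metrics over {background, seed coat, radicle}
# label rasters.

#' Segmentation evaluation scores
#'
#' Compares a predicted label raster against a ground-truth raster, both
#' coded 0 = background, 1 = seed coat, 2 = radicle.  The headline scores
#' treat coat + radicle as a single foreground region `M_p` / `M_g`:
#'
#' * Dice `= 2|Mp ∩ Mg| / (|Mp| + |Mg|)`
#' * IoU  `= |Mp ∩ Mg| / |Mp ∪ Mg|`
#' * PA   `= |Mp ∩ Mg| / |Mg|` — intersection over ground truth, i.e.
#'   foreground recall, implemented exactly as defined
#' * FPR  `= |Mp \ Mg| / |M_bg|` with `M_bg` the ground-truth background
#'
#' Component IoUs (`iou_sc`, `iou_rd`, `iou_bg`) are per-class
#' intersection-over-union and `miou` is their arithmetic mean.  Undefined
#' ratios (empty denominator) are reported as `NA`, never as 0.
#'
#' @param pred,gt Integer label matrices of equal shape with values in
#'   \{0, 1, 2\}.
#' @return Named list with `dice`, `iou`, `pa`, `fpr`, `iou_sc`, `iou_rd`,
#'   `iou_bg`, `miou`.
#' @export
segmentation_scores <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)), all(pred %in% 0:2), all(gt %in% 0:2))
  mp <- pred > 0L; mg <- gt > 0L
  inter <- sum(mp & mg); szp <- sum(mp); szg <- sum(mg)
  uni <- szp + szg - inter
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  class_iou <- function(k) {
    a <- pred == k; b <- gt == k
    ratio(sum(a & b), sum(a | b))
  }
  iou_bg <- class_iou(0L); iou_sc <- class_iou(1L); iou_rd <- class_iou(2L)
  list(
    dice = ratio(2 * inter, szp + szg),
    iou = ratio(inter, uni),
    pa = ratio(inter, szg),
    fpr = ratio(sum(mp & !mg), sum(!mg)),
    iou_sc = iou_sc, iou_rd = iou_rd, iou_bg = iou_bg,
    miou = mean(c(iou_bg, iou_sc, iou_rd))
  )
}
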