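#' Voxel confusion counts between two binary masks
#'
#' @param pred,gt Binary masks (logical arrays or `ct_volume` objects) on
#'   the same grid.
#' @return A list with `tp`, `fp`, `fn`, `tn` voxel counts (tn over the full
#'   grid).
#' @export
confusion <- function(pred, gt) {
  p <- as_mask_array(pred); g <- as_mask_array(gt)
  if (!identical(dim(p), dim(g))) stop("pred and gt grids differ in shape")
  tp <- sum(p & g)
  list(tp = tp, fp = sum(p) - tp, fn = sum(g) - tp,
       tn = length(p) - sum(p) - sum(g) + tp)
}

#' Segmentation metric panel
#'
#' The five overlap metrics used to evaluate artery and calcification
#' segmentations: Dice `2tp/(2tp+fp+fn)`, Jaccard `tp/(tp+fp+fn)`,
#' volumetric similarity `1 - |fp-fn|/(2tp+fp+fn)`, sensitivity
#' `tp/(tp+fn)` and precision `tp/(tp+fp)`.
#'
#' Conventions for degenerate inputs: if both masks are empty all five
#' metrics are 1 and the result carries attribute `empty_both = TRUE`
#' (needed for calcification-free arteries); if exactly one mask is empty,
#' Dice and Jaccard are 0 and the ratio with the empty denominator
#' (sensitivity for an empty `gt`, precision for an empty `pred`) is `NaN`.
#'
#' @inheritParams confusion
#' @return Named numeric vector `dice`, `jaccard`, `volumetric_similarity`,
#'   `sensitivity`, `precision`.
#' @export
metric_panel <- function(pred, gt) {
  cc <- confusion(pred, gt)
  tp <- cc$tp; fp <- cc$fp; fn <- cc$fn
  if (tp + fp + fn == 0) {
    out <- c(dice = 1, jaccard = 1, volumetric_similarity = 1,
             sensitivity = 1, precision = 1)
    attr(out, "empty_both") <- TRUE
    return(out)
  }
  c(dice = 2 * tp / (2 * tp + fp + fn),
    jaccard = tp / (tp + fp + fn),
    volumetric_similarity = 1 - abs(fp - fn) / (2 * tp + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
    precision = if (tp + fp > 0) tp / (tp + fp) else NaN)
}

#' Per-artery-region metric panels
#'
#' Evaluates each artery group (aorta, iliac, mesenteric, renal) as a binary
#' mask. Artery segmentations are evaluated after shortening, so both maps
#' should have been processed by [shorten()]; calcification masks are
#' evaluated unshortened via [metric_panel()] directly.
#'
#' @param pred,gt [artery_label_map()] objects on the same grid.
#' @return A data frame with one row per region and columns `region`,
#'   `dice`, `jaccard`, `volumetric_similarity`, `sensitivity`, `precision`,
#'   `empty_both`.
#' @export
per_region_panels <- function(pred, gt) {
  stopifnot(inherits(pred, "artery_label_map"), inherits(gt, "artery_label_map"))
  check_same_grid(pred, gt, "label maps")
  rows <- lapply(names(ARTERY_GROUPS), function(g) {
    lab <- ARTERY_GROUPS[[g]]
    pm <- metric_panel(pred$grid == lab, gt$grid == lab)
    data.frame(region = g, t(pm),
               empty_both = isTRUE(attr(pm, "empty_both")))
  })
  do.call(rbind, rows)
}
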