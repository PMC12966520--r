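#' Threshold a CTA volume inside an artery region
#'
#' Global HU thresholding restricted to a region of interest: voxels inside
#' `roi` with HU greater than or equal to `threshold` become calcification;
#' everything outside `roi` is background. With the default fixed clinical
#' threshold of 470 HU this is the "clinically realistic" baseline; it never
#' inspects ground truth. Note that in contrast-enhanced studies whose lumen
#' exceeds the threshold, this method labels the whole artery as
#' calcification — the characteristic failure mode of fixed thresholds on
#' CTA.
#'
#' @param hu A [hu_volume()].
#' @param roi Logical array (or `artery_label_map`/`calc_mask`) marking the
#'   artery region on the same grid.
#' @param threshold Threshold in HU (default 470, the fixed clinical value).
#' @return A [calc_mask()] on the grid of `hu`.
#' @export
apply_threshold <- function(hu, roi, threshold = 470) {
  stopifnot(inherits(hu, "hu_volume"))
  roi <- as_mask_array(roi, hu)
  if (!any(roi)) stop("ROI is empty")
  m <- array(0L, dim(hu$grid))
  m[roi & hu$grid >= threshold] <- 1L
  calc_mask(m, hu$spacing, hu$origin)
}

#' Per-case Dice-optimal global threshold
#'
#' The idealized thresholding baseline: candidate thresholds are placed at
#' 1% intensity intervals across the ROI (101 candidates by default), the
#' Dice score of each thresholded mask against the ground-truth
#' calcification is computed, and the best candidate is returned. Ties are
#' broken toward the lowest threshold. Because it consults the ground truth,
#' this is an upper bound on thresholding performance, not a clinical tool.
#'
#' @param hu A [hu_volume()].
#' @param roi Artery region (logical array or label map) on the same grid.
#' @param gt_calc Ground-truth [calc_mask()] (non-empty).
#' @param step_fraction Candidate spacing as a fraction of the intensity
#'   range (default 0.01, i.e. 1% intervals).
#' @param strategy `"range"` places candidates linearly over
#'   `[min, max]` HU within the ROI; `"percentile"` places them at the
#'   corresponding quantiles of the ROI intensities.
#' @return A `threshold_search` list: `best_threshold`, `best_dice`, and a
#'   data frame `candidates` with columns `threshold`, `dice`.
#' @export
optimal_threshold <- function(hu, roi, gt_calc, step_fraction = 0.01,
                              strategy = c("range", "percentile")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(hu, "hu_volume"), step_fraction > 0, step_fraction <= 1)
  roi <- as_mask_array(roi, hu)
  if (!any(roi)) stop("ROI is empty")
  gt <- as_mask_array(gt_calc, hu)
  if (!any(gt)) stop("ground-truth calcification mask is empty: Dice is undefined")

  vals <- hu$grid[roi]
  lo <- min(vals); hi <- max(vals)
  if (hi <= lo) stop("constant-intensity ROI: threshold search is degenerate")
  fr <- seq(0, 1, by = step_fraction)
  cand <- if (strategy == "range") lo + fr * (hi - lo)
          else unname(stats::quantile(vals, probs = fr, type = 7))

  gt_roi <- gt[roi]
  n_gt <- sum(gt)
  dice <- vapply(cand, function(t) {
    pred <- vals >= t
    tp <- sum(pred & gt_roi)
    2 * tp / (sum(pred) + n_gt)
  }, numeric(1))
  best <- which.max(dice)                 # first max = lowest threshold
  structure(list(best_threshold = cand[best], best_dice = dice[best],
                 candidates = data.frame(threshold = cand, dice = dice)),
            class = "threshold_search")
}

#' Mean optimal threshold over a training set
#'
#' Averages per-case Dice-optimal thresholds across cases; applying the
#' resulting constant to unseen cases is the clinically realistic baseline
#' (470 HU on the study data).
#'
#' @param cases A list, each element a list with components `hu`, `roi`,
#'   `gt_calc` as accepted by [optimal_threshold()].
#' @param ... Passed on to [optimal_threshold()].
#' @return The arithmetic mean of the per-case best thresholds (HU).
#' @export
mean_optimal_threshold <- function(cases, ...) {
  if (!length(cases)) stop("no cases supplied")
  mean(vapply(cases, function(cs) {
    optimal_threshold(cs$hu, cs$roi, cs$gt_calc, ...)$best_threshold
  }, numeric(1)))
}

# Coerce ROI/mask inputs to a logical array aligned with a reference volume.
as_mask_array <- function(x, ref = NULL) {
  m <- if (inherits(x, "ct_volume")) x$grid > 0 else x > 0
  if (!is.null(ref) && !identical(dim(m), dim(ref$grid)))
    stop("mask grid does not match the reference volume grid")
  m
}
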