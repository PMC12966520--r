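#' Paired score vectors for agreement analysis
#'
#' @param gt,pred Numeric vectors of equal length (>= 2), finite.
#' @param label Optional label (e.g. "aorta / burden / nn").
#' @return A `paired_scores` object.
#' @export
paired_scores <- function(gt, pred, label = "") {
  gt <- as.numeric(gt); pred <- as.numeric(pred)
  if (length(gt) != length(pred)) stop("gt and pred differ in length")
  if (length(gt) < 2) stop("need at least 2 paired scores")
  if (any(!is.finite(gt)) || any(!is.finite(pred)))
    stop("paired scores must be finite")
  structure(list(gt = gt, pred = pred, label = label),
            class = "paired_scores")
}

#' Agreement statistics between ground-truth and predicted scores
#'
#' Computes the full comparison suite for one score vector pair: Pearson
#' correlation and R-squared, ordinary-least-squares regression of `pred`
#' on `gt` (slope, intercept), Bland-Altman bias and 95% limits of
#' agreement, and a two-sided paired t-test. Differences are oriented
#' `pred - gt`; their standard deviation uses the n-1 denominator; limits
#' of agreement are `bias +/- 1.96 * sd(diff)`.
#'
#' Degenerate inputs are reported as `NA` rather than errors: zero variance
#' in either vector leaves the correlation undefined, zero variance in `gt`
#' leaves the regression undefined, and fewer than 3 pairs leave the
#' p-value undefined. Identical vectors give `t = 0`, `p = 1`.
#'
#' @param pairs A [paired_scores()] object, or the `gt` vector when `pred`
#'   is supplied.
#' @param pred Optional predicted vector (with `pairs` as `gt`).
#' @param label Optional label when building pairs on the fly.
#' @return A one-row data frame: `label`, `n`, `pearson_r`, `r_squared`,
#'   `slope`, `intercept`, `bias`, `loa_low`, `loa_high`, `t_stat`,
#'   `p_value`.
#' @export
agreement <- function(pairs, pred = NULL, label = "") {
  if (!inherits(pairs, "paired_scores"))
    pairs <- paired_scores(pairs, pred, label)
  gt <- pairs$gt; pr <- pairs$pred
  n <- length(gt)
  diffs <- pr - gt
  bias <- mean(diffs)
  sd_d <- stats::sd(diffs)

  r <- if (stats::var(gt) > 0 && stats::var(pr) > 0)
    stats::cor(gt, pr) else NA_real_
  if (stats::var(gt) > 0) {
    fit <- stats::lm.fit(cbind(1, gt), pr)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  } else {
    intercept <- NA_real_; slope <- NA_real_
  }
  if (sd_d > 0) {
    t_stat <- bias / (sd_d / sqrt(n))
    p <- if (n >= 3) 2 * stats::pt(-abs(t_stat), df = n - 1) else NA_real_
  } else {
    t_stat <- if (bias == 0) 0 else sign(bias) * Inf
    p <- if (n >= 3) (if (bias == 0) 1 else 0) else NA_real_
  }
  data.frame(label = pairs$label, n = n,
             pearson_r = r, r_squared = if (is.na(r)) NA_real_ else r^2,
             slope = slope, intercept = intercept,
             bias = bias, loa_low = bias - 1.96 * sd_d,
             loa_high = bias + 1.96 * sd_d,
             t_stat = t_stat, p_value = p)
}

#' Agreement table over many score vectors
#'
#' One [agreement()] row per element, in input order (one row per
#' group x metric x method in the typical layout). Per-row undefined
#' statistics propagate as `NA` without affecting other rows.
#'
#' @param all_pairs List of [paired_scores()] objects.
#' @return Data frame of agreement reports.
#' @export
batch_agreement <- function(all_pairs) {
  stopifnot(length(all_pairs) >= 1)
  do.call(rbind, lapply(all_pairs, agreement))
}

#' Bland-Altman plot
#'
#' Scatter of per-case means `(gt + pred)/2` against differences
#' `pred - gt`, with dotted horizontal lines at the mean difference and at
#' the 95% limits of agreement (mean difference +/- 1.96 SD of the
#' differences). The output format follows the file extension (`.png`,
#' `.pdf` or `.svg`).
#'
#' @param pairs A [paired_scores()] object.
#' @param path Output image path.
#' @param main Plot title (default: the pair label).
#' @return The [agreement()] row for `pairs`, invisibly.
#' @export
bland_altman_plot <- function(pairs, path, main = NULL) {
  stopifnot(inherits(pairs, "paired_scores"))
  rep <- agreement(pairs)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = 800, height = 600),
    pdf = grDevices::pdf(path, width = 7, height = 5.5),
    svg = grDevices::svg(path, width = 7, height = 5.5),
    stop("unsupported plot format: .", ext))
  on.exit(grDevices::dev.off())
  means <- (pairs$gt + pairs$pred) / 2
  diffs <- pairs$pred - pairs$gt
  ylim <- range(c(diffs, rep$loa_low, rep$loa_high))
  graphics::plot(means, diffs, pch = 19, col = "grey30",
                 xlab = "mean of ground truth and prediction",
                 ylab = "difference (prediction - ground truth)",
                 ylim = ylim, main = main %||% pairs$label)
  graphics::abline(h = rep$bias, lty = 3)
  graphics::abline(h = c(rep$loa_low, rep$loa_high), lty = 3, col = "grey50")
  invisible(rep)
}
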