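#' @useDynLib calciscore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

ARTERY_GROUPS <- c(aorta = 1L, iliac = 2L, mesenteric = 3L, renal = 4L)

new_ct_volume <- function(grid, spacing, origin = c(0, 0, 0), class) {
  stopifnot(is.array(grid), length(dim(grid)) == 3)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three strictly positive finite numbers")
  structure(
    list(grid = grid, spacing = spacing, origin = as.numeric(origin)),
    class = c(class, "ct_volume")
  )
}

#' Construct a Hounsfield-unit CTA volume
#'
#' A 3D scalar grid of Hounsfield units (HU) with voxel spacing in
#' millimetres. Axis 3 of the array is the superior-inferior axis with
#' increasing index = superior.
#'
#' @param grid 3D numeric array of HU values (finite).
#' @param spacing Voxel edge lengths in mm, length 3 (or a scalar, recycled).
#' @param origin Physical position of the first voxel corner, mm.
#' @return An object of class `hu_volume`.
#' @export
hu_volume <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (any(!is.finite(grid))) stop("HU volume contains non-finite values")
  new_ct_volume(grid, spacing, origin, "hu_volume")
}

#' Construct an artery label map
#'
#' Integer grid with the fixed label semantics 0 = background, 1 = aorta,
#' 2 = iliac, 3 = mesenteric, 4 = renal.
#'
#' @inheritParams hu_volume
#' @return An object of class `artery_label_map`.
#' @export
artery_label_map <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  u <- unique(as.vector(grid))
  bad <- setdiff(u, 0:4)
  if (length(bad))
    stop("artery label map contains labels outside {0,1,2,3,4}: ",
         paste(utils::head(bad, 5), collapse = ", "))
  storage.mode(grid) <- "integer"
  new_ct_volume(grid, spacing, origin, "artery_label_map")
}

#' Construct a binary calcification mask
#'
#' @inheritParams hu_volume
#' @return An object of class `calc_mask`.
#' @export
calc_mask <- function(grid, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  u <- unique(as.vector(grid))
  if (length(setdiff(u, c(0, 1))))
    stop("calcification mask must be binary (values in {0,1})")
  storage.mode(grid) <- "integer"
  new_ct_volume(grid, spacing, origin, "calc_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, spacing %s mm\n",
              class(x)[1], paste(dim(x$grid), collapse = "x"),
              paste(format(x$spacing, trim = TRUE), collapse = " x ")))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$grid)

voxel_volume_mm3 <- function(vol) prod(vol$spacing)

is_isotropic <- function(vol, target = NULL, tol = 1e-6) {
  s <- vol$spacing
  if (is.null(target)) return(max(s) - min(s) < tol)
  all(abs(s - target) < tol)
}

check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$grid), dim(b$grid)))
    stop(what, " are not on the same grid: ",
         paste(dim(a$grid), collapse = "x"), " vs ",
         paste(dim(b$grid), collapse = "x"))
  invisible(TRUE)
}

#' Resample a volume onto an isotropic grid
#'
#' Resamples to the target spacing (default 1 mm isotropic, the working grid
#' of the shortening algorithm). Label maps and masks use nearest-neighbour
#' interpolation so no new labels can appear; HU volumes use trilinear
#' interpolation. The output grid is anchored at the input origin and its
#' shape is `ceiling(physical extent / target)`, so the physical extent is
#' preserved to within one voxel per axis. An input already on the target
#' grid is returned unchanged.
#'
#' @param vol A `hu_volume`, `artery_label_map` or `calc_mask`.
#' @param target Target spacing in mm (scalar or length 3).
#' @return A volume of the same class on the target grid.
#' @export
resample_isotropic <- function(vol, target = c(1, 1, 1)) {
  stopifnot(inherits(vol, "ct_volume"))
  target <- as.numeric(target)
  if (length(target) == 1) target <- rep(target, 3)
  if (any(!is.finite(target)) || any(target <= 0))
    stop("target spacing must be strictly positive")
  d <- dim(vol$grid)
  if (any(d == 0)) stop("cannot resample a degenerate (zero-size) grid")
  if (is_isotropic(vol, target)) return(vol)

  extent <- d * vol$spacing
  dout <- pmax(1L, as.integer(ceiling(extent / target - 1e-9)))
  # voxel-centre coordinates of the output grid, in continuous input index
  # space (input voxel i has centre (i - 0.5) * spacing)
  idx <- lapply(1:3, function(a) {
    ((seq_len(dout[a]) - 0.5) * target[a]) / vol$spacing[a] + 0.5
  })
  linear <- inherits(vol, "hu_volume")
  if (!linear) {
    ii <- lapply(1:3, function(a) pmin(pmax(round(idx[[a]]), 1L), d[a]))
    out <- vol$grid[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  } else {
    out <- trilinear_gather(vol$grid, idx, d, dout)
  }
  dim(out) <- dout
  cls <- class(vol)[1]
  v <- switch(cls,
    hu_volume = hu_volume(out, target, vol$origin),
    artery_label_map = artery_label_map(out, target, vol$origin),
    calc_mask = calc_mask(out, target, vol$origin))
  v
}

# Vectorized trilinear interpolation at separable grid positions.
trilinear_gather <- function(grid, idx, d, dout) {
  f <- lapply(1:3, function(a) {
    lo <- floor(idx[[a]] - 0.5) + 0.5           # lower voxel centre
    i0 <- pmin(pmax(as.integer(lo + 0.5), 1L), d[a])
    i1 <- pmin(i0 + 1L, d[a])
    w <- pmin(pmax(idx[[a]] - lo, 0), 1)
    list(i0 = i0, i1 = i1, w = w)
  })
  acc <- array(0, dout)
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    ix <- if (cx == 0) f[[1]]$i0 else f[[1]]$i1
    iy <- if (cy == 0) f[[2]]$i0 else f[[2]]$i1
    iz <- if (cz == 0) f[[3]]$i0 else f[[3]]$i1
    wx <- if (cx == 0) 1 - f[[1]]$w else f[[1]]$w
    wy <- if (cy == 0) 1 - f[[2]]$w else f[[2]]$w
    wz <- if (cz == 0) 1 - f[[3]]$w else f[[3]]$w
    block <- grid[ix, iy, iz, drop = FALSE]
    wt <- outer(outer(wx, wy), wz)
    dim(wt) <- dout
    acc <- acc + block * wt
  }
  acc
}

# ---- shared voxel helpers used across modules ----

label_components <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  .cc_label(as.logical(mask), as.integer(d), as.integer(connectivity))
}

dilate_mask <- function(mask, iterations = 1L, connectivity = 6L) {
  d <- dim(mask)
  m <- as.logical(mask)
  for (i in seq_len(iterations))
    m <- .dilate_once(m, as.integer(d), as.integer(connectivity))
  array(m, d)
}
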