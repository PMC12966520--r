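#' Synthetic CTA phantom configuration
#'
#' Describes a synthetic abdominal CTA case: a vertical cylindrical aorta
#' with side branches (iliac, mesenteric, renal) attached orthogonally at
#' configurable slices, spherical calcified lesions, and Gaussian
#' intensity bands. The default bands (background -50 HU, contrast-filled
#' lumen 300 HU, calcification 900 HU, noise SD 20 HU) straddle the 470 HU
#' clinical threshold; raising `lumen_hu_mean` above 470 reproduces the
#' fixed-threshold failure regime.
#'
#' @param grid_shape Grid size in voxels, length 3.
#' @param spacing Voxel spacing in mm.
#' @param aorta_radius_mm,branch_radius_mm Vessel radii, mm.
#' @param aorta_z_range_mm Inferior/superior extent of the aorta, mm.
#' @param branch_specs List of branches, each
#'   `list(label, z0_mm, dir, length_mm, curvature = 0)`: `label` in 2:4
#'   (iliac/mesenteric/renal), `z0_mm` the attachment height, `dir` a unit
#'   3-vector orthogonal to the aorta axis, `curvature` an optional 1/mm
#'   bending of the centreline (arc parametrization).
#' @param lumen_hu_mean,lumen_hu_sd,calc_hu_mean,calc_hu_sd,background_hu,background_hu_sd
#'   Intensity band means and Gaussian noise SDs, HU. Set the SDs to 0 for
#'   noiseless phantoms.
#' @param lesions List of lesions, each `list(center, radius_mm, group)`
#'   with `center` in physical mm and `group` one of `"aorta"`, `"iliac"`,
#'   `"mesenteric"`, `"renal"` naming the host vessel.
#' @param seed RNG seed; a fixed seed makes the phantom bit-reproducible.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(144, 144, 128),
                           spacing = c(1, 1, 1),
                           aorta_radius_mm = 8,
                           branch_radius_mm = 3,
                           aorta_z_range_mm = c(6, 122),
                           branch_specs = default_branch_specs(),
                           lumen_hu_mean = 300, lumen_hu_sd = 20,
                           calc_hu_mean = 900, calc_hu_sd = 20,
                           background_hu = -50, background_hu_sd = 20,
                           lesions = default_lesions(),
                           seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            aorta_radius_mm > 0, branch_radius_mm > 0,
            all(spacing > 0))
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 aorta_radius_mm = aorta_radius_mm,
                 branch_radius_mm = branch_radius_mm,
                 aorta_z_range_mm = aorta_z_range_mm,
                 branch_specs = branch_specs,
                 lumen_hu_mean = lumen_hu_mean, lumen_hu_sd = lumen_hu_sd,
                 calc_hu_mean = calc_hu_mean, calc_hu_sd = calc_hu_sd,
                 background_hu = background_hu,
                 background_hu_sd = background_hu_sd,
                 lesions = lesions, seed = as.integer(seed)),
            class = "phantom_config")
}

# two iliac, two mesenteric (SMA/CA analogues), two renal branches, 60 mm
default_branch_specs <- function() {
  list(
    list(label = 2L, z0_mm = 20, dir = c(1, 0, 0), length_mm = 60),
    list(label = 2L, z0_mm = 20, dir = c(-1, 0, 0), length_mm = 60),
    list(label = 3L, z0_mm = 82, dir = c(0, 1, 0), length_mm = 60),
    list(label = 3L, z0_mm = 96, dir = c(0, 1, 0), length_mm = 60),
    list(label = 4L, z0_mm = 70, dir = c(1, 0, 0), length_mm = 60),
    list(label = 4L, z0_mm = 70, dir = c(-1, 0, 0), length_mm = 60))
}

# lesions sit inside the segment that survives shortening
default_lesions <- function() {
  list(
    list(center = c(77, 72, 40), radius_mm = 3.0, group = "aorta"),
    list(center = c(72, 67, 90), radius_mm = 2.5, group = "aorta"),
    list(center = c(90, 72, 20), radius_mm = 2.0, group = "iliac"),
    list(center = c(72, 90, 82), radius_mm = 2.0, group = "mesenteric"),
    list(center = c(56, 72, 70), radius_mm = 1.8, group = "renal"))
}

# sphere stencil: linear-index offsets reaching all voxels whose centre is
# within radius_mm of a voxel centre
sphere_offsets <- function(radius_mm, spacing) {
  rv <- ceiling(radius_mm / spacing)
  g <- expand.grid(dx = -rv[1]:rv[1], dy = -rv[2]:rv[2], dz = -rv[3]:rv[3])
  keep <- (g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 +
    (g$dz * spacing[3])^2 <= radius_mm^2
  as.matrix(g[keep, , drop = FALSE])
}

# voxel centres: index i covers physical ((i-1)*s, i*s], centre (i-0.5)*s
phys_to_index <- function(p, spacing) as.integer(round(p / spacing + 0.5))

centreline_points <- function(p0, dir, length_mm, curvature = 0, step = 0.5) {
  t <- seq(0, length_mm, by = step)
  if (!curvature || curvature == 0) {
    pts <- cbind(p0[1] + t * dir[1], p0[2] + t * dir[2], p0[3] + t * dir[3])
  } else {
    # arc in the plane spanned by dir and the aorta axis (z)
    R <- 1 / curvature
    nrm <- c(0, 0, 1)
    pts <- cbind(
      p0[1] + R * sin(t / R) * dir[1] + R * (1 - cos(t / R)) * nrm[1],
      p0[2] + R * sin(t / R) * dir[2] + R * (1 - cos(t / R)) * nrm[2],
      p0[3] + R * sin(t / R) * dir[3] + R * (1 - cos(t / R)) * nrm[3])
  }
  pts
}

# mark all voxels within radius of a polyline; returns linear indices
tube_voxels <- function(pts, radius_mm, dims, spacing) {
  offs <- sphere_offsets(radius_mm, spacing)
  ctr <- cbind(phys_to_index(pts[, 1], spacing[1]),
               phys_to_index(pts[, 2], spacing[2]),
               phys_to_index(pts[, 3], spacing[3]))
  ctr <- unique(ctr)
  ix <- rep(ctr[, 1], each = nrow(offs)) + offs[, 1]
  iy <- rep(ctr[, 2], each = nrow(offs)) + offs[, 2]
  iz <- rep(ctr[, 3], each = nrow(offs)) + offs[, 3]
  ok <- ix >= 1 & ix <= dims[1] & iy >= 1 & iy <= dims[2] &
    iz >= 1 & iz <= dims[3]
  out_of_grid <- any(!ok)
  idx <- unique(ix[ok] + dims[1] * (iy[ok] - 1) +
                  dims[1] * dims[2] * (iz[ok] - 1))
  attr(idx, "clipped") <- out_of_grid
  idx
}

#' Generate a synthetic CTA phantom
#'
#' Builds the three aligned volumes the pipeline consumes: an HU volume, a
#' ground-truth artery label map (1 aorta, 2 iliac, 3 mesenteric, 4 renal),
#' and a binary calcification mask. Vessels are voxelized from analytic
#' centrelines; lesions are spheres clipped to the artery region and given
#' the calcification intensity band. Construction metadata (branch
#' attachment points, per-lesion voxel sets) is attached for independent
#' truth computation via [construction_truth()]. Deterministic under the
#' config seed.
#'
#' @param cfg A [phantom_config()].
#' @return List with `hu` ([hu_volume()]), `arteries`
#'   ([artery_label_map()]), `calc` ([calc_mask()]) and `meta`.
#' @export
make_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  d <- cfg$grid_shape
  sp <- cfg$spacing
  centre <- c(d[1] * sp[1] / 2, d[2] * sp[2] / 2)

  xc <- (seq_len(d[1]) - 0.5) * sp[1]
  yc <- (seq_len(d[2]) - 0.5) * sp[2]
  zc <- (seq_len(d[3]) - 0.5) * sp[3]
  r2 <- outer((xc - centre[1])^2, (yc - centre[2])^2, `+`)
  in_disc <- r2 <= cfg$aorta_radius_mm^2
  in_z <- zc >= cfg$aorta_z_range_mm[1] & zc <= cfg$aorta_z_range_mm[2]
  aorta <- array(as.vector(in_disc) & rep(in_z, each = d[1] * d[2]), d)

  labels <- array(0L, d)
  branches <- list()
  for (b in cfg$branch_specs) {
    dirv <- b$dir / sqrt(sum(b$dir^2))
    # start 1 mm inside the aortic surface so branch and aorta always touch
    p0 <- c(centre + (cfg$aorta_radius_mm - 1) * dirv[1:2], b$z0_mm)
    pts <- centreline_points(p0, dirv, b$length_mm + 1,
                             b$curvature %||% 0)
    vox <- tube_voxels(pts, cfg$branch_radius_mm, d, sp)
    if (isTRUE(attr(vox, "clipped")))
      stop("branch (label ", b$label, ") leaves the grid")
    labels[vox] <- ifelse(labels[vox] == 0L, b$label, labels[vox])
    branches[[length(branches) + 1L]] <-
      list(label = b$label, dir = dirv, p0 = p0, length_mm = b$length_mm,
           voxels = as.integer(vox))
  }
  labels[aorta] <- 1L                       # aorta has priority at overlaps

  calc <- array(0L, d)
  lesion_meta <- list()
  for (ls in cfg$lesions) {
    ci <- phys_to_index(ls$center, sp)
    host_lab <- ARTERY_GROUPS[[ls$group]]
    if (any(ci < 1) || any(ci > d))
      stop("lesion centre outside the grid")
    centre_lab <- labels[ci[1], ci[2], ci[3]]
    if (centre_lab != host_lab)
      stop("lesion centre is not inside its host vessel (", ls$group,
           "): found label ", centre_lab)
    offs <- sphere_offsets(ls$radius_mm, sp)
    ix <- ci[1] + offs[, 1]; iy <- ci[2] + offs[, 2]; iz <- ci[3] + offs[, 3]
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    idx <- ix[ok] + d[1] * (iy[ok] - 1) + d[1] * d[2] * (iz[ok] - 1)
    idx <- idx[labels[idx] > 0L]            # clip to the artery region
    calc[idx] <- 1L
    lesion_meta[[length(lesion_meta) + 1L]] <-
      list(group = ls$group, center = ls$center, radius_mm = ls$radius_mm,
           voxels = as.integer(idx))
  }

  hu <- array(cfg$background_hu, d)
  if (cfg$background_hu_sd > 0)
    hu <- hu + stats::rnorm(length(hu), 0, cfg$background_hu_sd)
  art <- labels > 0L & calc == 0L
  n_art <- sum(art)
  hu[art] <- cfg$lumen_hu_mean +
    if (cfg$lumen_hu_sd > 0) stats::rnorm(n_art, 0, cfg$lumen_hu_sd) else 0
  n_cal <- sum(calc == 1L)
  if (n_cal > 0)
    hu[calc == 1L] <- cfg$calc_hu_mean +
      if (cfg$calc_hu_sd > 0) stats::rnorm(n_cal, 0, cfg$calc_hu_sd) else 0

  list(hu = hu_volume(hu, sp),
       arteries = artery_label_map(labels, sp),
       calc = calc_mask(calc, sp),
       meta = list(config = cfg, centre = centre, aorta = aorta,
                   branches = branches, lesions = lesion_meta))
}

#' Construction-derived ground truth for a phantom
#'
#' Computes per-group burden, cluster count and mean cluster size directly
#' from the phantom's construction metadata, without calling the shortening
#' or scoring code: the kept part of each straight branch is the set of its
#' voxels whose projection on the branch axis lies within
#' `aorta_dilations + n_dilations` voxels of the aortic surface, and the
#' kept aorta ends `aorta_margin_mm` above the highest kept branch voxel.
#' Serves as the independent oracle for pipeline cross-checks; exact up to
#' a one-voxel shell at vessel rims.
#'
#' @param phantom Output of [make_phantom()] (straight branches only).
#' @param cfg A [shortening_config()] (for the length constants).
#' @return Data frame with one row per group plus `combined`: columns as in
#'   [burden_scores()].
#' @export
construction_truth <- function(phantom, cfg = shortening_config()) {
  meta <- phantom$meta
  d <- dim(phantom$arteries$grid)
  sp <- phantom$arteries$spacing
  keep_mm <- (cfg$aorta_dilations_for_stump + cfg$n_dilations) * sp[1]

  kept <- array(FALSE, d)
  labels <- phantom$arteries$grid
  for (b in meta$branches) {
    if (!is.null(b$curvature) && isTRUE(b$curvature != 0))
      stop("construction truth supports straight branches only")
    vox <- b$voxels[labels[b$voxels] == b$label]   # outside-aorta part
    ai <- arrayInd(vox, d)
    pc <- sweep(ai, 2, sp, `*`) - 0.5 * matrix(sp, nrow(ai), 3, byrow = TRUE)
    proj <- (pc[, 1] - b$p0[1]) * b$dir[1] + (pc[, 2] - b$p0[2]) * b$dir[2] +
      (pc[, 3] - b$p0[3]) * b$dir[3]
    # aortic surface along this branch axis: farthest aorta voxel projection
    avox <- which(meta$aorta)
    # restrict to the branch footprint for a tight surface estimate
    foot <- avox[labels[avox] == 1L]
    aidx <- arrayInd(foot, d)
    apc <- sweep(aidx, 2, sp, `*`) - 0.5 * matrix(sp, nrow(aidx), 3, byrow = TRUE)
    lat2 <- rowSums((apc - matrix(b$p0, nrow(apc), 3, byrow = TRUE))^2) -
      ((apc[, 1] - b$p0[1]) * b$dir[1] + (apc[, 2] - b$p0[2]) * b$dir[2] +
         (apc[, 3] - b$p0[3]) * b$dir[3])^2
    in_foot <- lat2 <= (meta$config$branch_radius_mm + 0.5 * sp[1])^2
    s_proj <- max(((apc[in_foot, 1] - b$p0[1]) * b$dir[1] +
                   (apc[in_foot, 2] - b$p0[2]) * b$dir[2] +
                   (apc[in_foot, 3] - b$p0[3]) * b$dir[3]))
    kept[vox[proj <= s_proj + keep_mm]] <- TRUE
  }
  z_top <- if (any(kept)) max(arrayInd(which(kept), d)[, 3]) else d[3]
  aorta_kept <- meta$aorta
  z_idx <- rep(seq_len(d[3]), each = d[1] * d[2])
  aorta_kept[z_idx > z_top + cfg$aorta_margin_mm / sp[3]] <- FALSE

  vv <- prod(sp)
  group_mask <- function(g) {
    if (g == "aorta") aorta_kept else kept & labels == ARTERY_GROUPS[[g]]
  }
  rows <- lapply(names(ARTERY_GROUPS), function(g) {
    gm <- group_mask(g)
    les <- Filter(function(l) l$group == g, meta$lesions)
    calc_vox <- if (length(les)) sum(vapply(les, function(l)
      sum(gm[l$voxels]), numeric(1))) else 0
    art_vox <- sum(gm)
    data.frame(group = g,
               artery_volume_mm3 = art_vox * vv,
               calc_volume_mm3 = calc_vox * vv,
               burden = if (art_vox > 0) calc_vox / art_vox else NA_real_,
               cluster_count = length(les),
               mean_cluster_size_mm3 = if (length(les))
                 mean(vapply(les, function(l) length(l$voxels) * vv,
                             numeric(1)))
               else NA_real_)
  })
  tab <- do.call(rbind, rows)
  comb <- data.frame(group = "combined",
                     artery_volume_mm3 = sum(tab$artery_volume_mm3),
                     calc_volume_mm3 = sum(tab$calc_volume_mm3),
                     burden = sum(tab$calc_volume_mm3) / sum(tab$artery_volume_mm3),
                     cluster_count = sum(tab$cluster_count),
                     mean_cluster_size_mm3 = if (sum(tab$cluster_count) > 0)
                       sum(tab$cluster_count *
                             ifelse(is.na(tab$mean_cluster_size_mm3), 0,
                                    tab$mean_cluster_size_mm3)) /
                         sum(tab$cluster_count)
                     else NA_real_)
  out <- rbind(tab, comb)
  rownames(out) <- out$group
  out
}

#' Generate a cohort of phantoms with construction-known truth
#'
#' Randomizes lesion load and branch geometry around a base configuration
#' and records, per case and artery group, the construction-derived truth
#' table ([construction_truth()]). To bound memory, phantoms themselves are
#' not kept by default: each case's `phantom_config` (with its derived
#' seed) is returned, so `make_phantom(configs[[i]])` regenerates any case
#' bit-identically.
#'
#' @param n Number of cases (>= 1).
#' @param base_cfg Base [phantom_config()]; per-case seeds are
#'   `base_cfg$seed + case index`.
#' @param variability List of dispersion parameters:
#'   `lesion_rate` (named Poisson means per group),
#'   `lesion_radius_range` (mm), `branch_length_range` (mm),
#'   `branch_slice_jitter` (mm, uniform), `lumen_hu_jitter_sd` (HU,
#'   case-level shift of the lumen band).
#' @param shorten_cfg [shortening_config()] used for the truth's kept-region
#'   constants.
#' @param keep_phantoms Keep the generated phantoms in the result (memory
#'   heavy; default `FALSE`).
#' @return List with `configs` (length `n`), `truth` (data frame with a
#'   `case` column), and optionally `phantoms`.
#' @export
make_cohort <- function(n, base_cfg = phantom_config(),
                        variability = cohort_variability(),
                        shorten_cfg = shortening_config(),
                        keep_phantoms = FALSE) {
  stopifnot(n >= 1)
  v <- utils::modifyList(cohort_variability(), variability)
  configs <- vector("list", n)
  truths <- vector("list", n)
  phantoms <- if (keep_phantoms) vector("list", n) else NULL
  for (i in seq_len(n)) {
    cfg_i <- sample_case_config(base_cfg, v, base_cfg$seed + i)
    ph <- make_phantom(cfg_i)
    tt <- construction_truth(ph, shorten_cfg)
    tt <- cbind(case = i, tt)
    configs[[i]] <- cfg_i
    truths[[i]] <- tt
    if (keep_phantoms) phantoms[[i]] <- ph
  }
  out <- list(configs = configs, truth = do.call(rbind, truths))
  rownames(out$truth) <- NULL
  if (keep_phantoms) out$phantoms <- phantoms
  out
}

#' Default cohort dispersion parameters
#' @return Named list of dispersion parameters (see [make_cohort()]).
#' @export
cohort_variability <- function() {
  list(lesion_rate = c(aorta = 2.0, iliac = 1.2, mesenteric = 0.8, renal = 0.8),
       lesion_radius_range = c(1.5, 3.2),
       branch_length_range = c(35, 55),
       branch_slice_jitter = 3,
       lumen_hu_jitter_sd = 40)
}

# draw one case's config: jittered branches, Poisson lesion counts placed
# on vessel centrelines inside the segment that survives shortening
sample_case_config <- function(base, v, case_seed) {
  set.seed(case_seed %% .Machine$integer.max)
  sp <- base$spacing
  centre <- c(base$grid_shape[1] * sp[1] / 2, base$grid_shape[2] * sp[2] / 2)

  branches <- lapply(base$branch_specs, function(b) {
    b$length_mm <- stats::runif(1, v$branch_length_range[1],
                                v$branch_length_range[2])
    b$z0_mm <- b$z0_mm + stats::runif(1, -v$branch_slice_jitter,
                                      v$branch_slice_jitter)
    b
  })
  z_top <- max(vapply(branches, function(b) b$z0_mm, numeric(1))) +
    base$branch_radius_mm

  lesions <- list()
  placed <- matrix(numeric(0), 0, 4)         # x, y, z, radius
  try_place <- function(center, r) {
    if (nrow(placed) == 0) return(TRUE)
    dd <- sqrt(rowSums(sweep(placed[, 1:3, drop = FALSE], 2, center)^2))
    all(dd >= placed[, 4] + r + 2 * max(sp))
  }
  for (g in names(ARTERY_GROUPS)) {
    k <- stats::rpois(1, v$lesion_rate[[g]])
    for (j in seq_len(k)) {
      for (attempt in 1:25) {
        r <- stats::runif(1, v$lesion_radius_range[1], v$lesion_radius_range[2])
        if (g == "aorta") {
          z <- stats::runif(1, base$aorta_z_range_mm[1] + r + 2,
                            min(z_top + 8, base$aorta_z_range_mm[2]) - r - 2)
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, max(base$aorta_radius_mm - r - 0.5, 0))
          center <- c(centre[1] + rad * cos(ang), centre[2] + rad * sin(ang), z)
        } else {
          bs <- Filter(function(b) b$label == ARTERY_GROUPS[[g]], branches)
          b <- bs[[sample.int(length(bs), 1)]]
          dirv <- b$dir / sqrt(sum(b$dir^2))
          # along the first ~22 mm beyond the surface: survives shortening
          t <- stats::runif(1, r + 1, 22 - r)
          p0 <- c(centre + base$aorta_radius_mm * dirv[1:2], b$z0_mm)
          center <- p0 + t * dirv
        }
        if (try_place(center, r)) {
          placed <- rbind(placed, c(center, r))
          lesions[[length(lesions) + 1L]] <-
            list(center = center, radius_mm = r, group = g)
          break
        }
      }
    }
  }
  cfg <- base
  cfg$branch_specs <- branches
  cfg$lesions <- lesions
  cfg$lumen_hu_mean <- base$lumen_hu_mean +
    stats::rnorm(1, 0, v$lumen_hu_jitter_sd)
  cfg$seed <- as.integer((case_seed %% 100000) * 977 + 13)
  cfg
}

#' Phantom reproducing the fixed-threshold failure mode
#'
#' A phantom whose contrast-filled lumen exceeds the 470 HU clinical
#' threshold (default 550 HU), so fixed thresholding labels essentially the
#' whole artery as calcification while the per-case optimal search still
#' separates the bands.
#'
#' @param cfg A [phantom_config()]; its `lumen_hu_mean` must exceed 470.
#' @return As [make_phantom()].
#' @export
make_high_hu_case <- function(cfg = phantom_config(lumen_hu_mean = 550)) {
  if (cfg$lumen_hu_mean <= 470)
    stop("lumen_hu_mean must exceed 470 HU for the failure-mode phantom")
  make_phantom(cfg)
}
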