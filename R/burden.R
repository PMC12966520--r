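#' Connected calcification clusters
#'
#' Connected-component analysis of a calcification mask (6-connectivity by
#' default, matching the shortening algorithm's CCA convention). Cluster
#' sizes are physical volumes: voxel count times voxel volume.
#'
#' @param calc A [calc_mask()] on an isotropic grid.
#' @param connectivity 6, 18 or 26 (default 6).
#' @return A list of clusters, each `list(voxels, size_mm3)`; empty list for
#'   an empty mask.
#' @export
calc_clusters <- function(calc, connectivity = 6L) {
  stopifnot(inherits(calc, "calc_mask"))
  m <- calc$grid > 0L
  if (!any(m)) return(list())
  cc <- label_components(m, connectivity)
  vv <- voxel_volume_mm3(calc)
  lapply(seq_len(max(cc)), function(k) {
    vox <- which(cc == k)
    list(voxels = vox, size_mm3 = length(vox) * vv)
  })
}

#' Assign calcification clusters to artery groups
#'
#' Each cluster goes to the artery group with which it shares the most
#' voxels in the shortened label map; ties break by the priority
#' aorta > iliac > mesenteric > renal. Clusters with no overlap with any
#' group (e.g. lesions in trimmed-away distal vessel) are discarded and
#' counted in the `discarded` attribute.
#'
#' @param clusters Output of [calc_clusters()].
#' @param shortened A shortened [artery_label_map()] on the same grid.
#' @return Named list `aorta`, `iliac`, `mesenteric`, `renal` of cluster
#'   lists, with attribute `discarded` (number of unassigned clusters).
#' @export
assign_clusters <- function(clusters, shortened) {
  stopifnot(inherits(shortened, "artery_label_map"))
  out <- stats::setNames(vector("list", 4), names(ARTERY_GROUPS))
  for (g in names(out)) out[[g]] <- list()
  discarded <- 0L
  for (cl in clusters) {
    labs <- shortened$grid[cl$voxels]
    ov <- tabulate(labs[labs > 0L], 4L)
    if (all(ov == 0L)) { discarded <- discarded + 1L; next }
    g <- names(ARTERY_GROUPS)[which.max(ov)]   # first max = priority order
    out[[g]][[length(out[[g]]) + 1L]] <- cl
  }
  attr(out, "discarded") <- discarded
  out
}

#' Volume-normalized calcification burden scores
#'
#' The main burden score per artery group is the ratio of calcified volume
#' to artery volume within the standardized (shortened) artery segment.
#' Because the calcified volume is anatomically constrained by the artery,
#' the score is naturally normalized to `[0, 1]`: the numerator counts only
#' assigned-cluster voxels lying inside the group's artery mask. The
#' combined score pools volumes over the four groups
#' (sum of calcified volume / sum of artery volume), so it is dominated by
#' the larger aortic and iliac segments. Cluster morphology (count and mean
#' size in mm^3) is reported alongside.
#'
#' @param calc A [calc_mask()].
#' @param shortened A shortened [artery_label_map()] on the same isotropic
#'   grid.
#' @param connectivity CCA neighbourhood for clusters (default 6).
#' @return A data frame with rows `aorta`, `iliac`, `mesenteric`, `renal`,
#'   `combined` and columns `group`, `artery_volume_mm3`, `calc_volume_mm3`,
#'   `burden`, `cluster_count`, `mean_cluster_size_mm3`. A group absent from
#'   the label map gets `NA` burden (not 0); a group without clusters gets
#'   `NA` mean cluster size.
#' @export
burden_scores <- function(calc, shortened, connectivity = 6L) {
  stopifnot(inherits(calc, "calc_mask"), inherits(shortened, "artery_label_map"))
  check_same_grid(calc, shortened, "calcification mask and label map")
  vv <- voxel_volume_mm3(shortened)
  clusters <- calc_clusters(calc, connectivity)
  assigned <- assign_clusters(clusters, shortened)

  rows <- lapply(names(ARTERY_GROUPS), function(g) {
    lab <- ARTERY_GROUPS[[g]]
    art_vox <- sum(shortened$grid == lab)
    cls <- assigned[[g]]
    # numerator clipped to the group's artery mask keeps burden <= 1
    calc_vox <- if (length(cls)) {
      sum(vapply(cls, function(cl)
        sum(shortened$grid[cl$voxels] == lab), numeric(1)))
    } else 0
    data.frame(
      group = g,
      artery_volume_mm3 = art_vox * vv,
      calc_volume_mm3 = calc_vox * vv,
      burden = if (art_vox > 0) calc_vox / art_vox else NA_real_,
      cluster_count = length(cls),
      mean_cluster_size_mm3 = if (length(cls))
        sum(vapply(cls, `[[`, numeric(1), "size_mm3")) / length(cls)
      else NA_real_)
  })
  tab <- do.call(rbind, rows)
  tot_art <- sum(tab$artery_volume_mm3)
  tot_calc <- sum(tab$calc_volume_mm3)
  n_cl <- sum(tab$cluster_count)
  comb <- data.frame(
    group = "combined",
    artery_volume_mm3 = tot_art,
    calc_volume_mm3 = tot_calc,
    burden = if (tot_art > 0) tot_calc / tot_art else NA_real_,
    cluster_count = n_cl,
    mean_cluster_size_mm3 = if (n_cl > 0) {
      sum(tab$cluster_count * ifelse(is.na(tab$mean_cluster_size_mm3), 0,
                                     tab$mean_cluster_size_mm3)) / n_cl
    } else NA_real_)
  out <- rbind(tab, comb)
  rownames(out) <- out$group
  attr(out, "discarded_clusters") <- attr(assigned, "discarded")
  out
}

#' Cluster count and mean size per group
#'
#' @param assigned Output of [assign_clusters()].
#' @return Data frame with columns `group`, `cluster_count`,
#'   `mean_cluster_size_mm3` (`NA` when the group has no clusters; mean size
#'   uses the clusters' full physical volumes).
#' @export
cluster_stats <- function(assigned) {
  rows <- lapply(names(assigned), function(g) {
    cls <- assigned[[g]]
    data.frame(group = g, cluster_count = length(cls),
               mean_cluster_size_mm3 = if (length(cls))
                 mean(vapply(cls, `[[`, numeric(1), "size_mm3"))
               else NA_real_)
  })
  do.call(rbind, rows)
}
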