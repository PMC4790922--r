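#' Partition significant voxels by atlas region
#'
#' @param sig_mask logical 3D array of significant voxels.
#' @param atlas a `label_atlas` (see [generate_atlas()]) on the same grid.
#' @return named list label -> ijk matrix of that region's significant
#'   voxels; background (label 0) voxels appear under the name
#'   `"unassigned"` and are never dropped.
#' @export
partition_by_atlas <- function(sig_mask, atlas) {
  if (!identical(dim(sig_mask), dim(atlas$labels)))
    stop("significance mask and atlas grids do not match")
  idx <- which(sig_mask)
  out <- list()
  if (length(idx) == 0) return(out)
  labs <- atlas$labels[idx]
  for (r in sort(unique(labs))) {
    key <- if (r == 0) "unassigned" else as.character(r)
    out[[key]] <- arrayInd(idx[labs == r], dim(sig_mask))
  }
  out
}

#' Two-sample t on per-subject mean density over detected voxels
#'
#' Averages each subject's (adjusted) tissue density over the detected
#' voxels of a region and returns the pooled-variance two-sample t of those
#' per-subject means, signed placebo-minus-treated under `direction =
#' "less"` so that a deficit in the group of interest gives a positive t.
#'
#' @param maps cohort / list of volumes / subjects x voxels matrix.
#' @param labels logical, TRUE = group of interest.
#' @param voxels ijk matrix (or in-mask index vector) of detected voxels.
#' @param mask required for plain inputs.
#' @param direction `"less"` or `"greater"`.
#' @return list with `t` and `degenerate` (TRUE when the pooled variance of
#'   the per-subject means is zero; then `t = 0`).
#' @export
region_t <- function(maps, labels = NULL, voxels, mask = NULL,
                     direction = c("less", "greater")) {
  direction <- match.arg(direction)
  if (inherits(maps, "synth_cohort")) {
    if (is.null(labels)) labels <- cohort_labels(maps)
    mask <- maps$mask
    X <- cohort_matrix(maps)
  } else if (is.matrix(maps)) {
    X <- maps
    stopifnot(!is.null(mask))
  } else {
    mask <- maps[[1]]$mask
    X <- cohort_matrix(maps, mask)
  }
  ids <- voxels_to_mask_ids(voxels, mask)
  if (length(ids) == 0) stop("empty detected voxel set")
  m <- rowMeans(X[, ids, drop = FALSE])
  st <- neighborhood_statistic(matrix(m, ncol = 1), labels, 1, direction)
  list(t = st$s, degenerate = st$degenerate)
}

# ijk matrix or in-mask index vector -> column indices of cohort_matrix
voxels_to_mask_ids <- function(voxels, mask) {
  if (is.matrix(voxels)) {
    idmap <- array(0L, dim(mask))
    idmap[mask] <- seq_len(sum(mask))
    lin <- voxels[, 1] + dim(mask)[1] * (voxels[, 2] - 1L) +
      dim(mask)[1] * dim(mask)[2] * (voxels[, 3] - 1L)
    ids <- idmap[lin]
    if (any(ids == 0)) stop("detected voxels outside the analysis mask")
    ids
  } else {
    as.integer(voxels)
  }
}

#' Center of mass of a voxel set in world coordinates
#'
#' Unweighted mean of the member voxel centres, mapped through the grid
#' affine to mm. Coordinates are reported in the working template's mm
#' frame (no stereotaxic-space conversion is applied).
#'
#' @param voxels ijk matrix (1-based).
#' @param grid a [grid_geometry()].
#' @return numeric(3) mm coordinates.
#' @export
center_of_mass <- function(voxels, grid) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  if (nrow(voxels) == 0) stop("empty voxel set")
  colMeans(voxel_to_world(grid, voxels))
}

#' Region-partitioned findings report
#'
#' One row per atlas region containing significant voxels, with side,
#' centre-of-mass mm coordinates, significant-voxel count N and the
#' region-mean two-sample t — at both the FWE-corrected and the uncorrected
#' (trend) level. Rows are sorted by N descending within correction level.
#'
#' @param pmap a `p_value_map` from [permutation_pvalues()].
#' @param atlas a `label_atlas`.
#' @param maps,labels the (adjusted) data the t statistics are computed on.
#' @param alpha uncorrected (trend) voxel threshold.
#' @param cluster_alpha FWE-corrected cluster threshold.
#' @param comparison label stored in the `comparison` column.
#' @return data frame with columns `comparison`, `level`, `region`, `side`,
#'   `x`, `y`, `z`, `N`, `t`.
#' @export
make_report <- function(pmap, atlas, maps, labels = NULL, alpha = 0.05,
                        cluster_alpha = 0.05, comparison = "A<B") {
  direction <- if (grepl(">", comparison, fixed = TRUE)) "greater" else "less"
  trend_mask <- threshold_map(pmap, alpha)
  cl <- cluster_fwe(find_clusters(trend_mask, pmap$connectivity),
                    pmap$null_max_sizes)
  sig_mask <- array(FALSE, dim(pmap$mask))
  for (c_ in cl) if (c_$corrected_p < cluster_alpha)
    sig_mask[c_$voxels] <- TRUE

  one_level <- function(m, level) {
    parts <- partition_by_atlas(m, atlas)
    if (length(parts) == 0) return(NULL)
    rows <- lapply(names(parts), function(key) {
      vx <- parts[[key]]
      com <- center_of_mass(vx, atlas$grid)
      tt <- region_t(maps, labels, vx, mask = pmap$mask,
                     direction = direction)
      data.frame(
        comparison = comparison, level = level,
        region = if (key == "unassigned") "unassigned"
                 else unname(atlas$names[key]),
        side = if (key == "unassigned") ""
               else unname(atlas$sides[key]),
        x = com[1], y = com[2], z = com[3],
        N = nrow(vx), t = tt$t
      )
    })
    df <- do.call(rbind, rows)
    df[order(-df$N), , drop = FALSE]
  }

  out <- rbind(one_level(sig_mask, "FWE-corrected"),
               one_level(trend_mask, "uncorrected"))
  if (is.null(out))
    out <- data.frame(comparison = character(), level = character(),
                      region = character(), side = character(),
                      x = numeric(), y = numeric(), z = numeric(),
                      N = integer(), t = numeric())
  rownames(out) <- NULL
  out
}
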