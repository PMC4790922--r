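#' Grid geometry of a volume
#'
#' Describes the voxel grid all volumes of a cohort share: the array shape,
#' the voxel size in mm, and the world-coordinate (mm) position of the first
#' voxel. The affine maps 0-based voxel indices to mm; R's 1-based array
#' indices are converted internally. By default the origin centres the grid,
#' so world x = 0 is the mid-sagittal plane and x < 0 is the left side.
#'
#' @param shape integer(3), voxels per axis.
#' @param voxel_size numeric(3), mm per voxel along each axis.
#' @param origin numeric(3), mm coordinate of voxel index (1,1,1). Defaults
#'   to `-(shape - 1) / 2 * voxel_size` (grid centred at 0).
#' @return An object of class `grid_geometry` with fields `shape`,
#'   `voxel_size`, `origin` and the 4x4 `affine`.
#' @export
grid_geometry <- function(shape, voxel_size = c(1, 1, 1), origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  stopifnot(length(origin) == 3)
  affine <- diag(4)
  diag(affine)[1:3] <- voxel_size
  affine[1:3, 4] <- origin
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin), affine = affine),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat("grid_geometry:", paste(x$shape, collapse = " x "),
      "voxels,", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Map 1-based voxel indices to world (mm) coordinates
#'
#' @param grid a [grid_geometry()].
#' @param ijk integer matrix (n x 3) or vector of length 3, 1-based indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, ncol = 3)
  ijk0 <- sweep(ijk - 1, 2, grid$voxel_size, `*`)
  sweep(ijk0, 2, grid$origin, `+`)
}

# 1-based (i,j,k) coordinates of TRUE voxels, column-major order
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

#' Tissue-density volume
#'
#' One subject's 3D tissue-density image (RAVENS-style: non-negative,
#' mass-preserving densities) with its grid geometry and analysis mask.
#'
#' @param values numeric 3D array, non-negative inside `mask`.
#' @param grid a [grid_geometry()] matching `dim(values)`.
#' @param mask logical 3D array, the analysis domain (non-empty).
#' @return An object of class `volume_map`.
#' @export
volume_map <- function(values, grid, mask) {
  stopifnot(inherits(grid, "grid_geometry"))
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values shape does not match grid shape")
  if (!identical(dim(mask), as.integer(grid$shape)))
    stop("mask shape does not match grid shape")
  if (!any(mask)) stop("mask is empty")
  if (any(values[mask] < 0))
    stop("tissue densities must be non-negative inside the mask")
  structure(list(values = values, grid = grid, mask = mask),
            class = "volume_map")
}

#' @export
print.volume_map <- function(x, ...) {
  cat("volume_map:", paste(x$grid$shape, collapse = " x "),
      "voxels,", sum(x$mask), "in mask\n")
  invisible(x)
}

#' Ellipsoidal brain-like mask
#'
#' An ellipsoid inscribed in the grid with the given fractional margin,
#' used as the default analysis domain of the synthetic generator.
#'
#' @param grid a [grid_geometry()].
#' @param margin fraction of each semi-axis left outside the mask.
#' @return logical 3D array.
#' @export
ellipsoid_mask <- function(grid, margin = 0.08) {
  sh <- grid$shape
  ctr <- (sh + 1) / 2
  semi <- pmax((sh - 1) / 2 * (1 - margin), 0.5)
  i <- (seq_len(sh[1]) - ctr[1]) / semi[1]
  j <- (seq_len(sh[2]) - ctr[2]) / semi[2]
  k <- (seq_len(sh[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(i^2, j^2, `+`), k^2, `+`)
  r2 <= 1
}

#' Separable 3D Gaussian smoothing
#'
#' Convolves a 3D array with an axis-separable Gaussian kernel of the given
#' full-width-at-half-maximum, with zero padding at the edges.
#'
#' @param arr numeric 3D array.
#' @param fwhm_mm kernel FWHM in mm (scalar); 0 returns `arr` unchanged.
#' @param voxel_size numeric(3) mm per voxel.
#' @return list with `values` (smoothed array) and `kernel_ss` (sum of
#'   squared 3D kernel weights, the variance-shrink factor for white noise).
#' @export
gaussian_smooth3d <- function(arr, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (fwhm_mm <= 0) return(list(values = arr, kernel_ss = 1))
  out <- arr
  ss <- 1
  for (ax in 1:3) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size[ax]
    half <- max(1L, as.integer(ceiling(3 * sigma)))
    kk <- exp(-((-half:half)^2) / (2 * sigma^2))
    kk <- kk / sum(kk)
    ss <- ss * sum(kk^2)
    out <- convolve_axis(out, kk, ax)
  }
  list(values = out, kernel_ss = ss)
}

# zero-padded 1D convolution of a 3D array along one axis
convolve_axis <- function(arr, kernel, axis) {
  half <- (length(kernel) - 1L) / 2L
  n <- dim(arr)[axis]
  acc <- array(0, dim(arr))
  for (o in -half:half) {
    w <- kernel[o + half + 1L]
    src <- seq_len(n) + o
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    dst <- seq_len(n)[keep]
    idx_src <- src[keep]
    if (axis == 1L) {
      acc[dst, , ] <- acc[dst, , ] + w * arr[idx_src, , , drop = FALSE]
    } else if (axis == 2L) {
      acc[, dst, ] <- acc[, dst, ] + w * arr[, idx_src, , drop = FALSE]
    } else {
      acc[, , dst] <- acc[, , dst] + w * arr[, , idx_src, drop = FALSE]
    }
  }
  acc
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [volume_map()] or a bare 3D array (then `grid` is required).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param grid grid geometry when `vol` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, grid = NULL) {
  if (inherits(vol, "volume_map")) {
    values <- vol$values
    grid <- vol$grid
  } else {
    values <- vol
    stopifnot(inherits(grid, "grid_geometry"))
  }
  img <- RNifti::asNifti(values)
  aff <- grid$affine
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume into a volume_map
#'
#' @param path NIfTI file path.
#' @param mask optional logical array; default: everything in-mask.
#' @return a [volume_map()].
#' @export
read_volume <- function(path, mask = NULL) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img))
  aff <- RNifti::xform(img)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  grid <- grid_geometry(dim(values), voxel_size = vs, origin = aff[1:3, 4])
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  volume_map(values, grid, mask)
}
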