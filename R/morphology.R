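#' 3D separable Gaussian smoothing
#'
#' @param x 3D numeric array ordered (z, y, x).
#' @param sigma_um standard deviation in micrometres (scalar or z/y/x triple).
#' @param voxel_um voxel size in micrometres (scalar or z/y/x triple).
#' @param order derivative order per axis (0, 1 or 2); used internally to
#'   assemble Gaussian-derivative filters.
#' @return array of the same dimensions.
#' @export
gaussian_filter3 <- function(x, sigma_um, voxel_um, order = c(0L, 0L, 0L)) {
  sigma_um <- rep_len(sigma_um, 3L)
  voxel_um <- rep_len(voxel_um, 3L)
  ks <- lapply(1:3, function(a) {
    gauss_kernel1d(sigma_um[a] / voxel_um[a], order[a], voxel_um[a])
  })
  .cpp_sepconv3(x, ks[[1]], ks[[2]], ks[[3]])
}

# 1D Gaussian (derivative) kernel sampled at voxel pitch; derivative kernels
# are scaled to physical units (per um, per um^2)
gauss_kernel1d <- function(sigma_vox, order = 0L, voxel_um = 1) {
  r <- max(1L, ceiling(3 * sigma_vox))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- -t / sigma_vox^2 * g            # d/dx of Gaussian, voxel units
    k <- k - mean(k)                     # enforce zero response to constants
    return(k / voxel_um)
  }
  if (order == 2L) {
    k <- (t^2 / sigma_vox^2 - 1) / sigma_vox^2 * g
    k <- k - mean(k)
    return(k / voxel_um^2)
  }
  stop("order must be 0, 1 or 2")
}

#' Euclidean distance transform with nearest-feature lookup
#'
#' Exact anisotropic 3D distance transform; for every voxel returns the
#' distance (in physical units given by `spacing_um`) to the nearest nonzero
#' voxel of `mask`, and the linear index of that voxel.
#'
#' @param mask 3D logical/integer array; nonzero entries are features.
#' @param spacing_um voxel spacing, scalar or (z, y, x) triple.
#' @return list with `dist` (numeric array) and `feature` (integer array of
#'   1-based linear indices, 0 where the mask is empty).
#' @export
distance_transform3 <- function(mask, spacing_um = 1) {
  spacing_um <- rep_len(spacing_um, 3L)
  m <- array(as.integer(mask != 0), dim = dim(mask))
  .cpp_edt3(m, as.numeric(spacing_um))
}

#' Binary morphology with a Euclidean ball
#'
#' Erosion, dilation and opening of a 3D binary volume by a ball of physical
#' radius `r_um`, realized exactly through the Euclidean distance transform.
#'
#' @param mask 3D logical array.
#' @param r_um ball radius, micrometres.
#' @param voxel_um isotropic voxel size, micrometres.
#' @return logical array.
#' @export
ball_erode <- function(mask, r_um, voxel_um) {
  d <- distance_transform3(!mask, voxel_um)$dist
  out <- d > r_um
  dim(out) <- dim(mask)
  out
}

#' @rdname ball_erode
#' @export
ball_dilate <- function(mask, r_um, voxel_um) {
  if (!any(mask)) return(mask)
  d <- distance_transform3(mask, voxel_um)$dist
  out <- d <= r_um
  dim(out) <- dim(mask)
  out
}

#' @rdname ball_erode
#' @export
ball_open <- function(mask, r_um, voxel_um) {
  ball_dilate(ball_erode(mask, r_um, voxel_um), r_um, voxel_um)
}

#' Grey-scale top-hat background removal (cubic window)
#'
#' Estimates the non-uniform background as the grey-scale opening with a
#' cubic window of half-width `r_um` and subtracts it; output is clipped at
#' zero.
#'
#' @param x 3D numeric array.
#' @param r_um window half-width, micrometres.
#' @param voxel_um voxel size, micrometres (scalar or triple).
#' @return array of same dimensions, nonnegative.
#' @export
tophat3 <- function(x, r_um, voxel_um) {
  voxel_um <- rep_len(voxel_um, 3L)
  r <- as.integer(pmax(1L, round(r_um / voxel_um)))
  bg <- .cpp_minmax_box3(.cpp_minmax_box3(x, r, FALSE), r, TRUE)
  out <- pmax(x - bg, 0)
  dim(out) <- dim(x)
  out
}

#' Fill interior holes of a 3D binary mask
#'
#' Background components not connected (6-connectivity) to the array border
#' are absorbed into the mask.
#'
#' @param mask 3D logical array.
#' @return logical array.
#' @export
fill_holes3 <- function(mask) {
  bg <- array(as.integer(!mask), dim = dim(mask))
  lab <- .cpp_label3(bg, 6L)
  d <- dim(mask)
  border_labels <- unique(c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ],
                            lab[, , c(1, d[3])]))
  border_labels <- border_labels[border_labels > 0]
  out <- mask | (lab > 0 & !(lab %in% border_labels))
  dim(out) <- dim(mask)
  out
}

#' Keep the largest 6-connected component of a binary mask
#' @param mask 3D logical array.
#' @return logical array.
#' @export
largest_component3 <- function(mask) {
  lab <- .cpp_label3(array(as.integer(mask), dim = dim(mask)), 6L)
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  out <- lab == keep
  dim(out) <- dim(mask)
  out
}

#' Surface voxels of a 3D set (6-connected boundary)
#' @param mask 3D logical array.
#' @return logical array marking voxels of the set with at least one
#'   6-neighbour outside it (array borders count as outside).
#' @export
surface_voxels3 <- function(mask) {
  .cpp_boundary6(array(as.integer(mask), dim = dim(mask)), TRUE)
}

# binary dilation by the 3x3x3 cube (one max-filter step)
dilate_cube1 <- function(mask) {
  out <- .cpp_minmax_box3(array(as.numeric(mask), dim = dim(mask)),
                          c(1L, 1L, 1L), TRUE) > 0
  dim(out) <- dim(mask)
  out
}
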