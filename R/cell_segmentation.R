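#' Volume-constrained cluster mask
#'
#' Greedy thresholding of the smoothed membrane channel: voxels are
#' accumulated in descending intensity order until the mask volume first
#' reaches the target volume; the largest 6-connected component is kept and
#' holes are filled. A deviation of more than 10% from the target is logged
#' as a warning - the cluster does not suddenly gain or lose mass, so the
#' target is set once from the first time point (reference cell volumes
#' times cell counts).
#'
#' @param combined 3D array: the smoothed membrane channel, whose shell
#'   traces the cluster surface (prepared upstream, see [segment_cells()];
#'   the interior is recovered by the hole fill).
#' @param v_target_um3 target cluster volume, um^3.
#' @param voxel_um working voxel size, um.
#' @param must_cover optional 3D integer array of seed labels (e.g. the
#'   tracked nuclei); the threshold keeps descending past the volume
#'   optimum until every seed label intersects the mask, so a dim cell
#'   cannot be dropped from the cluster.
#' @param regularize_um scale (um) of the volume-preserving surface
#'   smoothing applied after thresholding (Gaussian smoothing of the mask
#'   indicator, re-thresholded at the same voxel count); removes the
#'   voxel-to-nucleus-scale surface roughness that would otherwise register
#'   as spurious opening residue downstream. 0 disables.
#' @return logical mask with attribute `volume_um3`.
#' @export
cluster_mask <- function(combined, v_target_um3, voxel_um = 0.33,
                         must_cover = NULL, regularize_um = 1) {
  if (v_target_um3 <= 0) stop("V_target must be > 0")
  vox_vol <- voxel_um^3
  n_target <- max(1L, round(v_target_um3 / vox_vol))
  v <- as.vector(combined)
  if (length(v) < n_target)
    stop("weak-signal error: image smaller than the target volume")
  # greedy descending-intensity accumulation over whole intensity levels;
  # the level minimizing |accumulated volume - target| is the threshold
  # (equals the exhaustive search over all distinct thresholds). Descending
  # to the full target count deliberately reaches the dim parts of the
  # membrane shell (the z-caps, attenuated by the coarse axial sampling) so
  # the shell closes before hole filling.
  lev <- sort(unique(v), decreasing = TRUE)
  cnt <- tabulate(match(v, lev), nbins = length(lev))
  cum <- cumsum(cnt)
  best <- which.min(abs(cum - n_target))
  mask_at <- function(i) {
    m <- combined >= lev[i]
    dim(m) <- dim(combined)
    fill_holes3(largest_component3(m))
  }
  if (!is.null(must_cover)) {
    seed_idx <- which(must_cover > 0)
    seed_lab <- must_cover[seed_idx]
    lab_set <- unique(seed_lab)
    covers <- function(i) {
      inside <- mask_at(i)[seed_idx]
      length(unique(seed_lab[inside])) == length(lab_set)
    }
    if (!covers(best)) {
      # coverage grows as the threshold descends: bisect the smallest
      # covering level
      lo2 <- best; hi2 <- length(lev)
      if (!covers(hi2))
        stop("weak-signal error: no threshold encloses every seed")
      while (hi2 - lo2 > 1L) {
        mid <- (lo2 + hi2) %/% 2L
        if (covers(mid)) hi2 <- mid else lo2 <- mid
      }
      best <- hi2
    }
  }
  mask <- mask_at(best)
  if (regularize_um > 0) {
    # hole filling of the shell band overshoots the target volume;
    # smoothing the mask indicator and keeping exactly the target voxel
    # count peels the overshoot along smooth level sets while also removing
    # voxel-scale surface roughness (a curvature flow step)
    sm <- gaussian_filter3(array(as.numeric(mask), dim(mask)),
                           regularize_um, voxel_um)
    thr2 <- sort(as.vector(sm), decreasing = TRUE)[n_target]
    keep <- sm >= thr2
    dim(keep) <- dim(combined)
    keep <- fill_holes3(largest_component3(keep))
    cover_ok <- is.null(must_cover) ||
      length(unique(must_cover[keep & must_cover > 0])) ==
        length(unique(must_cover[must_cover > 0]))
    if (cover_ok) mask <- keep
  }
  vol <- sum(mask) * vox_vol
  if (vol < 0.5 * v_target_um3)
    stop("weak-signal error: reachable cluster volume below half the target")
  if (abs(vol - v_target_um3) / v_target_um3 > 0.1)
    warning(sprintf("cluster volume %.0f um^3 deviates >10%% from target %.0f um^3",
                    vol, v_target_um3))
  attr(mask, "volume_um3") <- vol
  mask
}

#' Oriented plate-filter membrane enhancement
#'
#' Maximum response, over a bank of second-derivative "plate" kernels of
#' scale `sigma_um` rotated by `angular_step` degrees within the x-y, x-z
#' and y-z planes, of the convolution with the membrane channel. The
#' response of the kernel oriented along unit normal n equals the negated
#' second directional derivative -n' H n of the Gaussian-smoothed image, so
#' the bank is evaluated through the Gaussian Hessian; bright sheets of any
#' sampled orientation light up. Output is clipped at zero.
#'
#' @param frame 3D membrane-channel array.
#' @param sigma_um plate kernel scale, um.
#' @param angular_step in-plane rotation step, degrees (0 < step <= 90).
#' @param voxel_um working voxel size, um.
#' @return nonnegative array of the same dimensions.
#' @export
enhance_membrane <- function(frame, sigma_um = 0.66, angular_step = 30,
                             voxel_um = 0.33) {
  if (angular_step <= 0 || angular_step > 90)
    stop("angular step must be in (0, 90] degrees")
  H <- list(
    zz = gaussian_filter3(frame, sigma_um, voxel_um, c(2L, 0L, 0L)),
    yy = gaussian_filter3(frame, sigma_um, voxel_um, c(0L, 2L, 0L)),
    xx = gaussian_filter3(frame, sigma_um, voxel_um, c(0L, 0L, 2L)),
    zy = gaussian_filter3(frame, sigma_um, voxel_um, c(1L, 1L, 0L)),
    zx = gaussian_filter3(frame, sigma_um, voxel_um, c(1L, 0L, 1L)),
    yx = gaussian_filter3(frame, sigma_um, voxel_um, c(0L, 1L, 1L)))
  angles <- seq(0, 180 - angular_step, by = angular_step) * pi / 180
  normals <- list()
  for (a in angles) {
    normals[[length(normals) + 1]] <- c(0, sin(a), cos(a))   # x-y plane
    normals[[length(normals) + 1]] <- c(sin(a), 0, cos(a))   # x-z plane
    normals[[length(normals) + 1]] <- c(sin(a), cos(a), 0)   # y-z plane
  }
  out <- array(-Inf, dim(frame))
  for (nv in normals) {
    resp <- -(nv[1]^2 * H$zz + nv[2]^2 * H$yy + nv[3]^2 * H$xx +
                2 * nv[1] * nv[2] * H$zy + 2 * nv[1] * nv[3] * H$zx +
                2 * nv[2] * nv[3] * H$yx)
    out <- pmax(out, resp)
  }
  out <- pmax(out, 0)
  dim(out) <- dim(frame)
  out
}

#' Marker-controlled watershed cell segmentation
#'
#' Priority-flood watershed of the enhanced membrane image restricted to the
#' cluster mask, flooding outward from the tracked nuclei so that the
#' resulting cells partition the mask and each contains its seed. Voxels of
#' equal priority go to the front that queued them first (so each basin
#' keeps its own ridge flank), with the lower label as the final tie-break;
#' the result is deterministic.
#'
#' @param enhanced 3D array (high values = membrane barriers).
#' @param seeds 3D integer array of nucleus labels.
#' @param mask logical cluster mask.
#' @return 3D integer label array partitioning the mask.
#' @export
watershed_cells <- function(enhanced, seeds, mask) {
  labs <- sort(unique(seeds[seeds > 0]))
  inside <- seeds
  inside[!mask] <- 0L
  present <- sort(unique(inside[inside > 0]))
  missing <- setdiff(labs, present)
  if (length(missing))
    stop("seeding error: seed label(s) ",
         paste(missing, collapse = ", "), " outside the cluster mask")
  .cpp_watershed_seeded(enhanced, array(as.integer(inside), dim(seeds)),
                        array(as.integer(mask), dim(mask)))
}

#' Cell-cell and cell-substrate interface areas
#'
#' Each cell is dilated by the 3 x 3 x 3 structuring element (made slightly
#' "fatter"); voxels of the dilation overlapping a neighbour count toward
#' the internal interface with that neighbour, voxels overlapping the
#' complement of the cluster mask count toward the external interface.
#' Counts convert to areas via (voxel size)^2.
#'
#' @param cells 3D integer label array partitioning the cluster mask.
#' @param cluster 3D logical cluster mask.
#' @param voxel_um working voxel size, um.
#' @return data.frame with columns `cell`, `neighbour` (0 = external),
#'   `type` (`"external"`/`"internal"`), `voxels`, `area_um2`.
#' @export
cell_interfaces <- function(cells, cluster, voxel_um = 0.33) {
  labs <- sort(unique(cells[cells > 0]))
  rows <- list()
  a_vox <- voxel_um^2
  for (l in labs) {
    dil <- dilate_cube1(cells == l)
    ring <- dil & cells != l
    ext <- sum(ring & !cluster)
    rows[[length(rows) + 1]] <-
      data.frame(cell = l, neighbour = 0L, type = "external",
                 voxels = ext, area_um2 = ext * a_vox)
    inner <- cells[ring & cluster & cells > 0]
    if (length(inner)) {
      tb <- table(inner)
      for (nb in names(tb)) {
        rows[[length(rows) + 1]] <-
          data.frame(cell = l, neighbour = as.integer(nb), type = "internal",
                     voxels = as.integer(tb[[nb]]),
                     area_um2 = as.integer(tb[[nb]]) * a_vox)
      }
    }
  }
  do.call(rbind, rows)
}

#' Segment cell bodies of a whole movie
#'
#' Per frame: cluster mask from the smoothed membrane channel under the
#' volume constraint `c_border * v_border_ref + 2 * v_polar_ref`, oriented
#' plate-filter membrane enhancement, and marker-controlled watershed seeded
#' by the tracked nuclei.
#'
#' @param stack a preprocessed isotropic [movie_stack()].
#' @param nuclei a nuclei [label_volume()] from [segment_nuclei()].
#' @param config a [pipeline_config()].
#' @return list with `labels` (cells [label_volume()]), `cluster`
#'   (T-length list of masks) and `interfaces` (data.frame over frames).
#' @export
segment_cells <- function(stack, nuclei, config = pipeline_config()) {
  d <- dim(stack$data)
  v <- stack$voxel_size_zyx[1]
  ids <- nuclei$identity_map
  n_border <- sum(ids == "border")
  v_target <- n_border * config$v_border_ref + 2 * config$v_polar_ref
  labels <- array(0L, dim = c(d[1], d[3], d[4], d[5]))
  masks <- vector("list", d[1])
  iface <- list()
  has_mem <- "cell_membrane" %in% stack$channel_names
  for (t in seq_len(d[1])) {
    mem <- if (has_mem) get_frame(stack, t, "cell_membrane")
           else get_frame(stack, t, "nuclei")
    # the membrane shell traces the cluster surface; smoothing plus the
    # hole fill in cluster_mask recovers the solid volume
    combined <- gaussian_filter3(mem, config$cluster_smooth_um, v)
    seeds <- get_label_frame(nuclei, t)
    B <- cluster_mask(combined, v_target, v, must_cover = seeds)
    enh <- enhance_membrane(mem, config$membrane_sigma_um,
                            config$membrane_angular_step, v)
    cells <- watershed_cells(enh, seeds, B)
    labels[t, , , ] <- cells
    masks[[t]] <- B
    fi <- cell_interfaces(cells, B, v)
    fi$frame <- t
    iface[[t]] <- fi
    ccm_log("cells frame %d/%d: cluster %.0f um^3", t, d[1],
            attr(B, "volume_um3"))
  }
  list(labels = label_volume(labels, ids, "cells", stack$voxel_size_zyx,
                             stack$frame_interval),
       cluster = masks,
       interfaces = do.call(rbind, iface))
}
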