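#' Scene configuration for the synthetic movie generator
#'
#' Describes a ground-truthed synthetic border-cell cluster: a ball-shaped
#' cluster of two central polar cells and `n_border` border cells whose
#' bodies are the Voronoi partition of the ball seeded by their nuclei.
#' Defaults emulate the reference system: 0.33 um isotropic voxels before
#' z-decimation, border-cell volume about 1250 um^3, polar-cell volume about
#' 600 um^3, nucleus diameter about 5 um, 1 min frame interval, photobleached
#' low-SNR two-channel acquisition with three-fold coarser z sampling.
#'
#' @param n_border number of border cells (>= 1).
#' @param v_border_um3,v_polar_um3 cell volumes used to size the cluster
#'   ball, um^3.
#' @param nucleus_sigma_um Gaussian sigma of a nucleus blob, um.
#' @param border_ring_radius_um radius of the border-nucleus ring, um.
#' @param polar_offset_um polar nuclei sit at +/- this offset along the polar
#'   axis (the y axis of the scene), um.
#' @param voxel_um isotropic voxel size of the rendered scene before
#'   z-decimation, um.
#' @param frame_interval min between frames.
#' @param motion_schedule list of segments; each a list with `mode`
#'   (`"running"`, `"rotating"` or `"chaotic"`), `n_frames`, and `speed`
#'   (um/min, running/chaotic) or `rate` (deg/min, rotating) plus `axis`
#'   (z,y,x unit vector).
#' @param exchange_events list of lists with `label_a`, `label_b`,
#'   `start_frame`, `duration_frames`.
#' @param protrusion_events list of lists with `owner`, `direction` (z,y,x),
#'   `length_um`, `width_um`, `start`, `duration`.
#' @param bleach_rate per-frame exponential intensity decay constant.
#' @param noise_sd additive Gaussian read-noise standard deviation
#'   (intensity units).
#' @param shot_noise logical; apply Poisson shot noise to the expected
#'   intensities.
#' @param nuclei_amp,membrane_amp peak intensities of the two channels.
#' @param channels channels to render.
#' @param z_subsample_factor keep every k-th z slice, emulating the coarser
#'   confocal motor step.
#' @param seed integer seed; identical configs give identical movies.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(n_border = 6,
                         v_border_um3 = 1250,
                         v_polar_um3 = 600,
                         nucleus_sigma_um = 1.7,
                         border_ring_radius_um = 8.5,
                         polar_offset_um = 2.5,
                         voxel_um = 0.33,
                         frame_interval = 1,
                         motion_schedule = list(list(mode = "running",
                                                     n_frames = 10,
                                                     speed = 1,
                                                     axis = c(0, 0, 1))),
                         exchange_events = list(),
                         protrusion_events = list(),
                         bleach_rate = 0.02,
                         noise_sd = 3,
                         shot_noise = TRUE,
                         nuclei_amp = 120,
                         membrane_amp = 80,
                         channels = c("nuclei", "cell_membrane"),
                         z_subsample_factor = 3,
                         seed = 1L) {
  if (n_border < 1) stop("configuration error: n_border must be >= 1")
  total_v <- n_border * v_border_um3 + 2 * v_polar_um3
  cluster_radius_um <- (3 * total_v / (4 * pi))^(1 / 3)
  if (cluster_radius_um <= nucleus_sigma_um)
    stop("configuration error: cluster radius must exceed nucleus sigma")
  for (ev in exchange_events) {
    if (ev$label_a == ev$label_b)
      stop("configuration error: exchange labels must differ")
    if (ev$duration_frames < 1)
      stop("configuration error: exchange duration must be >= 1")
  }
  for (ev in protrusion_events)
    if (ev$duration < 1)
      stop("configuration error: protrusion duration must be >= 1")
  cfg <- list(n_border = as.integer(n_border),
              v_border_um3 = v_border_um3, v_polar_um3 = v_polar_um3,
              cluster_radius_um = cluster_radius_um,
              nucleus_sigma_um = nucleus_sigma_um,
              border_ring_radius_um = border_ring_radius_um,
              polar_offset_um = polar_offset_um,
              voxel_um = voxel_um, frame_interval = frame_interval,
              motion_schedule = motion_schedule,
              exchange_events = exchange_events,
              protrusion_events = protrusion_events,
              bleach_rate = bleach_rate, noise_sd = noise_sd,
              shot_noise = shot_noise,
              nuclei_amp = nuclei_amp, membrane_amp = membrane_amp,
              channels = channels,
              z_subsample_factor = as.integer(z_subsample_factor),
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

# initial cluster-frame nucleus offsets (um, z/y/x rows), polar first
scene_offsets <- function(cfg) {
  k <- cfg$n_border
  ang <- 2 * pi * (seq_len(k) - 1) / k
  border <- cbind(cfg$border_ring_radius_um * sin(ang), 0,
                  cfg$border_ring_radius_um * cos(ang))   # ring in z-x plane
  polar <- rbind(c(0, cfg$polar_offset_um, 0),
                 c(0, -cfg$polar_offset_um, 0))
  off <- rbind(polar, border)
  d <- as.matrix(stats::dist(off))
  diag(d) <- Inf
  if (min(d) < 2 * cfg$nucleus_sigma_um)
    stop("configuration error: initial nuclei closer than 2 * nucleus_sigma")
  off
}

#' Inject a neighbour-exchange event into per-frame center positions
#'
#' The two implicated centers follow smooth arcs that swap their
#' cluster-frame positions over `duration_frames`, bulging perpendicular to
#' the chord so they pass around rather than through each other; all other
#' positions are untouched.
#'
#' @param positions T x K x 3 numeric array of per-frame (z, y, x) centers.
#' @param event list with `label_a`, `label_b` (indices into the K axis),
#'   `start_frame`, `duration_frames`.
#' @return modified positions array.
#' @export
inject_exchange <- function(positions, event) {
  a <- event$label_a; b <- event$label_b
  if (a == b) stop("configuration error: exchange labels must differ")
  T_ <- dim(positions)[1]
  t0 <- event$start_frame
  dur <- event$duration_frames
  if (t0 < 1 || t0 + dur > T_) stop("exchange event frames out of range")
  pa <- positions[t0, a, ]
  pb <- positions[t0, b, ]
  chord <- pb - pa
  # perpendicular bulge direction: any unit vector orthogonal to the chord
  ref <- if (abs(chord[1]) < 0.9 * vnorm(chord)) c(1, 0, 0) else c(0, 1, 0)
  perp <- unitize(cross3(chord, ref))
  # lateral deviation of the passing arcs: the cells squeeze past each other
  # at a closest approach of 2 x 0.12 x chord (about one nucleus diameter
  # for a trans-cluster exchange)
  bulge <- 0.12 * vnorm(chord)
  for (t in t0:(t0 + dur)) {
    s <- (t - t0) / dur
    s2 <- s * s * (3 - 2 * s)       # smoothstep
    arc <- bulge * sin(pi * s2) * perp
    positions[t, a, ] <- (1 - s2) * pa + s2 * pb + arc
    positions[t, b, ] <- (1 - s2) * pb + s2 * pa - arc
  }
  if (t0 + dur < T_) {
    # keep the swap for the remainder of the movie
    for (t in (t0 + dur + 1):T_) {
      tmp <- positions[t, a, ]
      positions[t, a, ] <- positions[t, b, ]
      positions[t, b, ] <- tmp
    }
  }
  positions
}

# squared distance of every voxel (0-based grid, spacing voxel_um) to point p
dist2_grid <- function(dims, voxel_um, p) {
  dz <- ((0:(dims[1] - 1)) * voxel_um - p[1])^2
  dy <- ((0:(dims[2] - 1)) * voxel_um - p[2])^2
  dx <- ((0:(dims[3] - 1)) * voxel_um - p[3])^2
  outer(outer(dz, dy, "+"), dx, "+")
}

#' Generate a ground-truthed synthetic movie of a migrating cluster
#'
#' Renders the scene described by a [scene_config()]: cell bodies are the
#' Voronoi partition of the cluster ball seeded by the nuclei, the nuclei
#' channel is a sum of Gaussian blobs, the membrane channel is the
#' one-voxel-thick inter-cell boundary shell (plus the cluster surface)
#' lightly blurred, protrusions are cylinders unioned to their owner's label
#' and the cluster mask. Degradation (photobleaching, shot and read noise,
#' z-decimation) is applied to the intensity channels only; the returned
#' ground truth is untouched by it.
#'
#' @param cfg a `scene_config`.
#' @return list with `movie` (a [movie_stack()], z-decimated) and `truth`,
#'   a list holding `nuclei_labels` / `cell_labels` ([label_volume()], full
#'   resolution), `tracks` (data.frame of true per-frame nucleus centers in
#'   um), `cluster_center` (T x 3), `mode` (per-frame character),
#'   `event_log` (data.frame), `identity_map`, and the scene voxel size.
#' @export
generate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(derive_seed(cfg$seed, "generate_movie"))
  off0 <- scene_offsets(cfg)
  K <- nrow(off0)
  T_ <- sum(vapply(cfg$motion_schedule, function(s) s$n_frames, numeric(1)))
  dt <- cfg$frame_interval

  # cluster-frame offsets per frame (chaotic jitter + exchanges live here)
  offsets <- array(0, dim = c(T_, K, 3))
  for (t in seq_len(T_)) offsets[t, , ] <- off0

  # accumulate rigid motion: rotation Q(t) and center c(t)
  Qs <- vector("list", T_)
  center <- matrix(0, T_, 3)
  mode_lab <- character(T_)
  Q <- diag(3)
  cpos <- c(0, 0, 0)
  t <- 1L
  Qs[[1]] <- Q; center[1, ] <- cpos
  for (seg in cfg$motion_schedule) {
    for (i in seq_len(seg$n_frames)) {
      mode_lab[t] <- seg$mode
      if (t == T_) break
      if (seg$mode == "running") {
        cpos <- cpos + unitize(seg$axis) * seg$speed * dt
      } else if (seg$mode == "rotating") {
        Q <- rotation_matrix(seg$axis, seg$rate * pi / 180 * dt) %*% Q
        if (!is.null(seg$drift) && seg$drift > 0)
          cpos <- cpos + unitize(seg$drift_axis %||% c(0, 0, 1)) *
            seg$drift * dt
      } else if (seg$mode == "chaotic") {
        # per-cell isotropic random steps around the home offsets
        step <- matrix(rnorm(K * 3), K, 3)
        step <- step / sqrt(rowSums(step^2)) * seg$speed * dt
        offsets[t + 1, , ] <- off0 +
          0.6 * (offsets[t, , ] - off0) + step
      } else stop("unknown motion mode: ", seg$mode)
      t <- t + 1L
      Qs[[t]] <- Q
      center[t, ] <- cpos
      if (mode_lab[max(1, t - 1)] != "chaotic")
        offsets[t, , ] <- offsets[t - 1, , ]
    }
  }
  mode_lab[mode_lab == ""] <- mode_lab[max(which(mode_lab != ""))]

  for (ev in cfg$exchange_events) offsets <- inject_exchange(offsets, ev)

  # world positions (um, scene frame)
  pos <- array(0, dim = c(T_, K, 3))
  for (t in seq_len(T_))
    pos[t, , ] <- t(Qs[[t]] %*% t(offsets[t, , ])) +
      matrix(center[t, ], K, 3, byrow = TRUE)

  # bounding box
  max_prot <- if (length(cfg$protrusion_events))
    max(vapply(cfg$protrusion_events, function(e) e$length_um, numeric(1)))
  else 0
  margin <- cfg$cluster_radius_um + max_prot + 2.5
  lo <- apply(center, 2, min) - margin
  hi <- apply(center, 2, max) + margin
  v <- cfg$voxel_um
  dims <- ceiling((hi - lo) / v) + 1L
  # make (Z - 1) divisible by the decimation factor so resampling restores
  # the full grid exactly
  k <- cfg$z_subsample_factor
  dims[1] <- dims[1] + (k - (dims[1] - 1L) %% k) %% k
  dims <- as.integer(dims)
  origin <- lo
  # positions in box coordinates
  for (t in seq_len(T_))
    pos[t, , ] <- pos[t, , ] - matrix(origin, K, 3, byrow = TRUE)
  center <- sweep(center, 2, origin)

  nCh <- length(cfg$channels)
  Zd <- length(seq(1L, dims[1], by = k))
  movie <- array(0, dim = c(T_, nCh, Zd, dims[2], dims[3]))
  nuc_gt <- array(0L, dim = c(T_, dims[1], dims[2], dims[3]))
  cell_gt <- array(0L, dim = c(T_, dims[1], dims[2], dims[3]))
  nuc_r <- 1.5 * cfg$nucleus_sigma_um

  prot_log <- list()
  for (t in seq_len(T_)) {
    d2c <- dist2_grid(dims, v, center[t, ])
    ball <- d2c <= cfg$cluster_radius_um^2
    idx <- which(ball)
    ai <- arrayInd(idx, dims)
    coords <- (ai - 1) * v
    # Voronoi cells within the ball
    dmat <- matrix(0, length(idx), K)
    for (j in seq_len(K))
      dmat[, j] <- (coords[, 1] - pos[t, j, 1])^2 +
        (coords[, 2] - pos[t, j, 2])^2 + (coords[, 3] - pos[t, j, 3])^2
    lab <- max.col(-dmat, ties.method = "first")
    cells <- array(0L, dims)
    cells[idx] <- lab
    nuc <- array(0L, dims)
    nn <- which(dmat[cbind(seq_along(lab), lab)] <= nuc_r^2)
    nuc[idx[nn]] <- lab[nn]

    # protrusion cylinders
    for (ei in seq_along(cfg$protrusion_events)) {
      ev <- cfg$protrusion_events[[ei]]
      if (t < ev$start || t >= ev$start + ev$duration) next
      grow <- min(1, (t - ev$start + 1) / ev$duration)
      dirn <- unitize(ev$direction)
      p0 <- center[t, ] + (cfg$cluster_radius_um - 2) * dirn
      p1 <- center[t, ] + (cfg$cluster_radius_um + grow * ev$length_um) * dirn
      cyl <- cylinder_voxels(dims, v, p0, p1, ev$width_um / 2)
      newvox <- cyl[cells[cyl] == 0L]
      cells[newvox] <- as.integer(ev$owner)
      prot_log[[length(prot_log) + 1L]] <-
        data.frame(event = ei, frame = t, owner = ev$owner,
                   dir_z = dirn[1], dir_y = dirn[2], dir_x = dirn[3],
                   voxels_added = length(newvox))
    }
    cell_gt[t, , , ] <- cells
    nuc_gt[t, , , ] <- nuc

    # channels
    decay <- exp(-cfg$bleach_rate * (t - 1))
    for (ci in seq_along(cfg$channels)) {
      ch <- cfg$channels[ci]
      if (ch == "nuclei") {
        img <- gaussian_blobs(dims, v, pos[t, , , drop = TRUE],
                              cfg$nucleus_sigma_um, cfg$nuclei_amp)
      } else if (ch == "cell_membrane") {
        shell <- .cpp_boundary6(cells, TRUE)
        img <- array(as.numeric(shell) * cfg$membrane_amp, dims)
        img <- gaussian_filter3(img, 0.4, v)
      } else if (ch == "nurse_membrane") {
        img <- nurse_foam(dims, v, cells,
                          cfg$membrane_amp, derive_seed(cfg$seed, "nurse"))
      } else stop("unknown channel: ", ch)
      img <- img * decay
      if (cfg$shot_noise) img <- array(rpois(length(img), pmax(img, 0)), dims)
      if (cfg$noise_sd > 0)
        img <- img + rnorm(length(img), 0, cfg$noise_sd)
      img <- pmax(img, 0)
      movie[t, ci, , , ] <- img[seq(1L, dims[1], by = k), , ]
    }
  }

  identity_map <- setNames(c("polar", "polar", rep("border", cfg$n_border)),
                           as.character(seq_len(K)))
  tracks <- do.call(rbind, lapply(seq_len(T_), function(t)
    data.frame(label = seq_len(K), identity = unname(identity_map),
               frame = t, z = pos[t, , 1], y = pos[t, , 2], x = pos[t, , 3])))
  ex_log <- if (length(cfg$exchange_events))
    do.call(rbind, lapply(seq_along(cfg$exchange_events), function(i) {
      ev <- cfg$exchange_events[[i]]
      data.frame(event = i, label_a = ev$label_a, label_b = ev$label_b,
                 start_frame = ev$start_frame,
                 duration_frames = ev$duration_frames)
    }))
  else data.frame(event = integer(0), label_a = integer(0),
                  label_b = integer(0), start_frame = integer(0),
                  duration_frames = integer(0))

  stack <- movie_stack(movie, cfg$channels, c(v * k, v, v),
                       cfg$frame_interval)
  truth <- list(
    nuclei_labels = label_volume(nuc_gt, identity_map, "nuclei",
                                 rep(v, 3), cfg$frame_interval),
    cell_labels = label_volume(cell_gt, identity_map, "cells",
                               rep(v, 3), cfg$frame_interval),
    tracks = tracks,
    cluster_center = center,
    mode = mode_lab,
    event_log = ex_log,
    protrusion_log = if (length(prot_log)) do.call(rbind, prot_log)
                     else NULL,
    identity_map = identity_map,
    voxel_um = v,
    origin_um = origin)
  list(movie = stack, truth = truth)
}

# sum of isotropic Gaussian blobs rendered on local patches (+/- 4 sigma)
gaussian_blobs <- function(dims, voxel_um, centers, sigma_um, amp) {
  img <- array(0, dims)
  r <- ceiling(4 * sigma_um / voxel_um)
  for (j in seq_len(nrow(centers))) {
    cj <- centers[j, ] / voxel_um            # 0-based voxel coords
    lo <- pmax(floor(cj) - r, 0)
    hi <- pmin(ceiling(cj) + r, dims - 1)
    if (any(hi < lo)) next
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    gz <- exp(-((zz - cj[1]) * voxel_um)^2 / (2 * sigma_um^2))
    gy <- exp(-((yy - cj[2]) * voxel_um)^2 / (2 * sigma_um^2))
    gx <- exp(-((xx - cj[3]) * voxel_um)^2 / (2 * sigma_um^2))
    patch <- amp * outer(outer(gz, gy), gx)
    img[zz + 1, yy + 1, xx + 1] <- img[zz + 1, yy + 1, xx + 1] + patch
  }
  img
}

# voxel linear indices within a cylinder around segment p0-p1 (um)
cylinder_voxels <- function(dims, voxel_um, p0, p1, radius_um) {
  lo <- pmax(floor(pmin(p0, p1) / voxel_um) - ceiling(radius_um / voxel_um) - 1, 0)
  hi <- pmin(ceiling(pmax(p0, p1) / voxel_um) + ceiling(radius_um / voxel_um) + 1,
             dims - 1)
  if (any(hi < lo)) return(integer(0))
  zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
  g <- expand.grid(z = zz, y = yy, x = xx)
  p <- as.matrix(g) * voxel_um
  ax <- p1 - p0
  L2 <- sum(ax^2)
  w <- sweep(p, 2, p0)
  tt <- pmin(pmax((w %*% ax) / L2, 0), 1)
  proj <- outer(as.vector(tt), ax)
  d2 <- rowSums((w - proj)^2)
  keep <- d2 <= radius_um^2
  gi <- as.matrix(g[keep, , drop = FALSE])
  as.integer(gi[, 1] + 1 + dims[1] * (gi[, 2] + dims[2] * gi[, 3]))
}

# Voronoi foam of substrate membranes outside the cluster
nurse_foam <- function(dims, voxel_um, cells, amp, seed) {
  set.seed(seed)
  ext <- dims * voxel_um
  n_seed <- max(8L, ceiling(prod(ext) / 15^3))
  seeds <- cbind(runif(n_seed, 0, ext[1]), runif(n_seed, 0, ext[2]),
                 runif(n_seed, 0, ext[3]))
  # nearest-seed labels on a coarse lattice via EDT feature transform
  sm <- array(0L, dims)
  si <- round(seeds / voxel_um) + 1
  si[, 1] <- pmin(pmax(si[, 1], 1), dims[1])
  si[, 2] <- pmin(pmax(si[, 2], 1), dims[2])
  si[, 3] <- pmin(pmax(si[, 3], 1), dims[3])
  lin <- si[, 1] + dims[1] * ((si[, 2] - 1) + dims[2] * (si[, 3] - 1))
  sm[lin] <- seq_len(n_seed)
  ft <- distance_transform3(sm, voxel_um)$feature
  vor <- array(sm[ft], dims)
  vor[cells > 0] <- 0L
  shell <- .cpp_boundary6(vor, FALSE)
  img <- array(as.numeric(shell) * amp, dims)
  gaussian_filter3(img, 0.4, voxel_um)
}
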