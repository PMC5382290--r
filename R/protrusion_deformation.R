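#' Detect cluster external protrusions by morphological opening
#'
#' The protrusion set is `B \ opening(B, ball(r))`: the opening (erosion
#' then dilation with the same Euclidean ball) removes every structure
#' thinner than the ball, so elongated extensions along the cluster's
#' outward normal remain as the residue. The ball radius is the radius of
#' the sphere with the mean border-cell volume, `r = (3 V / (4 pi))^(1/3)`.
#'
#' @param B 3D logical cluster mask.
#' @param r_um opening ball radius, um.
#' @param voxel_um working voxel size, um.
#' @return list with `protrusion` (logical array), `body` (the opening,
#'   i.e. the cluster body) - both subsets of `B`.
#' @details On a voxel grid the exact Euclidean opening chips a thin rind
#'   off even a perfectly smooth ball (the swept ball cannot reproduce the
#'   voxelized sphere surface), which would register as a spurious shell
#'   protrusion. The erosion is therefore given a half-voxel radius
#'   tolerance - `body = B intersect dilate(erode(B, r - voxel/2), r)` -
#'   which restores the continuum invariant that a ball of radius > r has
#'   no residue while still removing every structure thinner than the ball.
#' @export
detect_protrusion <- function(B, r_um, voxel_um = 0.33) {
  if (r_um < voxel_um)
    stop("configuration error: opening radius below one voxel")
  body <- B & ball_dilate(ball_erode(B, r_um - voxel_um / 2, voxel_um),
                          r_um, voxel_um)
  prot <- B & !body
  list(protrusion = prot, body = body)
}

#' Sphere-equivalent opening radius from a mean cell volume
#' @param v_mean_um3 mean border-cell volume, um^3.
#' @return radius in um.
#' @export
opening_radius <- function(v_mean_um3) (3 * v_mean_um3 / (4 * pi))^(1 / 3)

#' Per-frame protrusion statistics
#'
#' Volume and rate (volume / frame interval), protrusion direction (unit
#' vector from the cluster body mass center to the protrusion mass center),
#' and owner cell (modal cell label inside the protrusion). The cluster
#' body center `m(t)` is the mass center of the opening; the caller obtains
#' the cluster speed from consecutive `m(t)`.
#'
#' @param prot logical protrusion voxel set (from [detect_protrusion()]).
#' @param body logical cluster-body mask (the opening).
#' @param cells 3D integer cell label array (may be NULL; owner then NA).
#' @param voxel_um working voxel size, um.
#' @param dt_min frame interval, minutes.
#' @return one-row data.frame: `volume_um3`, `rate_um3_min`, `dir_z`,
#'   `dir_y`, `dir_x` (NA when the direction cancels or volume is 0),
#'   `owner`, `m_z`, `m_y`, `m_x` (cluster body center, um).
#' @export
protrusion_stats <- function(prot, body, cells = NULL, voxel_um = 0.33,
                             dt_min = 1) {
  vox <- voxel_um^3
  m <- mass_center(body, voxel_um)
  vol <- sum(prot) * vox
  if (vol == 0) {
    return(data.frame(volume_um3 = 0, rate_um3_min = 0,
                      dir_z = NA_real_, dir_y = NA_real_, dir_x = NA_real_,
                      owner = NA_integer_,
                      m_z = m[1], m_y = m[2], m_x = m[3]))
  }
  pc <- mass_center(prot, voxel_um)
  dirv <- pc - m
  dirn <- if (vnorm(dirv) < voxel_um / 2) rep(NA_real_, 3) else unitize(dirv)
  owner <- NA_integer_
  if (!is.null(cells)) {
    inside <- cells[prot & cells > 0]
    if (length(inside)) owner <- as.integer(names(which.max(table(inside))))
  }
  data.frame(volume_um3 = vol, rate_um3_min = vol / dt_min,
             dir_z = dirn[1], dir_y = dirn[2], dir_x = dirn[3],
             owner = owner, m_z = m[1], m_y = m[2], m_x = m[3])
}

mass_center <- function(mask, voxel_um) {
  idx <- which(mask)
  ai <- (arrayInd(idx, dim(mask)) - 1) * voxel_um
  colMeans(ai)
}

#' Protrusion alignment with the cluster direction
#'
#' `PA(t) = d_prot(t) . d_cluster(t)` (both unit vectors): 1 when the
#' cluster moves along its protrusion, -1 when opposite. Frames with either
#' vector undefined are dropped.
#'
#' @param prot_dirs T x 3 matrix of protrusion unit directions.
#' @param cluster_dirs T x 3 matrix of cluster unit directions.
#' @return list with `pa` (per-frame series, NA where undefined) and
#'   `mean_pa`.
#' @export
protrusion_alignment <- function(prot_dirs, cluster_dirs) {
  pa <- rowSums(prot_dirs * cluster_dirs)
  if (all(is.na(pa))) {
    warning("no frame with both directions defined")
    return(list(pa = pa, mean_pa = NA_real_))
  }
  list(pa = pa, mean_pa = mean(pa, na.rm = TRUE))
}

#' Pearson correlation of two series
#'
#' Thin guard around [stats::cor()]: requires at least 3 paired
#' observations and nonzero variance in both series, returning NA with a
#' warning otherwise.
#'
#' @param X,Y numeric series (pairwise complete observations used).
#' @return scalar in \[-1, 1\] or NA.
#' @export
pearson <- function(X, Y) {
  ok <- is.finite(X) & is.finite(Y)
  if (sum(ok) < 3) {
    warning("fewer than 3 paired observations")
    return(NA_real_)
  }
  if (sd(X[ok]) == 0 || sd(Y[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(X[ok], Y[ok])
}

#' Signed surface-deformation field between two frames of one cell
#'
#' Surfaces are the 6-connected boundary voxels. A surface voxel of the
#' later frame lying outside the earlier cell is a positive sample (the
#' surface moved into previously unoccupied space); a surface voxel of the
#' earlier frame outside the later cell is a negative sample (retraction).
#' Magnitudes are distances (um) to the nearest surface voxel of the other
#' frame, realized through the exact Euclidean feature transform; each
#' sample also carries the displacement vector from its nearest match.
#' Summaries: MPD/MND = maximum positive/negative magnitude, PDE/NDE =
#' summed magnitudes.
#'
#' @param cell_t,cell_t1 3D logical voxel sets of the cell at t and t+1.
#' @param voxel_um working voxel size, um.
#' @return list with `positive` / `negative` (data.frames: voxel index,
#'   `z`, `y`, `x` um, `mag_um`, `vz`, `vy`, `vx`) and scalars `mpd`,
#'   `mnd`, `pde`, `nde`.
#' @export
deformation_map <- function(cell_t, cell_t1, voxel_um = 0.33) {
  if (!any(cell_t) || !any(cell_t1))
    stop("degenerate-cell error: empty voxel set")
  # crop to the union bounding box (plus one voxel): every sample and every
  # candidate nearest-surface voxel lies inside, so distances are exact
  dims <- dim(cell_t)
  ai <- arrayInd(which(cell_t | cell_t1), dims)
  lo <- pmax(apply(ai, 2, min) - 1L, 1L)
  hi <- pmin(apply(ai, 2, max) + 1L, dims)
  crop <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  off <- lo - 1L                       # voxel offset of the crop origin
  cell_t <- crop(cell_t)
  cell_t1 <- crop(cell_t1)
  s_t <- surface_voxels3(cell_t)
  s_t1 <- surface_voxels3(cell_t1)
  samples <- function(surf_new, other_set, other_surf) {
    idx <- which(surf_new & !other_set)
    if (!length(idx)) {
      return(data.frame(index = integer(0), z = numeric(0), y = numeric(0),
                        x = numeric(0), mag_um = numeric(0), vz = numeric(0),
                        vy = numeric(0), vx = numeric(0)))
    }
    ft <- distance_transform3(other_surf, voxel_um)
    pv <- arrayInd(idx, dim(surf_new)) - 1
    P <- sweep(pv, 2, off, "+") * voxel_um
    near <- ft$feature[idx]
    Q <- sweep(arrayInd(near, dim(surf_new)) - 1, 2, off, "+") * voxel_um
    V <- P - Q
    orig_idx <- (pv[, 1] + off[1]) + 1 +
      dims[1] * ((pv[, 2] + off[2]) + dims[2] * (pv[, 3] + off[3]))
    data.frame(index = orig_idx, z = P[, 1], y = P[, 2], x = P[, 3],
               mag_um = ft$dist[idx], vz = V[, 1], vy = V[, 2], vx = V[, 3])
  }
  pos <- samples(s_t1, cell_t, s_t)
  neg <- samples(s_t, cell_t1, s_t1)
  list(positive = pos, negative = neg,
       mpd = if (nrow(pos)) max(pos$mag_um) else 0,
       mnd = if (nrow(neg)) max(neg$mag_um) else 0,
       pde = sum(pos$mag_um), nde = sum(neg$mag_um))
}

#' Deformation fields for every cell over a movie
#'
#' @param cells a cells [label_volume()].
#' @return nested list `fields[[t]][[label]]` of [deformation_map()] results
#'   for frame pairs (t, t+1).
#' @export
deformation_fields <- function(cells) {
  d <- dim(cells$labels)
  v <- cells$voxel_size_zyx[1]
  labs <- as.integer(names(cells$identity_map))
  out <- vector("list", d[1] - 1)
  for (t in seq_len(d[1] - 1)) {
    f0 <- get_label_frame(cells, t)
    f1 <- get_label_frame(cells, t + 1)
    out[[t]] <- setNames(lapply(labs, function(l)
      deformation_map(f0 == l, f1 == l, v)), labs)
  }
  out
}

#' Per-frame cell-mobility parameter table
#'
#' The six mobility parameters: nucleus speed (NS) and cell speed (CS) from
#' the track tables, and MPD, MND, PDE, NDE averaged over cells from the
#' deformation fields. Reported per frame pair.
#'
#' @param nucleus_tracks,cell_tracks `track_table`s over the same frames.
#' @param fields a [deformation_fields()] result.
#' @return data.frame with `frame`, `ns`, `cs`, `mpd`, `mnd`, `pde`, `nde`.
#' @export
mobility_params <- function(nucleus_tracks, cell_tracks, fields) {
  T_ <- max(nucleus_tracks$frame)
  if (max(cell_tracks$frame) != T_ || length(fields) != T_ - 1)
    stop("alignment error: tracks and fields cover different frames")
  rows <- lapply(seq_len(T_ - 1), function(t) {
    ns <- mean(nucleus_tracks$speed[nucleus_tracks$frame == t], na.rm = TRUE)
    cs <- mean(cell_tracks$speed[cell_tracks$frame == t], na.rm = TRUE)
    fl <- fields[[t]]
    data.frame(frame = t, ns = ns, cs = cs,
               mpd = mean(vapply(fl, `[[`, numeric(1), "mpd")),
               mnd = mean(vapply(fl, `[[`, numeric(1), "mnd")),
               pde = mean(vapply(fl, `[[`, numeric(1), "pde")),
               nde = mean(vapply(fl, `[[`, numeric(1), "nde")))
  })
  do.call(rbind, rows)
}

#' Association between cluster rotation and internal cell extensions
#'
#' Per frame pair: the combined cluster rotating vector
#' `R = sum_k cross(r_hat_k, v_k)` from the nuclei displacement vectors,
#' and the combined protrusion rotating vector
#' `Q = sum_k cross(r_hat_k, u_k)` where `u_k` is the sum of cell k's
#' positive deformation vectors; the angle between them, and over the movie
#' the Pearson correlation of their magnitudes. Frames where either vector
#' vanishes are excluded from the angle average.
#'
#' @param tracks nucleus `track_table`.
#' @param fields a [deformation_fields()] result (cells).
#' @param c_m T x 3 matrix of cluster centers (um); default: per-frame mean
#'   of nucleus centers.
#' @return list with `per_frame` (data.frame: `frame`, `R_mag`, `Q_mag`,
#'   `angle_deg`), `mean_angle_deg`, `correlation`.
#' @export
rotation_association <- function(tracks, fields, c_m = NULL) {
  T_ <- max(tracks$frame)
  if (T_ < 3) stop("need at least 3 frames")
  labs <- sort(unique(tracks$label))
  if (is.null(c_m)) {
    c_m <- t(vapply(seq_len(T_), function(t) {
      ft <- tracks[tracks$frame == t, ]
      colMeans(as.matrix(ft[, c("z", "y", "x")]))
    }, numeric(3)))
  }
  rows <- lapply(seq_len(T_ - 1), function(t) {
    ft <- tracks[tracks$frame == t, ]
    Rv <- c(0, 0, 0)
    Qv <- c(0, 0, 0)
    for (l in labs) {
      row <- ft[ft$label == l, ]
      r <- c(row$z, row$y, row$x) - c_m[t, ]
      if (vnorm(r) == 0) next
      rh <- r / vnorm(r)
      vk <- c(row$dz, row$dy, row$dx)
      if (all(is.finite(vk))) Rv <- Rv + cross3(rh, vk)
      fl <- fields[[t]][[as.character(l)]]
      if (!is.null(fl) && nrow(fl$positive)) {
        uk <- c(sum(fl$positive$vz), sum(fl$positive$vy),
                sum(fl$positive$vx))
        Qv <- Qv + cross3(rh, uk)
      }
    }
    Rm <- vnorm(Rv); Qm <- vnorm(Qv)
    ang <- if (Rm > 0 && Qm > 0)
      acos(pmin(1, pmax(-1, sum(Rv * Qv) / (Rm * Qm)))) * 180 / pi
    else NA_real_
    data.frame(frame = t, R_mag = Rm, Q_mag = Qm, angle_deg = ang)
  })
  pf <- do.call(rbind, rows)
  list(per_frame = pf,
       mean_angle_deg = mean(pf$angle_deg, na.rm = TRUE),
       correlation = if (nrow(pf) >= 3) pearson(pf$R_mag, pf$Q_mag)
                     else NA_real_)
}

#' Protrusion analysis of a whole movie
#'
#' Runs [detect_protrusion()] and [protrusion_stats()] per frame on the
#' cluster masks, derives cluster speed/direction from the body mass
#' centers, and computes the alignment (PA), combined-direction (CD) and
#' protrusion-mass (CS) statistics.
#'
#' @param masks T-length list of cluster masks.
#' @param cell_labels optional cells [label_volume()] for protrusion
#'   ownership.
#' @param v_border_mean_um3 mean border-cell volume defining the opening
#'   radius.
#' @param voxel_um working voxel size, um.
#' @param dt_min frame interval, minutes.
#' @return list with `stats` (per-frame data.frame incl. cluster speed and
#'   PA), `mean_pa`, `cd`, `cs`.
#' @export
protrusion_series <- function(masks, cell_labels = NULL,
                              v_border_mean_um3 = 1250, voxel_um = 0.33,
                              dt_min = 1) {
  T_ <- length(masks)
  r <- opening_radius(v_border_mean_um3)
  st <- vector("list", T_)
  for (t in seq_len(T_)) {
    det <- detect_protrusion(masks[[t]], r, voxel_um)
    cells <- if (!is.null(cell_labels)) get_label_frame(cell_labels, t)
             else NULL
    st[[t]] <- cbind(frame = t,
                     protrusion_stats(det$protrusion, det$body, cells,
                                      voxel_um, dt_min))
  }
  st <- do.call(rbind, st)
  # cluster velocity from body mass centers
  M <- as.matrix(st[, c("m_z", "m_y", "m_x")])
  V <- rbind(M[-1, , drop = FALSE] - M[-T_, , drop = FALSE],
             c(NA, NA, NA)) / dt_min
  sp <- sqrt(rowSums(V^2))
  U <- V / sp
  U[!is.finite(U)] <- NA
  st$cluster_speed <- sp
  st$cdir_z <- U[, 1]; st$cdir_y <- U[, 2]; st$cdir_x <- U[, 3]
  pa <- protrusion_alignment(as.matrix(st[, c("dir_z", "dir_y", "dir_x")]),
                             U)
  st$pa <- pa$pa
  # CD: magnitude of the per-frame combined (normalized) protrusion
  # direction vs cluster speed; with one protrusion per frame the combined
  # magnitude is 1 wherever a protrusion exists, 0 otherwise
  comb <- as.matrix(st[, c("dir_z", "dir_y", "dir_x")])
  comb[is.na(comb)] <- 0
  cd <- tryCatch(pearson(sqrt(rowSums(comb^2)), st$cluster_speed),
                 warning = function(w) NA_real_)
  cs <- tryCatch(pearson(st$volume_um3, st$cluster_speed),
                 warning = function(w) NA_real_)
  list(stats = st, mean_pa = pa$mean_pa, cd = cd, cs = cs)
}
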