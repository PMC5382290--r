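# Shared fixtures: compact synthetic scenes kept small so the suite stays
# fast; geometry ratios match the full-scale defaults.

tiny_scene <- function(mode = "running", n_frames = 4, seed = 7,
                       speed = 1, rate = 20, ...) {
  sched <- switch(mode,
    running = list(list(mode = "running", n_frames = n_frames,
                        speed = speed, axis = c(0, 0, 1))),
    rotating = list(list(mode = "rotating", n_frames = n_frames,
                         rate = rate, axis = c(0, 1, 0))),
    chaotic = list(list(mode = "chaotic", n_frames = n_frames,
                        speed = speed)))
  args <- utils::modifyList(
    list(n_border = 4, v_border_um3 = 400, v_polar_um3 = 200,
         nucleus_sigma_um = 1.2, border_ring_radius_um = 5,
         polar_offset_um = 2, voxel_um = 0.5,
         motion_schedule = sched, z_subsample_factor = 2, seed = seed),
    list(...))
  do.call(scene_config, args)
}

tiny_annotation <- function(truth, voxel_um) {
  tr1 <- truth$tracks[truth$tracks$frame == 1, ]
  out <- data.frame(label = tr1$label, identity = tr1$identity,
                    z = round(tr1$z / voxel_um), y = round(tr1$y / voxel_um),
                    x = round(tr1$x / voxel_um))
  class(out) <- c("annotation", "data.frame")
  out
}

# solid ball mask on a cubic grid (voxel units)
ball_mask <- function(n, center, r) {
  ai <- arrayInd(seq_len(n^3), c(n, n, n))
  m <- rowSums(sweep(ai, 2, center)^2) <= r^2
  array(m, c(n, n, n))
}

# brute-force assignment oracle: enumerate all permutations
perm_all <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- perm_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(p >= k, p + 1L, p))))
}

brute_force_assignment <- function(S) {
  n <- nrow(S)
  P <- perm_all(n)
  vals <- apply(P, 1, function(p) sum(S[cbind(seq_len(n), p)]))
  max(vals)
}

# hexagonal ring of K centers used for exchange-metric scenes
ring_positions <- function(T_, K = 6, radius = 8.5) {
  ang <- 2 * pi * (seq_len(K) - 1) / K
  pos <- array(0, c(T_, K, 3))
  for (t in seq_len(T_))
    pos[t, , ] <- cbind(radius * sin(ang), 0, radius * cos(ang))
  pos
}

# protrusion analysis of a two-channel movie from membrane-channel cluster
# masks, preprocessing one frame at a time to bound memory
membrane_mask_protrusions <- function(movie, cfg) {
  v <- cfg$target_voxel_um
  v_target <- 6 * cfg$v_border_ref + 2 * cfg$v_polar_ref
  ci <- match("cell_membrane", movie$channel_names)
  d <- dim(movie$data)
  T_ <- d[1]
  tot1 <- NULL
  masks <- vector("list", T_)
  for (t in seq_len(T_)) {
    fr <- array(movie$data[t, ci, , , , drop = FALSE], dim = c(1, 1, d[3:5]))
    iso <- resample_isotropic(movie_stack(fr, "cell_membrane",
                                          movie$voxel_size_zyx,
                                          movie$frame_interval), v)
    tot <- sum(iso$data)
    if (t == 1L) tot1 <- tot
    iso$data <- iso$data * tot1 / tot      # bleach gain vs frame 1
    den <- denoise_background(iso, cfg$gaussian_sigma_um, cfg$bg_radius_um)
    comb <- gaussian_filter3(get_frame(den, 1, "cell_membrane"),
                             cfg$cluster_smooth_um, v)
    masks[[t]] <- suppressWarnings(cluster_mask(comb, v_target, v))
  }
  protrusion_series(masks, NULL, cfg$v_border_ref, v, movie$frame_interval)
}

random_rigid_transform <- function() {
  ax <- ccmigrate:::unitize(rnorm(3))
  th <- runif(1, 0, 2 * pi)
  list(R = ccmigrate:::rotation_matrix(ax, th), t = rnorm(3, 0, 10))
}
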