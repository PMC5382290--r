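#' Resample a movie onto an isotropic grid
#'
#' Per frame and channel, trilinear interpolation onto a grid of voxel size
#' `target_um` covering the same physical extent (within one voxel).
#' Compensates the coarser confocal z step; output geometry downstream is
#' isotropic.
#'
#' @param stack a [movie_stack()].
#' @param target_um target isotropic voxel size, um.
#' @return a resampled `movie_stack`.
#' @export
resample_isotropic <- function(stack, target_um) {
  if (target_um <= 0) stop("target_um must be > 0")
  d <- dim(stack$data)
  vs <- stack$voxel_size_zyx
  extent <- (d[3:5] - 1) * vs
  if (any(extent < target_um) && any(d[3:5] > 1))
    stop("degenerate-output error: target voxel exceeds image extent")
  if (all(abs(vs - target_um) < 1e-12)) return(stack)
  out_dim <- as.integer(round(extent / target_um) + 1)
  out <- array(0, dim = c(d[1], d[2], out_dim))
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    fr <- get_frame(stack, t, ch)
    out[t, ch, , , ] <- .cpp_resize3_trilinear(fr, out_dim, vs,
                                               rep(target_um, 3))
  }
  movie_stack(out, stack$channel_names, rep(target_um, 3),
              stack$frame_interval)
}

#' Correct photobleaching by total-fluorescence normalization
#'
#' Assumes the specimen carries a constant amount of fluorophore: each
#' frame of each channel is rescaled so its total intensity (after optional
#' background offset subtraction) matches frame 1. Gains at frame 1 are 1 by
#' construction.
#'
#' @param stack a [movie_stack()].
#' @param background constant background offset subtracted before computing
#'   totals (default 0).
#' @return list with `stack` (corrected movie) and `report`, a data.frame
#'   with per channel/frame raw totals and gains.
#' @export
correct_photobleaching <- function(stack, background = 0) {
  d <- dim(stack$data)
  out <- stack$data
  rep_rows <- list()
  for (ch in seq_len(d[2])) {
    totals <- numeric(d[1])
    for (t in seq_len(d[1])) {
      fr <- pmax(get_frame(stack, t, ch) - background, 0)
      totals[t] <- sum(fr)
    }
    if (any(totals <= 0)) {
      bad <- which(totals <= 0)[1]
      stop(sprintf("correction error: zero total fluorescence in channel '%s', frame %d",
                   stack$channel_names[ch], bad))
    }
    gains <- totals[1] / totals
    for (t in seq_len(d[1]))
      out[t, ch, , , ] <- stack$data[t, ch, , , ] * gains[t]
    rep_rows[[ch]] <- data.frame(channel = stack$channel_names[ch],
                                 frame = seq_len(d[1]),
                                 raw_total = totals, gain = gains)
  }
  list(stack = movie_stack(out, stack$channel_names, stack$voxel_size_zyx,
                           stack$frame_interval),
       report = do.call(rbind, rep_rows))
}

#' Denoise and remove non-uniform background
#'
#' Gaussian smoothing at `sigma_um` followed by grey-scale top-hat
#' background removal with window half-width `bg_radius_um`; output is
#' nonnegative.
#'
#' @param stack a [movie_stack()].
#' @param sigma_um smoothing sigma, um.
#' @param bg_radius_um background window half-width, um.
#' @return a `movie_stack`.
#' @export
denoise_background <- function(stack, sigma_um = 0.5, bg_radius_um = 10) {
  if (sigma_um <= 0 || bg_radius_um <= 0)
    stop("sigma_um and bg_radius_um must be > 0")
  d <- dim(stack$data)
  out <- stack$data
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) {
    fr <- gaussian_filter3(get_frame(stack, t, ch), sigma_um,
                           stack$voxel_size_zyx)
    out[t, ch, , , ] <- tophat3(fr, bg_radius_um, stack$voxel_size_zyx)
  }
  movie_stack(out, stack$channel_names, stack$voxel_size_zyx,
              stack$frame_interval)
}

#' Run the full pre-processing chain
#'
#' Isotropic resampling, photobleaching correction, then denoising with
#' background removal.
#'
#' @param stack a [movie_stack()].
#' @param config a [pipeline_config()].
#' @return list with `stack` and the bleach `report`.
#' @export
preprocess_movie <- function(stack, config = pipeline_config()) {
  iso <- resample_isotropic(stack, config$target_voxel_um)
  bc <- correct_photobleaching(iso)
  den <- denoise_background(bc$stack, config$gaussian_sigma_um,
                            config$bg_radius_um)
  list(stack = den, report = bc$report)
}
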