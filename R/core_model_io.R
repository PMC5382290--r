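#' Construct a calibrated 4D multi-channel movie stack
#'
#' The central raw-data container: a 5D array ordered T x C x Z x Y x X of
#' nonnegative intensities with physical calibration. All geometry in the
#' package uses 0-based voxel indices ordered (z, y, x); physical positions
#' in micrometres are index times voxel size.
#'
#' @param data 5D numeric array, dimensions T x C x Z x Y x X.
#' @param channel_names character vector, one per channel, drawn from
#'   `"nuclei"`, `"cell_membrane"`, `"nurse_membrane"`.
#' @param voxel_size_zyx numeric triple, voxel edge lengths in micrometres
#'   ordered (z, y, x).
#' @param frame_interval time between frames, minutes.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(data, channel_names, voxel_size_zyx, frame_interval) {
  if (length(dim(data)) != 5L)
    stop("`data` must be a 5D array (T x C x Z x Y x X)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  if (length(channel_names) != dim(data)[2L])
    stop("schema error: length(channel_names) != number of channels")
  if (anyDuplicated(channel_names)) stop("channel names must be unique")
  known <- c("nuclei", "cell_membrane", "nurse_membrane")
  if (!all(channel_names %in% known))
    stop("unknown channel name(s): ",
         paste(setdiff(channel_names, known), collapse = ", "))
  voxel_size_zyx <- as.numeric(rep_len(voxel_size_zyx, 3L))
  if (any(voxel_size_zyx <= 0)) stop("voxel sizes must be > 0")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  if (min(data, na.rm = TRUE) < 0) stop("intensities must be nonnegative")
  structure(list(data = data,
                 channel_names = as.character(channel_names),
                 voxel_size_zyx = voxel_size_zyx,
                 frame_interval = as.numeric(frame_interval)),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frame(s), %d channel(s) [%s], Z x Y x X = %d x %d x %d\n",
              d[1], d[2], paste(x$channel_names, collapse = ", "),
              d[3], d[4], d[5]))
  cat(sprintf("  voxel (z,y,x) = %.3g x %.3g x %.3g um, frame interval %.3g min\n",
              x$voxel_size_zyx[1], x$voxel_size_zyx[2], x$voxel_size_zyx[3],
              x$frame_interval))
  invisible(x)
}

#' Index of a named channel
#' @param stack a `movie_stack`.
#' @param name channel name.
#' @return integer channel index.
#' @export
channel_index <- function(stack, name) {
  i <- match(name, stack$channel_names)
  if (is.na(i)) stop("movie has no channel named '", name, "'")
  i
}

#' Extract one frame of one channel as a 3D (z, y, x) array
#' @param stack a `movie_stack`.
#' @param frame frame number (1-based).
#' @param channel channel name or index.
#' @return 3D numeric array.
#' @export
get_frame <- function(stack, frame, channel) {
  if (is.character(channel)) channel <- channel_index(stack, channel)
  d <- dim(stack$data)
  out <- stack$data[frame, channel, , , , drop = TRUE]
  dim(out) <- d[3:5]
  out
}

#' Write / read a movie stack as a multi-page TIFF plus JSON sidecar
#'
#' Slices are written in Z-fastest, then channel, then frame order as
#' 16-bit pages scaled by a factor recorded in the sidecar (`<path>.json`),
#' which also carries the calibration. The round trip is bit-exact for
#' integer-valued detector counts up to 65535 (the common case for confocal
#' acquisitions); a wider dynamic range is stored at a coarser power-of-two
#' quantization step noted in the sidecar.
#'
#' @param stack a `movie_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(stack, path) {
  d <- dim(stack$data)
  mx <- max(stack$data)
  scale <- 65535 * 2^max(0, ceiling(log2((mx + 1) / 65536)))
  pages <- vector("list", d[1] * d[2] * d[3])
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    m <- stack$data[t, ch, z, , , drop = TRUE]
    dim(m) <- d[4:5]
    pages[[k]] <- m / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(axes = "TCZYX", shape = as.integer(d),
               channel_names = stack$channel_names,
               voxel_size_zyx = stack$voxel_size_zyx,
               frame_interval = stack$frame_interval,
               intensity_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie
#' @param meta either `NULL` (read the `<path>.json` sidecar) or a list with
#'   entries `shape` (T, C, Z, Y, X), `channel_names`, `voxel_size_zyx`,
#'   `frame_interval` and optionally `intensity_scale`.
#' @export
read_movie <- function(path, meta = NULL) {
  if (is.null(meta)) {
    side <- paste0(path, ".json")
    if (!file.exists(side))
      stop("calibration error: no metadata supplied and no sidecar at ", side)
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  }
  req <- c("shape", "channel_names", "voxel_size_zyx", "frame_interval")
  if (!all(req %in% names(meta)))
    stop("calibration error: metadata must supply ",
         paste(setdiff(req, names(meta)), collapse = ", "))
  d <- as.integer(meta$shape)
  if (length(d) != 5L) stop("calibration error: shape must have 5 axes (TCZYX)")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != d[1] * d[2] * d[3])
    stop("schema error: TIFF has ", length(pages), " pages, metadata implies ",
         d[1] * d[2] * d[3])
  if (length(meta$channel_names) != d[2])
    stop("schema error: ", length(meta$channel_names),
         " channel names declared for ", d[2], " channels")
  scale <- meta$intensity_scale %||% 1
  data <- array(0, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) for (ch in seq_len(d[2])) for (z in seq_len(d[3])) {
    data[t, ch, z, , ] <- pages[[k]] * scale
    k <- k + 1L
  }
  movie_stack(data, meta$channel_names, meta$voxel_size_zyx,
              meta$frame_interval)
}

#' Construct a per-frame integer label volume
#'
#' @param labels 4D integer array T x Z x Y x X; 0 is background.
#' @param identity_map named character vector mapping label (as name) to
#'   `"polar"` or `"border"`.
#' @param kind `"nuclei"` or `"cells"`.
#' @param voxel_size_zyx voxel sizes in micrometres.
#' @param frame_interval frame interval in minutes.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, identity_map, kind = c("nuclei", "cells"),
                         voxel_size_zyx = c(1, 1, 1), frame_interval = 1) {
  kind <- match.arg(kind)
  if (length(dim(labels)) != 4L) stop("`labels` must be 4D (T x Z x Y x X)")
  present <- sort(unique(as.integer(labels[labels > 0])))
  known <- as.integer(names(identity_map))
  if (!all(present %in% known))
    stop("labels missing from identity_map: ",
         paste(setdiff(present, known), collapse = ", "))
  if (!all(identity_map %in% c("polar", "border")))
    stop("identities must be 'polar' or 'border'")
  structure(list(labels = labels, identity_map = identity_map, kind = kind,
                 voxel_size_zyx = as.numeric(rep_len(voxel_size_zyx, 3L)),
                 frame_interval = as.numeric(frame_interval)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("label_volume (%s): %d frame(s), Z x Y x X = %d x %d x %d, %d entit%s\n",
              x$kind, d[1], d[2], d[3], d[4], length(x$identity_map),
              if (length(x$identity_map) == 1) "y" else "ies"))
  invisible(x)
}

#' Extract one frame of a label volume as a 3D integer array
#' @param lv a `label_volume`.
#' @param frame frame number.
#' @return 3D integer array.
#' @export
get_label_frame <- function(lv, frame) {
  d <- dim(lv$labels)
  out <- lv$labels[frame, , , , drop = TRUE]
  dim(out) <- d[2:4]
  storage.mode(out) <- "integer"
  out
}

#' Write / read a label volume as 16-bit TIFF plus JSON sidecar
#' @param lv a `label_volume`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(lv, path) {
  d <- dim(lv$labels)
  if (max(lv$labels) > 65535L) stop("labels exceed 16-bit range")
  pages <- vector("list", d[1] * d[2])
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    m <- lv$labels[t, z, , , drop = TRUE]
    dim(m) <- d[3:4]
    pages[[k]] <- m / 65535
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(axes = "TZYX", shape = as.integer(d), kind = lv$kind,
               identity_labels = as.integer(names(lv$identity_map)),
               identity_values = unname(lv$identity_map),
               voxel_size_zyx = lv$voxel_size_zyx,
               frame_interval = lv$frame_interval)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  pages <- tiff::readTIFF(path, all = TRUE)
  labels <- array(0L, dim = d)
  k <- 1L
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) {
    labels[t, z, , ] <- as.integer(round(pages[[k]] * 65535))
    k <- k + 1L
  }
  im <- setNames(meta$identity_values, meta$identity_labels)
  label_volume(labels, im, meta$kind, meta$voxel_size_zyx,
               meta$frame_interval)
}

#' Read a first-frame annotation of nucleus centers
#'
#' The only manual input of the pipeline: a CSV (or JSON array of records)
#' with columns `z`, `y`, `x` (0-based voxel coordinates in frame 1) and
#' `identity` (`"polar"` or `"border"`). Exactly two polar rows are required.
#' Labels are assigned deterministically: polar cells get 1-2, border cells
#' 3..c, each group in file order.
#'
#' @param path CSV or JSON file path.
#' @param frame0_shape integer triple (Z, Y, X) of the first frame, used for
#'   bounds checking.
#' @return object of class `annotation`: a data.frame with columns `label`,
#'   `identity`, `z`, `y`, `x`.
#' @examples
#' ann <- read_annotation(
#'   system.file("extdata", "example_annotation.csv", package = "ccmigrate"),
#'   frame0_shape = c(92, 92, 92))
#' ann
#' @export
read_annotation <- function(path, frame0_shape) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("z", "y", "x", "identity")
  if (!all(req %in% names(df)))
    stop("validation error: annotation needs columns ",
         paste(req, collapse = ", "))
  df$identity <- tolower(trimws(df$identity))
  if (!all(df$identity %in% c("polar", "border")))
    stop("validation error: identity must be 'polar' or 'border'")
  n_polar <- sum(df$identity == "polar")
  if (n_polar != 2L)
    stop("validation error: expected exactly 2 polar rows, found ", n_polar)
  if (sum(df$identity == "border") < 1L)
    stop("validation error: at least 1 border row required")
  frame0_shape <- as.integer(frame0_shape)
  coords <- as.matrix(df[, c("z", "y", "x")])
  if (any(!is.finite(coords)) ||
      any(coords < 0) ||
      any(t(t(coords) >= frame0_shape)))
    stop("validation error: annotation center out of frame bounds")
  df <- rbind(df[df$identity == "polar", , drop = FALSE],
              df[df$identity == "border", , drop = FALSE])
  out <- data.frame(label = seq_len(nrow(df)), identity = df$identity,
                    z = df$z, y = df$y, x = df$x)
  class(out) <- c("annotation", "data.frame")
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with field defaults matching the
#' reference acquisition (0.33 um isotropic working grid) and analysis
#' settings.
#'
#' @param target_voxel_um isotropic working voxel size after resampling, um.
#' @param gaussian_sigma_um denoising Gaussian sigma, um.
#' @param bg_radius_um top-hat background window half-width, um.
#' @param gmm GMM settings, see [gmm_config()].
#' @param tracking_epsilon distance regulator of the tracking confidence, um.
#' @param membrane_sigma_um plate-kernel scale for membrane enhancement, um.
#' @param membrane_angular_step in-plane rotation step of the filter bank,
#'   degrees.
#' @param exchange_tau_voxels neighbour-exchange threshold in working voxels
#'   (default 30, i.e. about twice the average nucleus diameter).
#' @param v_border_ref,v_polar_ref reference border/polar cell volumes, um^3,
#'   used for the cluster volume constraint.
#' @param cluster_smooth_um smoothing applied to the membrane channel before
#'   greedy cluster thresholding, um.
#' @param seed master random seed; stages derive sub-seeds deterministically.
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(target_voxel_um = 0.33,
                            gaussian_sigma_um = 0.5,
                            bg_radius_um = 10,
                            gmm = gmm_config(),
                            tracking_epsilon = 0.33,
                            membrane_sigma_um = 0.66,
                            membrane_angular_step = 30,
                            exchange_tau_voxels = 30,
                            v_border_ref = 1250,
                            v_polar_ref = 600,
                            cluster_smooth_um = 1,
                            seed = 1L) {
  cfg <- list(target_voxel_um = target_voxel_um,
              gaussian_sigma_um = gaussian_sigma_um,
              bg_radius_um = bg_radius_um,
              gmm = gmm,
              tracking_epsilon = tracking_epsilon,
              membrane_sigma_um = membrane_sigma_um,
              membrane_angular_step = membrane_angular_step,
              exchange_tau_voxels = exchange_tau_voxels,
              v_border_ref = v_border_ref,
              v_polar_ref = v_polar_ref,
              cluster_smooth_um = cluster_smooth_um,
              seed = as.integer(seed))
  dimensional <- c("target_voxel_um", "gaussian_sigma_um", "bg_radius_um",
                   "tracking_epsilon", "membrane_sigma_um",
                   "membrane_angular_step", "exchange_tau_voxels",
                   "v_border_ref", "v_polar_ref", "cluster_smooth_um")
  for (f in dimensional)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("configuration error: `", f, "` must be > 0")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write stage outputs as CSV tables with a JSON run manifest
#'
#' Every data.frame in `results` is written as `<name>.csv`; the manifest
#' records the file digests, the configuration hash and the seed so a rerun
#' with identical inputs is verifiable byte for byte.
#'
#' @param results named list of data.frames (and/or objects with an
#'   `as.data.frame` method).
#' @param outdir output directory, created if missing.
#' @param config optional `pipeline_config` stored alongside.
#' @return invisible list: paths written plus the manifest.
#' @export
write_tables <- function(results, outdir, config = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("I/O error: cannot create ", outdir)
  paths <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    p <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(df, p, row.names = FALSE)
    paths[nm] <- p
  }
  cfg_hash <- NA_character_
  seed <- NA_integer_
  if (!is.null(config)) {
    cfg_path <- file.path(outdir, "config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    seed <- config$seed
    paths["config"] <- cfg_path
  }
  manifest <- list(files = lapply(paths, function(p) unname(tools::md5sum(p))),
                   config_hash = cfg_hash, seed = seed,
                   tool = paste0("ccmigrate ",
                                 as.character(utils::packageVersion("ccmigrate"))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, manifest = manifest, manifest_path = mpath))
}
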