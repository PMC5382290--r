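#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, preprocess, nuclei segmentation, tracking,
#' cell segmentation, coordination, protrusion and deformation analysis
#' with one configuration, writing every stage output (CSV tables, TIFF
#' label volumes) plus a JSON run manifest into `outdir`. Stages communicate
#' only through files and in-memory handoffs mirroring them, so any stage is
#' re-runnable in isolation.
#'
#' @param config a [pipeline_config()].
#' @param input `"simulate"` or a movie TIFF path (with JSON sidecar).
#' @param outdir output directory.
#' @param scene a [scene_config()] when simulating; its seed is replaced by
#'   the pipeline seed.
#' @param annotation annotation file path (ignored when simulating: the
#'   simulation ground truth provides frame-1 centers).
#' @return invisible list with the run manifest and the main in-memory
#'   results (`tracks`, `coordination`, `exchanges`, `protrusions`,
#'   `mobility`, `rotation`).
#' @export
run_pipeline <- function(config = pipeline_config(), input = "simulate",
                         outdir = tempfile("ccmigrate_run_"),
                         scene = NULL, annotation = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    with_stage_timer(name, tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)))
  }
  truth <- NULL
  raw <- stage("acquire", {
    if (identical(input, "simulate")) {
      scene <- scene %||% scene_config()
      scene$seed <- derive_seed(config$seed, "simulate")
      sim <- generate_movie(scene)
      truth <- sim$truth
      sim$movie
    } else {
      read_movie(input)
    }
  })
  if (!"nuclei" %in% raw$channel_names)
    stop("schema error: movie has no 'nuclei' channel")

  pp <- stage("preprocess", preprocess_movie(raw, config))
  iso <- pp$stack
  v <- config$target_voxel_um

  ann <- stage("annotate", {
    if (!is.null(truth)) {
      tr1 <- truth$tracks[truth$tracks$frame == 1, ]
      out <- data.frame(label = tr1$label, identity = tr1$identity,
                        z = round(tr1$z / v), y = round(tr1$y / v),
                        x = round(tr1$x / v))
      class(out) <- c("annotation", "data.frame")
      out
    } else {
      if (is.null(annotation))
        stop("an annotation file is required for real movies")
      read_annotation(annotation, dim(iso$data)[3:5])
    }
  })

  seg <- stage("segment-nuclei", segment_nuclei(iso, ann, config))
  ntracks <- stage("track", build_tracks(seg$labels,
                                         config$tracking_epsilon))
  cellseg <- stage("segment-cells", segment_cells(iso, seg$labels, config))
  ctracks <- stage("track-cells", build_tracks(cellseg$labels,
                                               config$tracking_epsilon))

  coord <- stage("coordinate", {
    clf <- default_mode_classifier(seed = config$seed)
    cs <- coordination_series(ntracks, clf)
    polar_labs <- as.integer(names(seg$labels$identity_map)[
      seg$labels$identity_map == "polar"])
    T_ <- max(ntracks$frame)
    pc <- array(NA_real_, c(T_, 2, 3))
    for (i in 1:2) {
      tr <- ntracks[ntracks$label == polar_labs[i], ]
      pc[tr$frame, i, ] <- as.matrix(tr[, c("z", "y", "x")])
    }
    list(series = cs, polar = polar_axis_series(pc))
  })

  exch <- stage("exchange", {
    T_ <- max(ntracks$frame)
    K <- length(unique(ntracks$label))
    centers <- array(NA_real_, c(T_, K, 3))
    labs <- sort(unique(ntracks$label))
    for (j in seq_along(labs)) {
      tr <- ntracks[ntracks$label == labs[j], ]
      centers[tr$frame, j, ] <- as.matrix(tr[, c("z", "y", "x")])
    }
    sp <- exchange_metric(centers, max_step = min(10L, T_ - 1L))
    tau <- config$exchange_tau_voxels * v
    list(space = sp,
         events = detect_exchanges(sp, tau, iso$frame_interval))
  })

  prot <- stage("protrusions",
                protrusion_series(cellseg$cluster, cellseg$labels,
                                  config$v_border_ref, v,
                                  iso$frame_interval))

  deform <- stage("deformation", {
    fields <- deformation_fields(cellseg$labels)
    mob <- mobility_params(ntracks, ctracks, fields)
    rot <- rotation_association(ntracks, fields)
    list(fields = fields, mobility = mob, rotation = rot)
  })

  stage("report", {
    write_labels(seg$labels, file.path(outdir, "nuclei_labels.tif"))
    write_labels(cellseg$labels, file.path(outdir, "cell_labels.tif"))
  })
  manifest <- write_tables(list(
    bleach_report = pp$report,
    nucleus_tracks = ntracks,
    cell_tracks = ctracks,
    coordination = coord$series,
    polar_axis = coord$polar,
    interfaces = cellseg$interfaces,
    exchanges = exch$events,
    exchange_scale_space = {
      g <- exch$space$g
      data.frame(frame = rep(seq_len(nrow(g)), ncol(g)),
                 step = rep(seq_len(ncol(g)), each = nrow(g)),
                 g = as.vector(g))
    },
    protrusions = prot$stats,
    mobility = deform$mobility,
    rotation = deform$rotation$per_frame), outdir, config)

  invisible(list(manifest = manifest, truth = truth,
                 tracks = ntracks, cell_tracks = ctracks,
                 coordination = coord$series, polar = coord$polar,
                 exchanges = exch$events, protrusions = prot,
                 mobility = deform$mobility, rotation = deform$rotation,
                 nuclei = seg, cells = cellseg))
}
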