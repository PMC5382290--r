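#' GMM segmentation settings
#'
#' @param alpha exponent applied to voxel brightness to obtain the per-voxel
#'   EM weight; `alpha = 1` makes the fitted means the intensity-weighted
#'   geometric centers of the nuclei.
#' @param lambda_reg positive ridge added to each covariance diagonal after
#'   every M-step (um^2), preventing the singular zero-variance maximum of
#'   the likelihood.
#' @param tol relative log-likelihood change below which EM stops.
#' @param max_iter maximum EM iterations.
#' @param kappa sharpening strength of the Laplacian boundary enhancement.
#' @param init_sigma_um isotropic standard deviation of the frame-1
#'   components seeded from the annotation, um.
#' @param seed_mass_fraction fraction of the mean annotated-center intensity
#'   used as the frame-1 seeding threshold from which the conserved nuclear
#'   mass is computed.
#' @return object of class `gmm_config`.
#' @export
gmm_config <- function(alpha = 1, lambda_reg = 1e-3, tol = 1e-6,
                       max_iter = 200L, kappa = 1, init_sigma_um = 2,
                       seed_mass_fraction = 0.5) {
  if (lambda_reg <= 0) stop("lambda_reg must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(alpha = alpha, lambda_reg = lambda_reg, tol = tol,
                 max_iter = as.integer(max_iter), kappa = kappa,
                 init_sigma_um = init_sigma_um,
                 seed_mass_fraction = seed_mass_fraction),
            class = "gmm_config")
}

#' Nucleus mixture model
#'
#' One Gaussian component per nucleus: means (um), covariances (um^2),
#' mixing weights, plus the stable label and polar/border identity carried
#' through the whole movie.
#'
#' @param means c x 3 matrix of component means (z, y, x), um.
#' @param covariances list of c symmetric positive-definite 3 x 3 matrices.
#' @param weights mixing proportions summing to 1.
#' @param labels integer labels.
#' @param identities `"polar"`/`"border"` per component.
#' @return object of class `nucleus_model`.
#' @export
nucleus_model <- function(means, covariances, weights, labels, identities) {
  c_ <- nrow(means)
  stopifnot(length(covariances) == c_, length(weights) == c_,
            length(labels) == c_, length(identities) == c_)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixing weights must sum to 1")
  structure(list(means = means, covariances = covariances,
                 weights = weights, labels = as.integer(labels),
                 identities = identities),
            class = "nucleus_model")
}

#' Initial nucleus model from a first-frame annotation
#' @param ann an [read_annotation()] result.
#' @param voxel_um working voxel size, um (annotation coordinates are in
#'   voxels of the working grid).
#' @param cfg a [gmm_config()].
#' @return a `nucleus_model` with isotropic covariances and uniform weights.
#' @export
init_model_from_annotation <- function(ann, voxel_um, cfg = gmm_config()) {
  mu <- as.matrix(ann[, c("z", "y", "x")]) * voxel_um
  c_ <- nrow(mu)
  nucleus_model(mu,
                rep(list(diag(3) * cfg$init_sigma_um^2), c_),
                rep(1 / c_, c_), ann$label, ann$identity)
}

#' Mass-conserving foreground mask of the nuclei channel
#'
#' Chooses the intensity threshold whose enclosed mass (sum of intensities
#' at or above it) is closest to `target_mass`; the target is computed once
#' at frame 1 and held fixed so that the segmented nuclear volume cannot
#' drift with bleaching residuals. Components smaller than `min_volume_um3`
#' are removed and holes filled.
#'
#' @param nuclei_frame 3D array.
#' @param target_mass total intensity mass to conserve.
#' @param voxel_um voxel size, um.
#' @param min_volume_um3 minimum component volume kept (default 1 um^3).
#' @return logical mask.
#' @export
foreground_mask <- function(nuclei_frame, target_mass, voxel_um,
                            min_volume_um3 = 1) {
  v <- as.vector(nuclei_frame)
  total <- sum(v)
  if (target_mass <= 0 || target_mass > total + 1e-9)
    stop("target_mass must lie in (0, total frame mass]")
  # candidate thresholds are the distinct intensities; enclosed mass per
  # candidate via descending cumulative group sums
  lev <- sort(unique(v), decreasing = TRUE)
  grp <- rowsum(v, match(v, lev))       # total mass per intensity level
  cs <- cumsum(grp[order(as.integer(rownames(grp))), 1])
  best <- which.min(abs(cs - target_mass))
  if (cs[best] < 0.5 * target_mass)
    stop("weak-signal error: no threshold reaches 50% of the target mass")
  thr <- lev[best]
  mask <- nuclei_frame >= thr
  dim(mask) <- dim(nuclei_frame)
  lab <- .cpp_label3(array(as.integer(mask), dim(mask)), 6L)
  if (max(lab) > 0) {
    counts <- tabulate(lab[lab > 0])
    min_vox <- max(1, floor(min_volume_um3 / prod(rep_len(voxel_um, 3))))
    small <- which(counts < min_vox)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  fill_holes3(mask)
}

#' Laplacian boundary enhancement for touching nuclei
#'
#' Unsharp sharpening: subtracts `kappa` times the 6-neighbour discrete
#' Laplacian, deepening the intensity valley between adjacent nuclei;
#' clipped at zero.
#'
#' @param nuclei_frame 3D array.
#' @param kappa sharpening strength.
#' @return array of same dimensions.
#' @export
enhance_boundaries <- function(nuclei_frame, kappa = 1) {
  lap <- .cpp_sepconv3(nuclei_frame, c(1, -2, 1), c(0, 1, 0), c(0, 1, 0)) +
    .cpp_sepconv3(nuclei_frame, c(0, 1, 0), c(1, -2, 1), c(0, 1, 0)) +
    .cpp_sepconv3(nuclei_frame, c(0, 1, 0), c(0, 1, 0), c(1, -2, 1))
  out <- pmax(nuclei_frame - kappa * lap, 0)
  dim(out) <- dim(nuclei_frame)
  out
}

# log density of N(mu, Sigma) at rows of X (n x 3)
ldmvn <- function(X, mu, Sigma) {
  L <- chol(Sigma)
  w <- backsolve(L, t(X) - mu, transpose = TRUE)
  -0.5 * colSums(w^2) - sum(log(diag(L))) - 1.5 * log(2 * pi)
}

#' Fit the nucleus Gaussian mixture by weighted EM
#'
#' EM over the spatial coordinates of masked voxels with per-voxel weights
#' proportional to brightness^alpha. After every M-step `lambda_reg` is
#' added to each covariance diagonal. Stops when the relative change of the
#' weighted log-likelihood falls below `tol` or after `max_iter` iterations.
#' The fitted means are the intensity-weighted geometric centers of the
#' nuclei.
#'
#' @param frame 3D intensity array.
#' @param mask logical foreground mask.
#' @param init a `nucleus_model` with c components (frame-1: from the
#'   annotation; later frames: the previous frame's fit).
#' @param cfg a [gmm_config()].
#' @param voxel_um working voxel size, um.
#' @return a fitted `nucleus_model` with attributes `loglik` (per-iteration
#'   trace) and `responsibilities_of` (closure for labelling).
#' @export
fit_gmm <- function(frame, mask, init, cfg = gmm_config(), voxel_um = 0.33) {
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  ai <- arrayInd(idx, dim(frame))
  X <- (ai - 1) * voxel_um
  w <- as.vector(frame)[idx]^cfg$alpha
  w <- pmax(w, 0)
  if (sum(w) == 0) stop("weak-signal error: zero total weight in mask")
  c_ <- nrow(init$means)
  mu <- init$means
  Sig <- init$covariances
  pi_ <- init$weights
  n <- nrow(X)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  R <- matrix(0, n, c_)
  for (it in seq_len(cfg$max_iter)) {
    # E-step
    lp <- matrix(0, n, c_)
    for (j in seq_len(c_))
      lp[, j] <- log(pi_[j]) + ldmvn(X, mu[j, ], Sig[[j]])
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    ll <- sum(w * lse)
    ll_trace <- c(ll_trace, ll)
    R <- exp(lp - lse)
    # M-step (brightness-weighted)
    wr <- R * w
    Nj <- colSums(wr)
    if (any(Nj < 1e-6 * sum(w)))
      stop("degenerate-component error: component ",
           init$labels[which.min(Nj)], " collapsed")
    pi_ <- Nj / sum(w)
    for (j in seq_len(c_)) {
      mu[j, ] <- colSums(X * wr[, j]) / Nj[j]
      Xc <- sweep(X, 2, mu[j, ])
      S <- crossprod(Xc * wr[, j], Xc) / Nj[j]
      Sig[[j]] <- (S + t(S)) / 2 + diag(3) * cfg$lambda_reg
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= cfg$tol * (abs(ll_old) + 1e-12)) break
    ll_old <- ll
  }
  out <- nucleus_model(mu, Sig, pi_, init$labels, init$identities)
  attr(out, "loglik") <- ll_trace
  out
}

#' Assign masked voxels to nuclei by maximum posterior
#'
#' Each foreground voxel receives the label of its maximum-posterior
#' component; exact ties go to the lower label.
#'
#' @param model a fitted `nucleus_model`.
#' @param mask logical foreground mask.
#' @param voxel_um working voxel size, um.
#' @return 3D integer label array (0 outside the mask).
#' @export
label_nuclei <- function(model, mask, voxel_um = 0.33) {
  idx <- which(mask)
  ai <- arrayInd(idx, dim(mask))
  X <- (ai - 1) * voxel_um
  c_ <- nrow(model$means)
  lp <- matrix(0, length(idx), c_)
  for (j in seq_len(c_))
    lp[, j] <- log(model$weights[j]) + ldmvn(X, model$means[j, ],
                                             model$covariances[[j]])
  best <- max.col(lp, ties.method = "first")   # lower label wins ties
  out <- array(0L, dim(mask))
  out[idx] <- model$labels[best]
  counts <- tabulate(factor(out[idx], levels = model$labels), nbins = c_)
  if (any(counts == 0))
    stop("degenerate-component error: component ",
         model$labels[which(counts == 0)[1]], " received no voxels")
  out
}

#' Segment all nuclei of a preprocessed movie
#'
#' Per frame: Laplacian boundary enhancement, mass-conserving foreground
#' thresholding (target mass fixed at frame 1 from the annotation-seeded
#' threshold), weighted-EM GMM fit initialized from the previous frame, and
#' maximum-posterior labelling.
#'
#' @param stack a preprocessed, isotropic [movie_stack()].
#' @param annotation an [read_annotation()] result (coordinates on the
#'   working grid of `stack`).
#' @param config a [pipeline_config()].
#' @return list with `labels` (a nuclei [label_volume()]), `models`
#'   (per-frame `nucleus_model`s) and `target_mass`.
#' @export
segment_nuclei <- function(stack, annotation, config = pipeline_config()) {
  d <- dim(stack$data)
  v <- stack$voxel_size_zyx[1]
  cfg <- config$gmm
  model <- init_model_from_annotation(annotation, v, cfg)
  labels <- array(0L, dim = c(d[1], d[3], d[4], d[5]))
  models <- vector("list", d[1])
  target_mass <- NULL
  for (t in seq_len(d[1])) {
    fr <- enhance_boundaries(get_frame(stack, t, "nuclei"), cfg$kappa)
    if (t == 1L) {
      # annotation-seeded threshold defines the conserved nuclear mass
      ci <- as.matrix(annotation[, c("z", "y", "x")]) + 1
      seed_int <- mean(fr[ci])
      thr0 <- cfg$seed_mass_fraction * seed_int
      target_mass <- sum(fr[fr >= thr0])
    }
    mask <- foreground_mask(fr, target_mass, v)
    model <- fit_gmm(fr, mask, model, cfg, v)
    models[[t]] <- model
    labels[t, , , ] <- label_nuclei(model, mask, v)
    ccm_log("nuclei frame %d/%d: ll iterations %d", t, d[1],
            length(attr(model, "loglik")))
  }
  im <- setNames(model$identities, model$labels)
  list(labels = label_volume(labels, im, "nuclei", stack$voxel_size_zyx,
                             stack$frame_interval),
       models = models, target_mass = target_mass)
}
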