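# two Gaussian blobs on a grid, in um
blob_frame <- function(dims, centers, sigma, amps, voxel = 0.5) {
  f <- array(0, dims)
  ai <- (arrayInd(seq_len(prod(dims)), dims) - 1) * voxel
  for (j in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(ai, 2, centers[j, ])^2)
    f <- f + amps[j] * exp(-d2 / (2 * sigma^2))
  }
  array(f, dims)
}

test_that("foreground threshold minimizes the mass deficit (brute force)", {
  set.seed(31)
  fr <- array(sample(0:40, 14^3, replace = TRUE), c(14, 14, 14))
  target <- 0.4 * sum(fr)
  # independent oracle: enumerate every distinct intensity as threshold
  cand <- sort(unique(as.vector(fr)))
  masses <- vapply(cand, function(th) sum(fr[fr >= th]), numeric(1))
  best_mass <- masses[which.min(abs(masses - target))]
  mask <- foreground_mask(fr, target, voxel_um = 1, min_volume_um3 = 0)
  expect_equal(sum(fr[mask]), best_mass)
})

test_that("mass-conserving mask recovers bright balls on dark background", {
  dims <- c(20, 20, 20)
  fr <- array(0, dims)
  ball <- ball_mask(20, c(10, 10, 10), 5)
  fr[ball] <- 30
  mask <- foreground_mask(fr, sum(fr), voxel_um = 0.5)
  expect_identical(as.vector(mask), as.vector(ball))
  # two balls, target = total mass: both covered
  fr2 <- array(0, c(20, 20, 40))
  b1 <- ball_mask(20, c(10, 10, 10), 4)
  fr2[, , 1:20][b1] <- 30
  fr2[, , 21:40][b1] <- 30
  mask2 <- foreground_mask(fr2, sum(fr2), voxel_um = 0.5)
  expect_equal(sum(mask2), 2 * sum(b1))
  expect_error(foreground_mask(fr, 2 * sum(fr), 0.5), "target_mass")
})

test_that("Laplacian enhancement deepens inter-nucleus valleys only", {
  cst <- array(4, c(10, 10, 10))
  expect_equal(enhance_boundaries(cst, 1), cst)
  # two merged blobs: the valley between the peaks deepens
  dims <- c(21, 21, 41)
  fr <- blob_frame(dims, rbind(c(5, 5, 6), c(5, 5, 14)), sigma = 2,
                   amps = c(30, 30), voxel = 0.5)
  enh <- enhance_boundaries(fr, 1)
  midline <- fr[11, 11, ]
  midline_e <- enh[11, 11, ]
  valley <- 14:28   # between the two peak planes (x = 6 and 14 um)
  expect_lt(min(midline_e[valley]) / max(midline_e),
            min(midline[valley]) / max(midline))
  # a single symmetric blob keeps its peak position
  fr1 <- blob_frame(dims, rbind(c(5, 5, 10)), 2, 30, 0.5)
  enh1 <- enhance_boundaries(fr1, 1)
  expect_equal(which.max(enh1), which.max(fr1))
})

test_that("single-component EM recovers the intensity-weighted centroid", {
  dims <- c(19, 19, 19)
  fr <- blob_frame(dims, rbind(c(4.2, 4.8, 4.5)), 1.5, 25, 0.5)
  mask <- fr > 1
  init <- nucleus_model(matrix(c(4.5, 4.5, 4.5), 1), list(diag(3) * 4), 1,
                        1L, "border")
  fit <- fit_gmm(fr, mask, init, gmm_config(), voxel_um = 0.5)
  idx <- which(mask)
  X <- (arrayInd(idx, dims) - 1) * 0.5
  w <- fr[idx]
  centroid <- colSums(X * w) / sum(w)
  expect_equal(as.numeric(fit$means[1, ]), as.numeric(centroid),
               tolerance = 1e-6)
})

test_that("EM separates two blobs and is invariant to init permutation", {
  dims <- c(25, 25, 49)
  truth <- rbind(c(6, 6, 5), c(6, 6, 17))
  fr <- blob_frame(dims, truth, 2, c(30, 30), 0.5)
  mask <- fr > 0.5
  init <- nucleus_model(rbind(c(6, 6, 7), c(6, 6, 15)),
                        rep(list(diag(3) * 4), 2), c(0.5, 0.5), 1:2,
                        c("border", "border"))
  fit <- fit_gmm(fr, mask, init, gmm_config(), 0.5)
  err <- sqrt(rowSums((fit$means - truth)^2))
  expect_lt(max(err), 0.5)
  # log-likelihood trace is nondecreasing
  ll <- attr(fit, "loglik")
  expect_true(all(diff(ll) >= -1e-6 * abs(ll[-length(ll)])))
  # swapped init: same means up to the label permutation fixed by init
  init2 <- nucleus_model(rbind(c(6, 6, 15), c(6, 6, 7)),
                         rep(list(diag(3) * 4), 2), c(0.5, 0.5), 1:2,
                         c("border", "border"))
  fit2 <- fit_gmm(fr, mask, init2, gmm_config(), 0.5)
  expect_equal(fit2$means[2:1, ], fit$means, tolerance = 1e-4)
})

test_that("weighted EM agrees with mclust on an unweighted point cloud", {
  skip_if_not_installed("mclust")
  suppressMessages(require(mclust, quietly = TRUE))
  set.seed(33)
  # points drawn from two Gaussians, histogrammed onto a voxel grid: the
  # voxel counts are the brightness weights, so alpha = 1 EM on the grid
  # must match an unweighted mixture fit on the raw points
  n <- 4000
  pts <- rbind(matrix(rnorm(n * 3, 0, 1), ncol = 3) +
                 matrix(c(5, 5, 4), n, 3, byrow = TRUE),
               matrix(rnorm(n * 3, 0, 1), ncol = 3) +
                 matrix(c(5, 5, 12), n, 3, byrow = TRUE))
  dims <- c(21, 21, 33)
  vox <- pmin(pmax(round(pts / 0.5), 0), matrix(dims - 1, 2 * n, 3,
                                                byrow = TRUE))
  lin <- vox[, 1] + 1 + dims[1] * (vox[, 2] + dims[2] * vox[, 3])
  fr <- array(0, dims)
  tb <- table(lin)
  fr[as.integer(names(tb))] <- as.integer(tb)
  mask <- fr > 0
  init <- nucleus_model(rbind(c(5, 5, 5), c(5, 5, 11)),
                        rep(list(diag(3) * 2), 2), c(0.5, 0.5), 1:2,
                        c("border", "border"))
  fit <- fit_gmm(fr, mask, init, gmm_config(lambda_reg = 1e-4), 0.5)
  mc <- mclust::Mclust(pts, G = 2, modelNames = "VVV", verbose = FALSE)
  mc_means <- t(mc$parameters$mean)
  o <- order(mc_means[, 3])
  expect_equal(fit$means, mc_means[o, ], tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("posterior labelling partitions the mask with bisector boundary", {
  dims <- c(15, 15, 31)
  fr <- blob_frame(dims, rbind(c(3.5, 3.5, 3), c(3.5, 3.5, 12)), 2,
                   c(20, 20), 0.5)
  mask <- fr > 0.3
  model <- nucleus_model(rbind(c(3.5, 3.5, 3), c(3.5, 3.5, 12)),
                         rep(list(diag(3) * 2), 2), c(0.5, 0.5), 1:2,
                         c("border", "border"))
  lab <- label_nuclei(model, mask, 0.5)
  # partition property
  expect_equal(sum(lab > 0), sum(mask))
  expect_setequal(unique(lab[lab > 0]), 1:2)
  # equal symmetric components: boundary is the perpendicular bisector
  # plane x = 7.5 um (voxel index 16)
  idx <- which(mask)
  xs <- (arrayInd(idx, dims)[, 3] - 1) * 0.5
  expect_true(all(lab[idx][xs < 7.5 - 1e-9] == 1))
  expect_true(all(lab[idx][xs > 7.5 + 1e-9] == 2))
  # single component labels everything
  m1 <- nucleus_model(matrix(c(3.5, 3.5, 7.5), 1), list(diag(3) * 2), 1,
                      4L, "polar")
  expect_true(all(label_nuclei(m1, mask, 0.5)[mask] == 4L))
})

test_that("nucleus centroids are recovered within one voxel on a movie", {
  sim <- generate_movie(tiny_scene("running", n_frames = 4, seed = 9))
  cfg <- pipeline_config(target_voxel_um = 0.5, seed = 9)
  pp <- preprocess_movie(sim$movie, cfg)
  ann <- tiny_annotation(sim$truth, 0.5)
  seg <- segment_nuclei(pp$stack, ann, cfg)
  errs <- c()
  for (t in 1:4) {
    tr <- sim$truth$tracks[sim$truth$tracks$frame == t, ]
    mu <- seg$models[[t]]$means
    errs <- c(errs, sqrt(rowSums((mu - as.matrix(tr[, c("z", "y", "x")]))^2)))
  }
  expect_lt(median(errs), 0.5)   # one working voxel
})
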