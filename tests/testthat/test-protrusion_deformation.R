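# brute-force binary morphology oracle: direct structuring-element sweeps
brute_erode <- function(mask, r) {
  dims <- dim(mask)
  off <- arrayInd(which(ball_mask(2 * r + 1, rep(r + 1, 3), r)),
                  rep(2 * r + 1, 3)) - (r + 1)
  out <- array(FALSE, dims)
  for (i in which(mask)) {
    p <- arrayInd(i, dims)
    q <- sweep(off, 2, as.integer(p), "+")
    inside <- q[, 1] >= 1 & q[, 1] <= dims[1] & q[, 2] >= 1 &
      q[, 2] <= dims[2] & q[, 3] >= 1 & q[, 3] <= dims[3]
    if (all(inside) &&
        all(mask[q[inside, , drop = FALSE]])) out[i] <- TRUE
  }
  out
}

brute_dilate <- function(mask, r) {
  dims <- dim(mask)
  off <- arrayInd(which(ball_mask(2 * r + 1, rep(r + 1, 3), r)),
                  rep(2 * r + 1, 3)) - (r + 1)
  out <- array(FALSE, dims)
  for (i in which(mask)) {
    p <- arrayInd(i, dims)
    q <- sweep(off, 2, as.integer(p), "+")
    keep <- q[, 1] >= 1 & q[, 1] <= dims[1] & q[, 2] >= 1 &
      q[, 2] <= dims[2] & q[, 3] >= 1 & q[, 3] <= dims[3]
    out[q[keep, , drop = FALSE]] <- TRUE
  }
  out
}

test_that("opening equals the erosion-then-dilation oracle", {
  set.seed(71)
  m <- ball_mask(16, c(8, 8, 8), 5) | ball_mask(16, c(5, 10, 11), 3)
  r <- 2
  oracle <- brute_dilate(brute_erode(m, r), r)
  ours <- ball_open(m, r_um = r, voxel_um = 1)
  expect_identical(as.vector(ours), as.vector(oracle))
  # and erosion/dilation individually
  expect_identical(as.vector(ball_erode(m, r, 1)),
                   as.vector(brute_erode(m, r)))
  expect_identical(as.vector(ball_dilate(m, r, 1)),
                   as.vector(brute_dilate(m, r)))
})

test_that("opening residue isolates thin fingers, never a smooth ball", {
  B <- ball_mask(40, rep(20, 3), 12)
  det <- detect_protrusion(B, r_um = 5, voxel_um = 1)
  expect_equal(sum(det$protrusion), 0)
  expect_true(all(det$body == B))
  # ball + finger of width < 2r: residue is essentially the finger
  finger <- array(FALSE, rep(40, 3))
  finger[18:22, 18:22, 20:38] <- TRUE
  B2 <- B | finger
  det2 <- detect_protrusion(B2, r_um = 5, voxel_um = 1)
  added <- finger & !B
  jacc <- sum(det2$protrusion & added) / sum(det2$protrusion | added)
  expect_gte(jacc, 0.8)
  # anti-extensivity
  expect_true(all(which(det2$protrusion) %in% which(B2)))
  expect_true(all(which(det2$body) %in% which(B2)))
  # the detector's opening equals the erosion-then-dilation composition
  # built from first principles (half-voxel erosion tolerance included)
  comp <- B2 & ball_dilate(ball_erode(B2, 5 - 0.5, 1), 5, 1)
  expect_identical(as.vector(det2$body), as.vector(comp))
  expect_error(detect_protrusion(B, 0.1, 1), "configuration error")
})

test_that("protrusion statistics report direction, owner and rates", {
  B <- ball_mask(40, rep(20, 3), 10)
  finger <- array(FALSE, rep(40, 3))
  finger[19:21, 19:21, 20:37] <- TRUE
  det <- detect_protrusion(B | finger, r_um = 5, voxel_um = 1)
  cells <- array(0L, rep(40, 3))
  cells[B | finger] <- 3L
  st <- protrusion_stats(det$protrusion, det$body, cells, voxel_um = 1,
                         dt_min = 2)
  expect_equal(st$rate_um3_min, st$volume_um3 / 2)
  expect_equal(c(st$dir_z, st$dir_y, st$dir_x), c(0, 0, 1),
               tolerance = 0.1)
  expect_identical(st$owner, 3L)
  # two equal antipodal fingers cancel: direction undefined
  f2 <- array(FALSE, rep(40, 3))
  f2[19:21, 19:21, 3:20] <- TRUE
  det2 <- detect_protrusion(B | finger | f2, 5, 1)
  st2 <- protrusion_stats(det2$protrusion, det2$body, NULL, 1, 1)
  expect_true(is.na(st2$dir_x))
  # empty protrusion: zero-volume record, no error
  det3 <- detect_protrusion(B, 5, 1)
  st3 <- protrusion_stats(det3$protrusion, det3$body, NULL, 1, 1)
  expect_equal(st3$volume_um3, 0)
})

test_that("alignment and correlation follow their closed forms", {
  expect_equal(protrusion_alignment(rbind(c(0, 0, 1)),
                                    rbind(c(0, 0, 1)))$mean_pa, 1)
  expect_equal(protrusion_alignment(rbind(c(0, 0, 1)),
                                    rbind(c(0, 0, -1)))$mean_pa, -1)
  # 60 degrees apart: cosine 0.5
  expect_equal(protrusion_alignment(
    rbind(c(0, 0, 1)), rbind(c(0, sin(pi / 3), cos(pi / 3))))$mean_pa,
    0.5, tolerance = 1e-12)

  x <- c(1, 3, 2, 5)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  y <- c(2, 1, 4, 3)
  manual <- sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
  expect_equal(pearson(x, y), manual, tolerance = 1e-12)
  expect_warning(expect_true(is.na(pearson(1:2, 2:1))), "fewer")
  expect_warning(expect_true(is.na(pearson(rep(1, 5), 1:5))), "variance")
})

test_that("deformation mapping matches analytic sphere constructions", {
  dims <- rep(30, 3)
  b0 <- ball_mask(30, rep(15, 3), 8)
  expect_error(deformation_map(b0, array(FALSE, dims)), "degenerate-cell")
  # identical sets: all summaries zero
  dm0 <- deformation_map(b0, b0, 1)
  expect_equal(c(dm0$mpd, dm0$mnd, dm0$pde, dm0$nde), rep(0, 4))
  # ball grown by one voxel radius: positive-only, magnitudes about 1
  b1 <- ball_mask(30, rep(15, 3), 9)
  dm <- deformation_map(b0, b1, 1)
  expect_equal(dm$nde, 0)
  expect_gt(nrow(dm$positive), 0)
  expect_true(all(dm$positive$mag_um <= 2))
  expect_equal(median(dm$positive$mag_um), 1, tolerance = 0.5)
  # translation by 3 voxels: front and back both move by about 3
  sh <- array(FALSE, dims)
  sh[, , 4:30] <- b0[, , 1:27]
  dmt <- deformation_map(b0, sh, 0.33)
  expect_equal(dmt$mpd, 3 * 0.33, tolerance = 0.33)
  expect_equal(dmt$mnd, 3 * 0.33, tolerance = 0.33)
  # sign partition: no voxel is both a positive and a negative sample
  expect_length(intersect(dmt$positive$index, dmt$negative$index), 0)
})

test_that("deformation energies track volume change across random frames", {
  set.seed(72)
  vols <- nets <- c()
  for (i in 1:12) {
    r0 <- 6
    r1 <- runif(1, 4.5, 7.5)
    c1 <- rep(13, 3) + round(rnorm(3, 0, 1))
    a <- ball_mask(26, rep(13, 3), r0)
    b <- ball_mask(26, c1, r1)
    dm <- deformation_map(a, b, 1)
    vols <- c(vols, sum(b) - sum(a))
    nets <- c(nets, dm$pde - dm$nde)
  }
  expect_gt(cor(vols, nets, method = "spearman"), 0.8)
})

test_that("mobility parameters aggregate speeds and deformations", {
  # static movie: all six parameters about zero
  lab <- array(0L, c(3, 10, 10, 10))
  for (t in 1:3) lab[t, 3:7, 3:7, 3:7] <- 1L
  lv <- label_volume(lab, setNames("border", 1), "cells", rep(1, 3), 1)
  tr <- build_tracks(lv)
  fields <- deformation_fields(lv)
  mob <- mobility_params(tr, tr, fields)
  expect_equal(unlist(mob[, c("ns", "cs", "mpd", "mnd", "pde", "nde")]),
               setNames(rep(0, 12), NULL), ignore_attr = TRUE)
  # an injected extension strictly raises PDE over the static control
  lab2 <- lab
  lab2[3, 3:7, 3:7, 8:9] <- 1L
  lv2 <- label_volume(lab2, setNames("border", 1), "cells", rep(1, 3), 1)
  mob2 <- mobility_params(build_tracks(lv2), build_tracks(lv2),
                          deformation_fields(lv2))
  expect_gt(mob2$pde[2], mob$pde[2])
  expect_error(mobility_params(tr, tr, fields[1]), "alignment")
})

test_that("rotation association links tangential extensions to rotation", {
  # rigidly rotating label movie built from voxelized balls on a ring
  T_ <- 5
  K <- 4
  dims <- rep(34, 3)
  lab <- array(0L, c(T_, dims))
  centers <- array(0, c(T_, K, 3))
  for (t in 1:T_) {
    th0 <- (t - 1) * 12 * pi / 180
    f <- array(0L, dims)
    for (k in 1:K) {
      a <- th0 + 2 * pi * (k - 1) / K
      cc <- c(17 + 9 * sin(a), 17, 17 + 9 * cos(a))
      centers[t, k, ] <- cc
      f[ball_mask(34, cc, 4.2) & f == 0] <- k
    }
    lab[t, , , ] <- f
  }
  lv <- label_volume(lab, setNames(rep("border", K), 1:K), "cells",
                     rep(1, 3), 1)
  tr <- build_tracks(lv)
  fields <- deformation_fields(lv)
  ra <- rotation_association(tr, fields)
  expect_lt(ra$mean_angle_deg, 30)
  expect_true(all(ra$per_frame$angle_deg >= 0 &
                    ra$per_frame$angle_deg <= 180, na.rm = TRUE))
  # purely radial growth: Q vanishes, frames flagged
  lab3 <- array(0L, c(3, 26, 26, 26))
  for (t in 1:3) {
    f <- array(0L, rep(26, 3))
    f[ball_mask(26, c(13, 13, 8), 3 + t)] <- 1L
    f[ball_mask(26, c(13, 13, 18), 3 + t) & f == 0] <- 2L
    lab3[t, , , ] <- f
  }
  lv3 <- label_volume(lab3, setNames(rep("border", 2), 1:2), "cells",
                      rep(1, 3), 1)
  ra3 <- rotation_association(build_tracks(lv3), deformation_fields(lv3))
  expect_true(all(is.na(ra3$per_frame$angle_deg) |
                    ra3$per_frame$Q_mag < ra$per_frame$Q_mag[1] / 5))
})
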