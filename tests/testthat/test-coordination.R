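test_that("group polarization follows the vector-sum closed forms", {
  U <- matrix(rep(c(0, 0, 1), 5), ncol = 3, byrow = TRUE)
  expect_identical(as.numeric(group_polarization(U)), 1)
  anti <- rbind(c(0, 0, 1), c(0, 0, -1))
  expect_equal(as.numeric(group_polarization(anti)), 0)
  # hand vector sum: (+x, -x, +y, +y) -> |(0, 2, 0)| / 4 = 0.5
  U4 <- rbind(c(0, 0, 1), c(0, 0, -1), c(0, 1, 0), c(0, 1, 0))
  expect_equal(as.numeric(group_polarization(U4)), 0.5)
  # all-NA rows: undefined frame, flagged, no exception
  und <- group_polarization(matrix(NA_real_, 2, 3))
  expect_true(is.na(und) && isTRUE(attr(und, "undefined")))
})

test_that("angular momentum is exact for closed-form constructions", {
  K <- 8
  ang <- 2 * pi * (seq_len(K) - 1) / K
  C <- cbind(10 * sin(ang), 0, 10 * cos(ang))
  # exact tangential directions: M = 1
  U <- cbind(cos(ang), 0, -sin(ang))
  expect_equal(as.numeric(angular_momentum(U, C, c(0, 0, 0))), 1,
               tolerance = 1e-12)
  # radial directions: cross products vanish
  R <- C / 10
  expect_equal(as.numeric(angular_momentum(R, C, c(0, 0, 0))), 0,
               tolerance = 1e-12)
  # 4-cell planar hand computation against direct arithmetic
  C4 <- rbind(c(0, 0, 2), c(0, 2, 0), c(0, 0, -2), c(0, -2, 0))
  U4 <- rbind(c(0, 1, 0), c(0, 0, -1), c(0, -1, 0), c(1, 0, 0))
  manual <- (ccmigrate:::cross3(c(0, 0, 1), c(0, 1, 0)) +
               ccmigrate:::cross3(c(0, 1, 0), c(0, 0, -1)) +
               ccmigrate:::cross3(c(0, 0, -1), c(0, -1, 0)) +
               ccmigrate:::cross3(c(0, -1, 0), c(1, 0, 0)))
  expect_equal(as.numeric(angular_momentum(U4, C4, c(0, 0, 0))),
               sqrt(sum(manual^2)) / 4, tolerance = 1e-12)
  # a center coinciding with the cluster center is skipped with a warning
  expect_warning(angular_momentum(U4, rbind(C4[1:3, ], c(0, 0, 0)),
                                  c(0, 0, 0)), "skipped")
})

test_that("order parameters stay in [0, 1] for random direction sets", {
  set.seed(61)
  for (i in 1:200) {
    K <- sample(1:12, 1)
    U <- matrix(rnorm(K * 3), K)
    U <- U / sqrt(rowSums(U^2))
    C <- matrix(rnorm(K * 3, 0, 5), K)
    P <- group_polarization(U)
    M <- suppressWarnings(angular_momentum(U, C, c(0, 0, 0)))
    expect_true(P >= 0 && P <= 1 + 1e-12)
    expect_true(is.na(M) || (M >= 0 && M <= 1 + 1e-12))
  }
})

test_that("mode classifier boundary and default behaviour are sensible", {
  # classes mirrored across P = M: the boundary contains the diagonal
  set.seed(62)
  n <- 150
  run <- cbind(P = rnorm(n, 0.8, 0.07), M = rnorm(n, 0.3, 0.07))
  rot <- run[, 2:1]
  colnames(rot) <- c("P", "M")
  samples <- rbind(data.frame(run, mode = "running"),
                   data.frame(rot, mode = "rotating"))
  clf <- fit_mode_classifier(samples)
  for (v in c(0.2, 0.5, 0.8)) {
    r <- classify_mode(v, v, clf)
    expect_lt(abs(r$posterior - 0.5), 0.05)
  }
  # each training point of tight clusters classifies to its own class
  tight <- rbind(data.frame(P = c(0.9, 0.91, 0.89), M = c(0.1, 0.11, 0.1),
                            mode = "running"),
                 data.frame(P = c(0.1, 0.12, 0.1), M = c(0.9, 0.88, 0.9),
                            mode = "rotating"))
  expect_warning(clf2 <- fit_mode_classifier(tight), "singular")
  for (i in seq_len(nrow(tight)))
    expect_identical(classify_mode(tight$P[i], tight$M[i], clf2)$mode,
                     tight$mode[i])
  # the shipped synthetic-trained default
  clf0 <- default_mode_classifier()
  expect_identical(classify_mode(0.95, 0.05, clf0)$mode, "running")
  expect_identical(classify_mode(0.05, 0.95, clf0)$mode, "rotating")
})

test_that("classifier separates held-out synthetic schedules at >= 90%", {
  clf <- default_mode_classifier(seed = 63)
  sim_r <- generate_movie(tiny_scene("running", n_frames = 8, seed = 64,
                                     noise_sd = 1))
  sim_o <- generate_movie(tiny_scene("rotating", rate = 25, n_frames = 8,
                                     seed = 65, noise_sd = 1))
  acc <- c()
  for (sim in list(sim_r, sim_o)) {
    tr <- build_tracks(sim$truth$nuclei_labels)
    cs <- coordination_series(tr, clf)
    cs <- cs[!is.na(cs$mode) & cs$frame < max(cs$frame), ]
    acc <- c(acc, cs$mode == sim$truth$mode[cs$frame])
  }
  expect_gte(mean(acc), 0.9)
})

test_that("polar axis series measures undirected precession angles", {
  T_ <- 10
  pc <- array(0, c(T_, 2, 3))
  for (t in 1:T_) {
    pc[t, 1, ] <- c(0, 3, 0)
    pc[t, 2, ] <- c(0, -3, 0)
  }
  st <- polar_axis_series(pc)
  expect_equal(st$step_angle_deg[1:(T_ - 1)], rep(0, T_ - 1))
  # axis precessing 10 degrees per frame about a perpendicular
  for (t in 1:T_) {
    a <- (t - 1) * 10 * pi / 180
    ax <- c(sin(a), cos(a), 0)
    pc[t, 1, ] <- 3 * ax
    pc[t, 2, ] <- -3 * ax
  }
  st <- polar_axis_series(pc)
  expect_equal(st$step_angle_deg[1:(T_ - 1)], rep(10, T_ - 1),
               tolerance = 1e-9)
  expect_equal(st$step_angle_ma[5], 10, tolerance = 1e-9)
  # sign-flipped input gives identical angles (undirected axis)
  pc2 <- pc
  pc2[, , ] <- pc[, 2:1, ]
  st2 <- polar_axis_series(pc2)
  expect_equal(st2$step_angle_deg, st$step_angle_deg, tolerance = 1e-9)
})

test_that("exchange metric vanishes for rigid motion and static clusters", {
  pos <- ring_positions(12, 6)
  expect_equal(max(exchange_metric(pos, 5)$g, na.rm = TRUE), 0)
  # random rigid motions per frame: distance-matrix invariance
  set.seed(66)
  for (rep_ in 1:5) {
    p <- ring_positions(12, 6)
    for (t in 1:12) {
      tf <- random_rigid_transform()
      p[t, , ] <- t(tf$R %*% t(p[t, , ])) +
        matrix(tf$t, 6, 3, byrow = TRUE)
    }
    expect_lt(max(exchange_metric(p, 5)$g, na.rm = TRUE), 1e-9)
  }
})

test_that("injected exchanges are detected with onset and duration", {
  pos <- ring_positions(30, 6)
  p <- inject_exchange(pos, list(label_a = 2, label_b = 5,
                                 start_frame = 12, duration_frames = 6))
  sp <- exchange_metric(p, 8)
  expect_equal(sp$g[1, 1], 0)   # g(t, s -> 0) continuity at rigid frames
  ev <- detect_exchanges(sp, tau = 9.9, frame_interval = 1.5)
  expect_equal(nrow(ev), 1)
  expect_lte(abs(ev$frame - 12), 1)
  expect_lte(abs(ev$duration_min / 1.5 - 6), 1)
  expect_setequal(c(ev$label_a, ev$label_b), c(2, 5))
  # no supra-threshold structure: no events
  expect_equal(nrow(detect_exchanges(exchange_metric(pos, 8), 9.9)), 0)
})
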