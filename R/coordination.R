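#' Group polarization of a set of movement directions
#'
#' `P = |sum of unit directions| / K`: 1 when all K entities move the same
#' way, near 0 for incoherent motion. Rows with undefined direction (zero
#' displacement) must be excluded by the caller; `K` is the number of rows
#' actually supplied.
#'
#' @param directions K x 3 matrix of unit vectors (rows with NAs are
#'   dropped).
#' @return scalar in \[0, 1\], or NA (with attribute `undefined`) when no
#'   valid direction remains.
#' @export
group_polarization <- function(directions) {
  directions <- directions[stats::complete.cases(directions), , drop = FALSE]
  K <- nrow(directions)
  if (K == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  vnorm(colSums(directions)) / K
}

#' Angular momentum of a set of movement directions about the cluster center
#'
#' `M = |sum of cross(r_hat_k, d_hat_k)| / K` where `r_hat_k` is the unit
#' vector from the cluster center to entity k: 1 for coherent equatorial
#' rotation, near 0 for translation or incoherent motion. Entities whose
#' center coincides with the cluster center are skipped with a warning.
#'
#' @param directions K x 3 matrix of unit movement directions.
#' @param centers K x 3 matrix of entity centers (um).
#' @param c_m cluster center, length-3 (um).
#' @return scalar in \[0, 1\], or NA when no valid term remains.
#' @export
angular_momentum <- function(directions, centers, c_m) {
  ok <- stats::complete.cases(directions)
  acc <- c(0, 0, 0)
  K <- 0L
  skipped <- 0L
  for (k in which(ok)) {
    r <- centers[k, ] - c_m
    if (vnorm(r) == 0) { skipped <- skipped + 1L; next }
    acc <- acc + cross3(r / vnorm(r), directions[k, ])
    K <- K + 1L
  }
  if (skipped > 0)
    warning(skipped, " entit(ies) coincide with the cluster center; skipped")
  if (K == 0L) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  vnorm(acc) / K
}

#' Per-frame coordination series from a track table
#'
#' Computes P(t) and M(t) from the tracked entities' unit directions (zero
#' displacement entries excluded frame by frame), the cluster center (mean
#' of entity centers), and optionally mode labels from a classifier.
#'
#' @param tracks a `track_table` from [build_tracks()].
#' @param classifier optional [fit_mode_classifier()] result.
#' @return data.frame with columns `frame`, `P`, `M`, `K`, and when a
#'   classifier is given `mode` and `posterior`.
#' @export
coordination_series <- function(tracks, classifier = NULL) {
  frames <- sort(unique(tracks$frame))
  rows <- lapply(frames, function(t) {
    ft <- tracks[tracks$frame == t, ]
    U <- as.matrix(ft[, c("uz", "uy", "ux")])
    C <- as.matrix(ft[, c("z", "y", "x")])
    c_m <- colMeans(C)
    ok <- stats::complete.cases(U)
    P <- group_polarization(U)
    M <- if (any(ok))
      angular_momentum(U[ok, , drop = FALSE], C[ok, , drop = FALSE], c_m)
    else NA_real_
    data.frame(frame = t, P = as.numeric(P), M = as.numeric(M),
               K = sum(ok))
  })
  out <- do.call(rbind, rows)
  if (!is.null(classifier)) {
    cl <- t(vapply(seq_len(nrow(out)), function(i) {
      if (is.na(out$P[i]) || is.na(out$M[i])) return(c(NA, NA))
      r <- classify_mode(out$P[i], out$M[i], classifier)
      c(r$mode == "rotating", r$posterior)
    }, numeric(2)))
    out$mode <- ifelse(is.na(cl[, 1]), NA_character_,
                       ifelse(cl[, 1] == 1, "rotating", "running"))
    out$posterior <- cl[, 2]
  }
  out
}

#' Fit the running/rotating mode classifier
#'
#' Maximum-likelihood bivariate Gaussian per class over (P, M) with
#' class-frequency priors; the decision boundary is the equal-posterior
#' locus. A singular class covariance is ridged with 1e-4 and warned about.
#'
#' @param samples data.frame with columns `P`, `M`, `mode` (two classes,
#'   `"running"` and `"rotating"`, each with >= 2 samples).
#' @return object of class `mode_classifier`.
#' @export
fit_mode_classifier <- function(samples) {
  classes <- c("running", "rotating")
  if (!all(classes %in% samples$mode))
    stop("need samples of both modes")
  fit <- lapply(classes, function(cl) {
    Xc <- as.matrix(samples[samples$mode == cl, c("P", "M")])
    if (nrow(Xc) < 2) stop("need >= 2 samples per class")
    S <- stats::cov(Xc) * (nrow(Xc) - 1) / nrow(Xc)   # ML covariance
    if (det(S) < 1e-12) {
      warning("singular covariance for class ", cl, "; ridged")
      S <- S + diag(2) * 1e-4
    }
    list(mean = colMeans(Xc), cov = S, prior = nrow(Xc) / nrow(samples))
  })
  names(fit) <- classes
  structure(fit, class = "mode_classifier")
}

#' Classify one (P, M) observation
#'
#' Argmax posterior under the two fitted Gaussians; exactly on the boundary
#' the running mode is returned by convention with posterior 0.5. The
#' posterior makes near-boundary "continuum" frames visible.
#'
#' @param P,M scalars in \[0, 1\].
#' @param clf a `mode_classifier`.
#' @return list with `mode` and `posterior` (of the returned mode).
#' @export
classify_mode <- function(P, M, clf) {
  x <- c(P, M)
  lp <- vapply(clf, function(f) {
    S <- f$cov
    d <- x - f$mean
    -0.5 * sum(d * solve(S, d)) - 0.5 * log(det(S)) + log(f$prior)
  }, numeric(1))
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  if (abs(post[1] - post[2]) < 1e-12)
    return(list(mode = "running", posterior = 0.5))
  i <- which.max(post)
  list(mode = names(clf)[i], posterior = unname(post[i]))
}

#' Default mode classifier trained on simulated order parameters
#'
#' Draws (P, M) samples from simulated coherent-translation frames (running;
#' direction noise around a common heading) and coherent equatorial-rotation
#' frames (rotating; tangential directions with noise) of an 8-entity
#' cluster, and fits [fit_mode_classifier()]. Ships as the default because
#' the reference fitted boundary is not published; users should refit on
#' their own annotated data when available.
#'
#' @param n_per_class simulated frames per class.
#' @param seed integer seed.
#' @return a `mode_classifier`.
#' @export
default_mode_classifier <- function(n_per_class = 300, seed = 99L) {
  set.seed(derive_seed(seed, "default_classifier"))
  K <- 8
  sim_frame <- function(mode) {
    ang <- 2 * pi * (seq_len(K) - 1) / K
    C <- cbind(sin(ang), 0, cos(ang)) * 8
    if (mode == "running") {
      axis <- unitize(rnorm(3))
      U <- t(vapply(seq_len(K), function(k)
        unitize(axis + rnorm(3, 0, 0.45)), numeric(3)))
    } else {
      U <- t(vapply(seq_len(K), function(k) {
        tang <- unitize(cross3(c(0, 1, 0), C[k, ]))
        unitize(tang + rnorm(3, 0, 0.45))
      }, numeric(3)))
    }
    P <- group_polarization(U)
    M <- angular_momentum(U, C, c(0, 0, 0))
    data.frame(P = as.numeric(P), M = as.numeric(M), mode = mode)
  }
  samples <- do.call(rbind, c(
    lapply(seq_len(n_per_class), function(i) sim_frame("running")),
    lapply(seq_len(n_per_class), function(i) sim_frame("rotating"))))
  fit_mode_classifier(samples)
}

#' Polar axis orientation series
#'
#' The polar axis is the (undirected) line through the two polar-cell
#' centers. Per frame pair, the step angle is `acos(|a_t . a_{t+1}|)` in
#' degrees; a centered 5-point moving average (windows shrink at the ends)
#' summarizes the rotation rate.
#'
#' @param polar_centers T x 2 x 3 array of the two polar centers per frame
#'   (um).
#' @param window moving-average window (odd, default 5).
#' @return data.frame with `frame`, `axis_z`, `axis_y`, `axis_x`,
#'   `step_angle_deg` (NA at the last frame and where the axis is
#'   undefined), `step_angle_ma`.
#' @export
polar_axis_series <- function(polar_centers, window = 5L) {
  T_ <- dim(polar_centers)[1]
  axes <- matrix(NA_real_, T_, 3)
  for (t in seq_len(T_)) {
    d <- polar_centers[t, 1, ] - polar_centers[t, 2, ]
    if (vnorm(d) == 0) next      # coincident centers: axis undefined
    axes[t, ] <- unitize(d)
  }
  ang <- rep(NA_real_, T_)
  for (t in seq_len(T_ - 1)) {
    if (any(is.na(axes[t, ])) || any(is.na(axes[t + 1, ]))) next
    ang[t] <- acos(pmin(1, abs(sum(axes[t, ] * axes[t + 1, ])))) * 180 / pi
  }
  h <- (window - 1L) %/% 2L
  ma <- vapply(seq_len(T_), function(t) {
    w <- max(1, t - h):min(T_, t + h)
    if (all(is.na(ang[w]))) NA_real_ else mean(ang[w], na.rm = TRUE)
  }, numeric(1))
  data.frame(frame = seq_len(T_), axis_z = axes[, 1], axis_y = axes[, 2],
             axis_x = axes[, 3], step_angle_deg = ang, step_angle_ma = ma)
}

#' Temporal topology change metric for neighbour exchange
#'
#' With `D(t)` the pairwise center-distance matrix, the metric is
#' `g(t, s) = max_ij | D(t+s)_ij - D(t)_ij |` over temporal step sizes
#' `s = 1..max_step`. Rigid cluster motion (any rotation + translation)
#' leaves `g` at zero; a border cell sliding past its neighbours produces a
#' hot spot whose height approaches the swapped pair's separation.
#'
#' @param centers T x K x 3 array of per-frame centers (um).
#' @param max_step largest temporal step size (frames, < T).
#' @return object of class `exchange_scale_space`: list with `g`
#'   ((T-1) x max_step matrix, NA where t+s exceeds the movie), `pair_i`,
#'   `pair_j` (argmax pair per cell), `frame_interval` unset here (attach
#'   via attribute when known).
#' @export
exchange_metric <- function(centers, max_step) {
  T_ <- dim(centers)[1]
  K <- dim(centers)[2]
  if (K < 2) stop("need at least two entities")
  if (max_step >= T_) stop("max_step must be < number of frames")
  Dm <- lapply(seq_len(T_), function(t)
    as.matrix(stats::dist(centers[t, , , drop = TRUE])))
  g <- matrix(NA_real_, T_ - 1, max_step)
  pi_ <- matrix(NA_integer_, T_ - 1, max_step)
  pj_ <- matrix(NA_integer_, T_ - 1, max_step)
  for (t in seq_len(T_ - 1)) {
    for (s in seq_len(min(max_step, T_ - t))) {
      A <- abs(Dm[[t + s]] - Dm[[t]])
      g[t, s] <- max(A)
      w <- which(A == g[t, s], arr.ind = TRUE)[1, ]
      pi_[t, s] <- min(w); pj_[t, s] <- max(w)
    }
  }
  structure(list(g = g, pair_i = pi_, pair_j = pj_, max_step = max_step),
            class = "exchange_scale_space")
}

#' Detect neighbour-exchange events in the scale space
#'
#' Each connected supra-threshold region of the (t, s) scale space yields
#' one event (non-maximal cells within a region are suppressed). The peak
#' of `g` marks the comparison of the last undisturbed frame with the
#' exchange's closest approach at its temporal midpoint, so the event frame
#' is the latest t attaining the regional maximum and the full exchange
#' duration spans twice the peak step.
#'
#' @param space an [exchange_metric()] result.
#' @param tau threshold in um (default: 30 working voxels, about twice the
#'   average nucleus diameter).
#' @param frame_interval minutes per frame.
#' @return data.frame with `frame`, `step` (peak temporal step size),
#'   `duration_min` (`2 * step * frame_interval`), `g`, `label_a`,
#'   `label_b`.
#' @export
detect_exchanges <- function(space, tau = 30 * 0.33, frame_interval = 1) {
  if (tau <= 0) stop("tau must be > 0")
  g <- space$g
  nT <- nrow(g); nS <- ncol(g)
  hot <- !is.na(g) & g > tau
  # one event per connected supra-threshold region: suppression of all
  # non-maximal cells within the 3 x 3 neighbourhood graph of the hot set
  lab <- array(as.integer(hot), dim = c(nT, nS, 1L))
  lab <- .cpp_label3(lab, 26L)[, , 1, drop = TRUE]
  dim(lab) <- c(nT, nS)
  events <- list()
  for (r in seq_len(max(lab, 0))) {
    w <- which(lab == r, arr.ind = TRUE)
    vals <- g[w]
    near_max <- vals >= max(vals) * (1 - 1e-9)
    # the peak cells compare an undisturbed frame t with the closest
    # approach at t + s; the event corner is the near-max cell whose
    # comparison ends earliest (min t + s), at the latest onset frame
    top <- w[near_max, , drop = FALSE]
    top <- top[order(top[, 1] + top[, 2], -top[, 1])[1], , drop = TRUE]
    t <- top[1]; s <- top[2]
    events[[length(events) + 1]] <-
      data.frame(frame = t, step = s,
                 duration_min = 2 * s * frame_interval,
                 g = g[t, s], label_a = space$pair_i[t, s],
                 label_b = space$pair_j[t, s])
  }
  if (!length(events))
    return(data.frame(frame = integer(0), step = integer(0),
                      duration_min = numeric(0), g = numeric(0),
                      label_a = integer(0), label_b = integer(0)))
  ev <- do.call(rbind, events)
  ev <- ev[order(ev$frame, ev$step), , drop = FALSE]
  # one exchange produces two scale-space lobes (onset-to-midpoint and
  # midpoint-to-completion comparisons): merge same-pair events whose time
  # extents overlap, keeping the stronger (earlier on ties = the onset)
  keep <- rep(TRUE, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(ev))) {
      if (i == j || !keep[j]) next
      same_pair <- ev$label_a[i] == ev$label_a[j] &&
        ev$label_b[i] == ev$label_b[j]
      overlap <- ev$frame[j] <= ev$frame[i] + 2 * ev$step[i] &&
        ev$frame[i] <= ev$frame[j] + 2 * ev$step[j]
      if (same_pair && overlap) {
        # the earlier lobe carries the onset; keep it, remember the peak
        if (ev$frame[j] > ev$frame[i] ||
            (ev$frame[j] == ev$frame[i] && ev$step[j] >= ev$step[i])) {
          ev$g[i] <- max(ev$g[i], ev$g[j])
          keep[j] <- FALSE
        } else {
          ev$g[j] <- max(ev$g[i], ev$g[j])
          keep[i] <- FALSE
          break
        }
      }
    }
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
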