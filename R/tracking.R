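#' Tracking confidence between two segmented frames
#'
#' Score between segment i at frame t and segment j at frame t+1:
#' `S_ij = (|overlap_ij| + 1) / (||c_i - c_j|| + epsilon)` with the overlap
#' in voxels and the center distance in um. Larger overlap at equal distance
#' and smaller distance at equal overlap both increase the score; the +1
#' keeps fully disjoint pairs (fast movers) rankable by distance.
#'
#' @param seg_t,seg_t1 3D integer label arrays with the same set of c
#'   nonzero labels.
#' @param voxel_um working voxel size, um.
#' @param eps distance regulator, um (> 0).
#' @return list with `S` (c x c matrix, rows = labels at t), `labels_t`,
#'   `labels_t1`, `centers_t`, `centers_t1`.
#' @export
tracking_confidence <- function(seg_t, seg_t1, voxel_um = 0.33, eps = 0.33) {
  if (eps <= 0) stop("configuration error: eps must be > 0")
  lt <- sort(unique(seg_t[seg_t > 0]))
  lt1 <- sort(unique(seg_t1[seg_t1 > 0]))
  if (length(lt) != length(lt1))
    stop("count-mismatch error: ", length(lt), " vs ", length(lt1),
         " segments")
  ct <- label_centers(seg_t, lt, voxel_um)
  ct1 <- label_centers(seg_t1, lt1, voxel_um)
  both <- seg_t > 0 & seg_t1 > 0
  S <- matrix(0, length(lt), length(lt1),
              dimnames = list(lt, lt1))
  if (any(both)) {
    ov <- table(factor(seg_t[both], levels = lt),
                factor(seg_t1[both], levels = lt1))
    S <- S + unclass(ov)
  }
  D <- as.matrix(stats::dist(rbind(ct, ct1)))[seq_along(lt),
                                              length(lt) + seq_along(lt1),
                                              drop = FALSE]
  S <- (S + 1) / (D + eps)
  list(S = S, labels_t = lt, labels_t1 = lt1,
       centers_t = ct, centers_t1 = ct1)
}

# geometric centers (um) of each label, rows ordered as `labels`
label_centers <- function(seg, labels, voxel_um) {
  idx <- which(seg > 0)
  ai <- (arrayInd(idx, dim(seg)) - 1) * voxel_um
  f <- factor(seg[idx], levels = labels)
  m <- cbind(tapply(ai[, 1], f, mean), tapply(ai[, 2], f, mean),
             tapply(ai[, 3], f, mean))
  unname(m)
}

#' Globally optimal frame-to-frame assignment
#'
#' Finds the permutation maximizing the summed tracking confidence
#' (solved as a min-cost assignment by shortest augmenting paths, the
#' Hungarian method). Among tied optima the lexicographically smallest
#' permutation is returned.
#'
#' @param S square score matrix.
#' @return integer permutation `sigma`; segment i at t maps to
#'   `sigma[i]` at t+1.
#' @export
assign_tracks <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("shape error: confidence matrix must be square")
  n <- nrow(S)
  if (n == 1L) return(1L)
  cost <- max(S) - S
  sigma <- hungarian_min(cost)
  best <- sum(S[cbind(seq_len(n), sigma)])
  tol <- 1e-9 * max(1, abs(best))
  # lexicographic refinement over tied optima
  fixed <- integer(0)
  for (i in seq_len(n)) {
    cand <- sort(setdiff(seq_len(n), fixed))
    for (j in cand) {
      if (sigma[i] == j) break
      val <- constrained_best(S, c(fixed, j))
      if (val >= best - tol) {
        sigma <- c(fixed, j, constrained_rest(S, c(fixed, j)))
        break
      }
    }
    fixed <- sigma[seq_len(i)]
  }
  as.integer(sigma)
}

# optimal value with sigma[1..k] forced to `prefix`
constrained_best <- function(S, prefix) {
  n <- nrow(S)
  k <- length(prefix)
  head_val <- sum(S[cbind(seq_len(k), prefix)])
  if (k == n) return(head_val)
  rows <- (k + 1):n
  cols <- setdiff(seq_len(n), prefix)
  sub <- S[rows, cols, drop = FALSE]
  sig <- hungarian_min(max(sub) - sub)
  head_val + sum(sub[cbind(seq_along(rows), sig)])
}

constrained_rest <- function(S, prefix) {
  n <- nrow(S)
  k <- length(prefix)
  if (k == n) return(integer(0))
  rows <- (k + 1):n
  cols <- setdiff(seq_len(n), prefix)
  sub <- S[rows, cols, drop = FALSE]
  sig <- hungarian_min(max(sub) - sub)
  cols[sig]
}

# Shortest augmenting path solver (Hungarian method with potentials) for the
# min-cost assignment problem; O(n^3). Returns sigma with rows -> columns.
# Rows and columns carry a virtual index 0, stored at R position 1.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1)        # row potentials, u[i + 1]
  v <- numeric(n + 1)        # column potentials, v[j + 1]
  p <- integer(n + 1)        # p[j + 1] = row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1]) next
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  sigma <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) sigma[p[j + 1]] <- j
  sigma
}

#' Build per-entity tracks from a segmented label movie
#'
#' Chains per-step optimal assignments into stable track labels (those of
#' frame 1) and computes, per entity and frame, the center (um), the
#' displacement vector to the next frame, the speed (um/min) and the unit
#' direction. Directions are undefined (NA) at zero displacement and at the
#' last frame.
#'
#' @param label_movie a [label_volume()].
#' @param eps tracking confidence distance regulator, um.
#' @return a `track_table`: data.frame with columns `label`, `identity`,
#'   `frame`, `z`, `y`, `x`, `dz`, `dy`, `dx`, `speed`, `uz`, `uy`, `ux`;
#'   the frame interval is carried in attribute `frame_interval`.
#' @export
build_tracks <- function(label_movie, eps = 0.33) {
  lv <- label_movie
  d <- dim(lv$labels)
  T_ <- d[1]
  voxel <- lv$voxel_size_zyx[1]
  f1 <- get_label_frame(lv, 1)
  labs <- sort(unique(f1[f1 > 0]))
  c_ <- length(labs)
  centers <- array(NA_real_, c(T_, c_, 3))
  centers[1, , ] <- label_centers(f1, labs, voxel)
  # stable[j] = which label in frame t corresponds to track j
  stable <- labs
  prev <- f1
  for (t in seq_len(T_ - 1)) {
    cur <- get_label_frame(lv, t + 1)
    n_cur <- length(unique(cur[cur > 0]))
    if (n_cur != c_)
      stop("count-mismatch error: frame ", t + 1, " has ", n_cur,
           " segments, expected ", c_)
    tc <- tracking_confidence(prev, cur, voxel, eps)
    sigma <- assign_tracks(tc$S)
    # track j currently carried by label stable[j] = tc$labels_t[r];
    # it moves to tc$labels_t1[sigma[r]]
    r <- match(stable, tc$labels_t)
    stable <- tc$labels_t1[sigma[r]]
    centers[t + 1, , ] <- tc$centers_t1[sigma[r], , drop = FALSE]
    prev <- cur
  }
  dt <- lv$frame_interval
  rows <- lapply(seq_len(c_), function(j) {
    P <- centers[, j, , drop = TRUE]
    dim(P) <- c(T_, 3)
    D <- rbind(P[-1, , drop = FALSE] - P[-T_, , drop = FALSE],
               c(NA, NA, NA))
    sp <- sqrt(rowSums(D^2)) / dt
    U <- D / sqrt(rowSums(D^2))
    U[!is.finite(U)] <- NA
    data.frame(label = labs[j],
               identity = unname(lv$identity_map[as.character(labs[j])]),
               frame = seq_len(T_),
               z = P[, 1], y = P[, 2], x = P[, 3],
               dz = D[, 1], dy = D[, 2], dx = D[, 3],
               speed = sp, uz = U[, 1], uy = U[, 2], ux = U[, 3])
  })
  out <- do.call(rbind, rows)
  attr(out, "frame_interval") <- dt
  class(out) <- c("track_table", "data.frame")
  out
}
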