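# Shared fixtures and independent oracles used across the suite.

# a deterministic, already-normalized walking sequence (view 0, no noise)
walking_seq <- function(seed = 1, subject = "S001", view = 0,
                        duration = 4, fps = 30, noise = 0,
                        condition = "NM", cadence = NULL) {
  p <- draw_gait_params(seed, subject)
  if (!is.null(cadence)) p$cadence <- cadence
  simulate_sequence(p, covariate_spec(condition, view_deg = view),
                    duration = duration, fps = fps, noise_sigma = noise,
                    seed = seed)
}

# view-aligned (but not translation-normalized) version of a walk, so the
# hip trajectory stays available for direction estimation
aligned_walk <- function(...) {
  s <- walking_seq(...)
  apply_view_transform(s, build_view_transform(s))
}

# random rigid 4x4 homogeneous transform (rotation + translation)
random_rigid <- function() {
  A <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(A))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- rnorm(3)
  M
}

# random 17-keypoint frame in canvas coordinates
random_frame <- function(w = 80, h = 120) {
  cbind(runif(17, -5, w + 5), runif(17, -5, h + 5))
}

# Brute-force rasterization oracles: full-canvas per-pixel distance tests,
# no bounding-box shortcuts (intentionally independent of the
# implementation's windowed stamping).
oracle_lines <- function(points, thickness, w = 80, h = 120, conf = NULL) {
  if (is.null(conf)) conf <- rep(1, nrow(points))
  uc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  vc <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  mask <- matrix(0, h, w)
  kp <- gsi17_keypoints()
  ed <- gsi17_edges()
  for (e in seq_len(nrow(ed))) {
    i <- match(ed[e, 1], kp); j <- match(ed[e, 2], kp)
    if (conf[i] <= 0 || conf[j] <= 0) next
    p1 <- points[i, ]; p2 <- points[j, ]
    d <- p2 - p1
    l2 <- sum(d^2)
    if (l2 == 0) {
      d2 <- (uc - p1[1])^2 + (vc - p1[2])^2
    } else {
      tt <- pmin(1, pmax(0, ((uc - p1[1]) * d[1] + (vc - p1[2]) * d[2]) / l2))
      d2 <- (uc - p1[1] - tt * d[1])^2 + (vc - p1[2] - tt * d[2])^2
    }
    mask[d2 <= (thickness / 2)^2] <- 1
  }
  mask
}

oracle_joints <- function(points, radius, w = 80, h = 120, conf = NULL) {
  if (is.null(conf)) conf <- rep(1, nrow(points))
  uc <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  vc <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)
  mask <- matrix(0, h, w)
  for (i in seq_len(nrow(points))) {
    if (conf[i] <= 0) next
    d2 <- (uc - points[i, 1])^2 + (vc - points[i, 2])^2
    mask[d2 <= radius^2] <- 1
  }
  mask
}

# pairwise intra-frame distance matrix of one frame of a sequence
frame_dists <- function(seq, k) {
  as.matrix(dist(seq$frames[, , k]))
}
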