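# Independent rule tables for the table-driven oracles: written out
# directly from the documented mapping, not read from the package's YAML.
kinect_direct <- c(
  head = "Head", neck = "Neck", shoulder_center = "SpineShoulder",
  spine_center = "SpineMid", hip_center = "SpineBase",
  l_shoulder = "ShoulderLeft", r_shoulder = "ShoulderRight",
  l_elbow = "ElbowLeft", r_elbow = "ElbowRight",
  l_wrist = "WristLeft", r_wrist = "WristRight",
  l_hip = "HipLeft", r_hip = "HipRight",
  l_knee = "KneeLeft", r_knee = "KneeRight",
  l_ankle = "AnkleLeft", r_ankle = "AnkleRight")

mp_direct <- c(
  head = "nose", l_shoulder = "left_shoulder", r_shoulder = "right_shoulder",
  l_elbow = "left_elbow", r_elbow = "right_elbow",
  l_wrist = "left_wrist", r_wrist = "right_wrist",
  l_hip = "left_hip", r_hip = "right_hip",
  l_knee = "left_knee", r_knee = "right_knee",
  l_ankle = "left_ankle", r_ankle = "right_ankle")

rand_seq <- function(layout, nf = 4, seed = 11) {
  set.seed(seed)
  nj <- length(switch(layout, KINECT25 = kinect25_joints(),
                      MEDIAPIPE33 = mediapipe33_landmarks(),
                      GSI17 = gsi17_keypoints()))
  skeleton_sequence(array(rnorm(nj * 3 * nf), c(nj, 3, nf)),
                    layout = layout)
}

test_that("the 17-keypoint topology is a connected acyclic tree", {
  kp <- gsi17_keypoints()
  ed <- gsi17_edges()
  expect_length(kp, 17)
  expect_equal(nrow(ed), 16)
  expect_true(all(ed %in% kp))
  # connectivity by flood fill; acyclicity follows from n_edges = n_nodes - 1
  reach <- "head"
  repeat {
    nxt <- unique(c(reach, ed[ed[, 1] %in% reach, 2],
                    ed[ed[, 2] %in% reach, 1]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_setequal(reach, kp)
  # no direct left-right limb link
  left <- grepl("^l_", ed)
  dim(left) <- dim(ed)
  right <- grepl("^r_", ed)
  dim(right) <- dim(ed)
  expect_false(any(rowSums(left) > 0 & rowSums(right) > 0))
})

test_that("mapping tables cover every source joint and keypoint exactly once", {
  for (layout in c("KINECT25", "MEDIAPIPE33")) {
    m <- source_mapping(layout)
    produced <- c(names(m$direct), names(m$midpoints))
    expect_setequal(produced, gsi17_keypoints())
    used <- c(unlist(m$direct, use.names = FALSE), m$discarded)
    src <- if (layout == "KINECT25") kinect25_joints()
           else mediapipe33_landmarks()
    expect_setequal(used, src)
    expect_equal(anyDuplicated(used), 0)
  }
})

test_that("Kinect conversion applies the direct-map table with the z flip", {
  s <- rand_seq("KINECT25")
  g <- map_kinect25_to_gsi17(s)
  expect_equal(g$layout, "GSI17")
  kj <- kinect25_joints()
  kp <- gsi17_keypoints()
  flip <- diag(c(1, 1, -1))
  for (nm in names(kinect_direct)) {
    expect_equal(g$frames[match(nm, kp), , ],
                 flip %*% s$frames[match(kinect_direct[[nm]], kj), , ],
                 ignore_attr = TRUE)
  }
  # SpineBase maps to the hip center (z adapted to the camera convention)
  s2 <- rand_seq("KINECT25", nf = 2)
  s2$frames[match("SpineBase", kj), , 1] <- c(1, 2, 3)
  g2 <- map_kinect25_to_gsi17(s2)
  expect_equal(g2$frames[match("hip_center", kp), , 1], c(1, 2, -3))

  z <- skeleton_sequence(array(0, c(25, 3, 2)), layout = "KINECT25")
  expect_true(all(map_kinect25_to_gsi17(z)$frames == 0))
  expect_error(map_kinect25_to_gsi17(rand_seq("MEDIAPIPE33")), "KINECT25")
})

test_that("MediaPipe conversion matches brute-force midpoint evaluation", {
  s <- rand_seq("MEDIAPIPE33", seed = 13)
  g <- map_mediapipe33_to_gsi17(s)
  ml <- mediapipe33_landmarks()
  kp <- gsi17_keypoints()
  at <- function(seq, names_, idx)
    seq$frames[match(names_, if (seq$layout == "GSI17") kp else ml), , idx]
  for (k in seq_len(n_frames(s))) {
    for (nm in names(mp_direct))
      expect_equal(at(g, nm, k), at(s, mp_direct[[nm]], k))
    sc <- (at(s, "left_shoulder", k) + at(s, "right_shoulder", k)) / 2
    hc <- (at(s, "left_hip", k) + at(s, "right_hip", k)) / 2
    expect_equal(at(g, "shoulder_center", k), sc)
    expect_equal(at(g, "hip_center", k), hc)
    expect_equal(at(g, "spine_center", k), (sc + hc) / 2)
    expect_equal(at(g, "neck", k), (at(s, "nose", k) + sc) / 2)
  }
})

test_that("MediaPipe midpoint examples hold", {
  s <- rand_seq("MEDIAPIPE33", nf = 2)
  ml <- mediapipe33_landmarks()
  s$frames[match("left_shoulder", ml), , 1] <- c(0, 2, 0)
  s$frames[match("right_shoulder", ml), , 1] <- c(2, 2, 0)
  s$frames[match("left_hip", ml), , 1] <- c(0, 0, 0)
  s$frames[match("right_hip", ml), , 1] <- c(2, 0, 0)
  g <- map_mediapipe33_to_gsi17(s)
  kp <- gsi17_keypoints()
  expect_equal(g$frames[match("shoulder_center", kp), , 1], c(1, 2, 0))
  expect_equal(g$frames[match("spine_center", kp), , 1], c(1, 1, 0))
})

test_that("conversion is frame-local and commutes with rigid transforms", {
  s <- rand_seq("MEDIAPIPE33", nf = 5, seed = 17)
  g <- map_mediapipe33_to_gsi17(s)
  perm <- c(3, 1, 5, 2, 4)
  s2 <- s
  s2$frames <- s$frames[, , perm]
  s2$conf <- s$conf[, perm]
  g2 <- map_mediapipe33_to_gsi17(s2)
  expect_equal(g2$frames, g$frames[, , perm])

  set.seed(23)
  M <- random_rigid()
  sr <- s
  d <- dim(s$frames)
  P <- M[1:3, 1:3] %*% matrix(aperm(s$frames, c(2, 1, 3)), nrow = 3) +
    M[1:3, 4]
  sr$frames <- aperm(array(P, c(3, d[1], d[3])), c(2, 1, 3))
  gr <- map_mediapipe33_to_gsi17(sr)
  gref <- g
  P2 <- M[1:3, 1:3] %*% matrix(aperm(g$frames, c(2, 1, 3)), nrow = 3) +
    M[1:3, 4]
  gref$frames <- aperm(array(P2, c(3, 17, d[3])), c(2, 1, 3))
  expect_equal(gr$frames, gref$frames, tolerance = 1e-12)
})

test_that("confidence propagates as the minimum through midpoints", {
  s <- rand_seq("MEDIAPIPE33", nf = 2)
  ml <- mediapipe33_landmarks()
  conf <- matrix(1, 33, 2)
  conf[match("left_shoulder", ml), 1] <- 0
  conf[match("right_hip", ml), 2] <- 0.4
  s$conf <- conf
  g <- map_mediapipe33_to_gsi17(s)
  kp <- gsi17_keypoints()
  expect_equal(g$conf[match("shoulder_center", kp), 1], 0)
  expect_equal(g$conf[match("spine_center", kp), 1], 0)
  expect_equal(g$conf[match("neck", kp), 1], 0)
  expect_equal(g$conf[match("hip_center", kp), 2], 0.4)
  # missing keypoints carry the conventional origin coordinates
  expect_equal(g$frames[match("shoulder_center", kp), , 1], c(0, 0, 0))
})
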