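test_that("walking direction comes from the horizontal hip trajectory", {
  fr <- array(0, c(17, 3, 3))
  hi <- match("hip_center", gsi17_keypoints())
  fr[hi, , 1] <- c(0, 1, 0)
  fr[hi, , 2] <- c(1, 1, 0)
  fr[hi, , 3] <- c(2, 1, 0)
  s <- skeleton_sequence(fr)
  expect_equal(estimate_walking_direction(s), c(1, 0, 0))

  # diagonal walk with vertical bounce: bounce must not bias the fit
  nf <- 30
  fr <- array(0, c(17, 3, nf))
  t <- seq_len(nf) - 1
  fr[hi, 1, ] <- t / 10 / sqrt(2)
  fr[hi, 2, ] <- 1 + 0.05 * sin(t)
  fr[hi, 3, ] <- t / 10 / sqrt(2)
  s <- skeleton_sequence(fr)
  expect_equal(estimate_walking_direction(s), c(1, 0, 1) / sqrt(2),
               tolerance = 1e-6)

  # stationary subject
  fr <- array(0, c(17, 3, 5))
  fr[hi, 1, ] <- 0.001 * (1:5)
  expect_error(estimate_walking_direction(skeleton_sequence(fr)),
               "degenerate")
})

test_that("view transform composes as Rz S Ry T and fixes normalized walks", {
  s <- aligned_walk(seed = 5, view = 0)
  vt <- build_view_transform(s)
  expect_equal(vt$M_view,
               gsigait:::rotation_z(vt$theta_z) %*% vt$S %*%
                 gsigait:::rotation_y(vt$theta_y) %*% vt$T)
  expect_lt(max(abs(vt$M_view - diag(4))), 1e-9)
  R <- vt$M_view[1:3, 1:3]
  expect_equal(det(R), if (vt$reflected) -1 else 1, tolerance = 1e-9)
})

test_that("a 90-degree yaw is recovered and undone exactly", {
  s0 <- aligned_walk(seed = 6, view = 0)
  s90 <- apply_view_transform(s0, gsigait:::rotation_y(pi / 2))
  vt <- build_view_transform(s90)
  expect_equal(vt$theta_y, -pi / 2, tolerance = 1e-9)
  expect_false(vt$reflected)
  back <- apply_view_transform(s90, vt)
  expect_equal(back$frames, s0$frames, tolerance = 1e-9)
})

test_that("walking toward -X triggers the reflection and restores +X", {
  s0 <- aligned_walk(seed = 7, view = 0)
  sm <- s0
  sm$frames[, 1, ] <- -sm$frames[, 1, ]
  vt <- build_view_transform(sm)
  expect_true(vt$reflected)
  expect_equal(vt$S, diag(c(-1, 1, 1, 1)))
  out <- apply_view_transform(sm, vt)
  d <- estimate_walking_direction(out)
  expect_gt(d[1], 0.99)
  expect_equal(det(vt$M_view[1:3, 1:3]), -1, tolerance = 1e-9)
})

test_that("apply_view_transform is an isometry for random rigid transforms", {
  s <- walking_seq(seed = 8, duration = 1)
  set.seed(42)
  for (r in seq_len(100)) {
    M <- random_rigid()
    out <- apply_view_transform(s, M)
    k <- sample(n_frames(s), 1)
    expect_lt(max(abs(frame_dists(out, k) - frame_dists(s, k))), 1e-9)
  }
  # identity and pure translation behave elementwise
  expect_equal(apply_view_transform(s, diag(4))$frames, s$frames)
  fr <- array(0, c(17, 3, 2))
  fr[, , 1] <- matrix(c(1, 2, 3), 17, 3, byrow = TRUE)
  st <- skeleton_sequence(fr)
  Tm <- gsigait:::translation_matrix(c(-1, -2, -3))
  expect_true(all(abs(apply_view_transform(st, Tm)$frames[, , 1]) < 1e-12))
})

test_that("translation normalization removes only the horizontal trajectory", {
  s <- walking_seq(seed = 9, view = 0)
  hi <- match("hip_center", gsi17_keypoints())
  fr <- array(rnorm(17 * 3), c(17, 3, 1))[, , rep(1, 10)]
  fr[, 1, ] <- fr[, 1, ] + rep(seq(0, 9), each = 17)  # pure X translation
  sp <- skeleton_sequence(fr)
  out <- normalize_translation(sp)
  for (k in 2:10) expect_equal(out$frames[, , k], out$frames[, , 1])

  n <- normalize_translation(s)
  expect_true(all(abs(n$frames[hi, 1, ]) < 1e-12))
  expect_true(all(abs(n$frames[hi, 3, ]) < 1e-12))
  # Y time series untouched for every joint
  expect_equal(n$frames[, 2, ], s$frames[, 2, ])

  fr2 <- array(0, c(17, 3, 2))
  fr2[hi, , 1] <- c(5, 1, 2)
  fr2[1, , 1] <- c(6, 2, 3)
  out2 <- normalize_translation(skeleton_sequence(fr2))
  expect_equal(out2$frames[hi, , 1], c(0, 1, 0))
  expect_equal(out2$frames[1, , 1], c(1, 2, 1))
})

test_that("canvas fitting scales the box height to 90% and centers it", {
  fr <- array(0, c(17, 3, 2))
  fr[1, , ] <- c(0, 1, 0)   # head at 1 m, everything else at the origin
  s <- skeleton_sequence(fr)
  p <- project_and_fit(s)
  expect_equal(max(p$frames[, 2, 1]) - min(p$frames[, 2, 1]), 108)
  expect_equal(unique(round(p$frames[, 1, 1], 9)), 40)
  # top of the head above the canvas middle after the Y flip
  expect_lt(p$frames[1, 2, 1], 60)

  s2 <- s
  s2$frames <- s$frames * 2
  p2 <- project_and_fit(s2)
  expect_equal(p2$frames, p$frames, tolerance = 1e-12)

  flat <- skeleton_sequence(array(0, c(17, 3, 2)))
  expect_error(project_and_fit(flat), "zero-height")
})

test_that("mirrored walks produce identical projections", {
  s <- walking_seq(seed = 10, view = 0)
  m <- s
  m$frames[, 1, ] <- -m$frames[, 1, ]   # right-to-left version of the walk
  ps <- project_and_fit(normalize_sequence(s))
  pm <- project_and_fit(normalize_sequence(m))
  expect_lt(max(abs(ps$frames - pm$frames)), 1e-6)
})
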