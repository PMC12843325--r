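test_that("rasterization equals the brute-force per-pixel distance test", {
  set.seed(31)
  for (r in seq_len(15)) {
    pts <- random_frame()
    conf <- ifelse(runif(17) < 0.1, 0, 1)
    for (v in c(2, 8, 12)) {
      expect_identical(rasterize_lines(pts, v, conf = conf),
                       oracle_lines(pts, v, conf = conf))
      expect_identical(rasterize_joints(pts, v, conf = conf),
                       oracle_joints(pts, v, conf = conf))
    }
  }
})

test_that("rasterization handles degenerate cases", {
  pts <- matrix(40, 17, 2)
  pts[, 2] <- 60
  # all keypoints coincident: lines give a disc of radius t/2
  img <- rasterize_lines(pts, 8)
  expect_identical(img, oracle_joints(pts[1, , drop = FALSE], 4))
  # coincident keypoints are idempotent under union
  expect_identical(rasterize_joints(pts, 8),
                   oracle_joints(pts[1, , drop = FALSE], 8))
  expect_equal(sum(rasterize_joints(pts[1, , drop = FALSE], 8)),
               sum(abs(outer((1:120) - 60.5, (1:80) - 40.5,
                             function(a, b) a^2 + b^2) <= 64)))
  # invalid joints produce nothing
  expect_true(all(rasterize_lines(random_frame(), 8,
                                  conf = rep(0, 17)) == 0))
  # a far outside keypoint with small radius leaves the canvas empty
  far <- matrix(c(-50, -50), 17, 2, byrow = TRUE)
  expect_true(all(rasterize_joints(far, 2) == 0))
})

test_that("footprints grow monotonically with thickness and radius", {
  set.seed(33)
  for (r in seq_len(10)) {
    pts <- random_frame()
    vals <- c(2, 4, 6, 8, 10, 12)
    lines <- lapply(vals, function(v) rasterize_lines(pts, v))
    joints <- lapply(vals, function(v) rasterize_joints(pts, v))
    for (k in seq_along(vals)[-1]) {
      expect_true(all(lines[[k]] >= lines[[k - 1]]))
      expect_true(all(joints[[k]] >= joints[[k - 1]]))
    }
  }
})

test_that("accumulation is the pixel-wise mean with exact identities", {
  set.seed(35)
  f <- rasterize_joints(random_frame(), 8)
  t1 <- accumulate(list(f, f, f))
  expect_identical(t1$pixels, f)
  t2 <- accumulate(list(f, matrix(0, 120, 80)))
  expect_identical(t2$pixels, f / 2)
  stack <- lapply(1:7, function(i) rasterize_lines(random_frame(), 4))
  acc <- accumulate(stack)
  brute <- matrix(0, 120, 80)
  for (f in stack) brute <- brute + f
  expect_equal(acc$pixels, brute / 7, tolerance = 1e-12)
  expect_error(accumulate(list()), "no frames")
  # max accumulation equals the union mask of binary frames
  expect_identical(accumulate(stack, method = "max")$pixels,
                   (brute > 0) * 1)
})

test_that("template support is bounded by the union of frame supports", {
  set.seed(36)
  stack <- lapply(1:5, function(i) rasterize_joints(random_frame(), 6))
  acc <- accumulate(stack)
  union <- Reduce(pmax, stack)
  expect_identical((acc$pixels > 0) * 1, union)
})

test_that("the full pipeline is deterministic with plausible support", {
  s <- walking_seq(seed = 21, view = 36, noise = 0.005)
  cfg <- gsi_config("joints", 8)
  t1 <- compute_gsi(s, cfg)
  t2 <- compute_gsi(s, cfg)
  expect_identical(t1$pixels, t2$pixels)
  frac <- mean(t1$pixels > 0)
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.9)
  expect_true(all(t1$pixels >= 0 & t1$pixels <= 1))
})

test_that("templates are invariant to the viewing angle without noise", {
  base <- compute_gsi(walking_seq(seed = 22, view = 0, noise = 0),
                      gsi_config("joints", 8))
  for (v in c(36, 72, 90)) {
    tv <- compute_gsi(walking_seq(seed = 22, view = v, noise = 0),
                      gsi_config("joints", 8))
    expect_lte(mean(abs(tv$pixels - base$pixels)), 0.02)
  }
})

test_that("per-cycle templates cover the same cycles as the default", {
  s <- walking_seq(seed = 23, view = 0, noise = 0)
  cfgs <- gsi_config("lines", 8, per_cycle = TRUE)
  tpl <- compute_gsi(s, cfgs)
  expect_true(is.list(tpl) && length(tpl) >= 1)
  for (t in tpl) expect_s3_class(t, "gait_template")
})

test_that("the GEI is the mean of aligned silhouettes", {
  s <- walking_seq(seed = 24, view = 0, noise = 0, duration = 2)
  sil <- simulate_silhouettes(s, body_width = 0.12)
  g <- compute_gei(sil)
  expect_s3_class(g, "gait_template")
  expect_equal(g$variant, "gei")
  # constant stack: GEI equals the aligned frame
  one <- silhouette_stack(sil$frames[rep(1, 5)], fps = 30)
  gone <- compute_gei(one)
  gsingle <- compute_gei(silhouette_stack(sil$frames[1], fps = 30))
  expect_identical(gone$pixels, gsingle$pixels)
  expect_true(all(gone$pixels %in% c(0, 1)))
  # brute-force mean over the aligned frames
  aligned <- lapply(sil$frames, gsigait:::align_silhouette,
                    canvas_w = 80L, canvas_h = 120L, margin = 0.9)
  brute <- Reduce(`+`, aligned) / length(aligned)
  expect_equal(g$pixels, brute, tolerance = 1e-12)
  expect_error(compute_gei(structure(list(frames = list()),
                                     class = "silhouette_stack")),
               "empty")
})

test_that("silhouettes contain the skeleton line rendering", {
  s <- walking_seq(seed = 25, view = 0, noise = 0, duration = 1)
  sil <- simulate_silhouettes(s, body_width = 0.1)
  thin <- simulate_silhouettes(s, body_width = 0)
  for (k in c(1, 10)) expect_true(all(sil$frames[[k]] >= thin$frames[[k]]))
  # zero body width degenerates to 1-px lines on the same projection
  proj <- project_and_fit(normalize_sequence(s))
  expect_identical(thin$frames[[1]],
                   rasterize_lines(proj$frames[, , 1], 1,
                                   conf = proj$conf[, 1]))
})

test_that("the parameter sweep grows support and matches the default", {
  s <- walking_seq(seed = 26, view = 0, noise = 0, duration = 2)
  sw <- sweep_params(s, c(2, 8))
  expect_named(sw, c("2", "8"))
  f2 <- mean(sw[["2"]][[1]]$pixels > 0)
  f8 <- mean(sw[["8"]][[1]]$pixels > 0)
  expect_gt(f8, f2)
  expect_identical(sweep_params(s, 8)[["8"]][[1]]$pixels,
                   compute_gsi(s, gsi_config("joints", 8))$pixels)
  expect_error(sweep_params(s, integer(0)), "empty")
})
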