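test_that("noise-free simulation keeps bone lengths constant and advances", {
  s <- walking_seq(seed = 41, view = 0, noise = 0)
  kp <- gsi17_keypoints()
  ed <- gsi17_edges()
  for (e in seq_len(nrow(ed))) {
    a <- match(ed[e, 1], kp); b <- match(ed[e, 2], kp)
    lens <- sqrt(colSums((s$frames[a, , ] - s$frames[b, , ])^2))
    expect_lt(max(lens) - min(lens), 1e-9)
  }
  hip_x <- s$frames[match("hip_center", kp), 1, ]
  expect_true(all(diff(hip_x) > 0))
})

test_that("legs and arms are symmetric up to a half-stride phase shift", {
  p <- draw_gait_params(2, "S001")
  p$cadence <- 1.0
  s <- simulate_sequence(p, covariate_spec("NM", 0), duration = 4, fps = 30,
                         noise_sigma = 0, seed = 1)
  kp <- gsi17_keypoints()
  half <- 15                       # half a stride at 1 Hz / 30 fps
  nf <- n_frames(s)
  la <- s$frames[match("l_ankle", kp), 2, ]
  ra <- s$frames[match("r_ankle", kp), 2, ]
  expect_equal(la[seq_len(nf - half)], ra[(half + 1):nf], tolerance = 1e-6)
})

test_that("simulation is deterministic in its seed", {
  p <- draw_gait_params(3, "S002")
  a <- simulate_sequence(p, covariate_spec("BG", 45), seed = 7)
  b <- simulate_sequence(p, covariate_spec("BG", 45), seed = 7)
  expect_identical(a$frames, b$frames)
  c <- simulate_sequence(p, covariate_spec("BG", 45), seed = 8)
  expect_false(identical(a$frames, c$frames))
})

test_that("the ankle-separation period matches the commanded cadence", {
  s <- walking_seq(seed = 44, view = 0, noise = 0, cadence = 1.0)
  kp <- gsi17_keypoints()
  sep <- s$frames[match("l_ankle", kp), 1, ] -
    s$frames[match("r_ankle", kp), 1, ]
  # signed separation has the stride period: locate zero upcrossings
  ups <- which(sep[-1] > 0 & sep[-length(sep)] <= 0)
  expect_true(all(abs(diff(ups) - 30) <= 1))
})

test_that("covariates perturb the kinematics as specified", {
  p <- draw_gait_params(5, "S004")
  nm <- simulate_sequence(p, covariate_spec("NM", 0), noise_sigma = 0,
                          seed = 1)
  bg <- simulate_sequence(p, covariate_spec("BG", 0), noise_sigma = 0,
                          seed = 1)
  kp <- gsi17_keypoints()
  swing <- function(s, joint)
    diff(range(s$frames[match(joint, kp), 1, ] -
                 s$frames[match(ifelse(grepl("^l", joint), "l_shoulder",
                                       "r_shoulder"), kp), 1, ]))
  # the carried bag suppresses swing on the carrying side only
  expect_lt(swing(bg, "r_wrist"), 0.5 * swing(nm, "r_wrist"))
  expect_equal(swing(bg, "l_wrist"), swing(nm, "l_wrist"), tolerance = 1e-9)

  cl <- simulate_sequence(p, covariate_spec("CL", 0), noise_sigma = 0,
                          seed = 1)
  expect_false(identical(cl$frames, nm$frames))
})

test_that("Kinect-layout emission round-trips through the converter", {
  p <- draw_gait_params(6, "S005")
  g <- simulate_sequence(p, covariate_spec("NM", 30), noise_sigma = 0.003,
                         seed = 2, layout = "GSI17")
  k <- simulate_sequence(p, covariate_spec("NM", 30), noise_sigma = 0.003,
                         seed = 2, layout = "KINECT25")
  expect_equal(k$layout, "KINECT25")
  back <- map_kinect25_to_gsi17(k)
  expect_equal(back$frames, g$frames, tolerance = 1e-12)
})

test_that("cohorts are deterministic with separable per-subject parameters", {
  m1 <- make_cohort(10, 10, views = 90, covariates = "NM", seed = 1,
                    duration = 1)
  expect_equal(nrow(m1), 100)
  expect_equal(length(unique(m1$subject)), 10)
  m2 <- make_cohort(10, 10, views = 90, covariates = "NM", seed = 1,
                    duration = 1)
  expect_identical(m1$subject, m2$subject)
  expect_identical(m1$sequence[[37]]$frames, m2$sequence[[37]]$frames)
  expect_error(make_cohort(1, 5), "2 subjects")

  # kinematic parameters differ across subjects but not across trials
  pars <- t(sapply(sprintf("S%03d", 1:10), function(id)
    unlist(draw_gait_params(1, id))))
  inter <- as.matrix(dist(pars))
  expect_gt(min(inter[upper.tri(inter)]), 0.01)
})

test_that("cohorts round-trip through the on-disk manifest format", {
  dir <- withr::local_tempdir()
  m <- make_cohort(2, 2, views = c(0, 90), seed = 9, duration = 1,
                   dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(m$file)))
  r <- read_sequence(m$file[[3]])
  expect_identical(r$frames, m$sequence[[3]]$frames)
})

test_that("parameter validation enforces the documented ranges", {
  expect_error(gait_params(thigh = 0.05), "0.1, 0.8")
  expect_error(gait_params(cadence = 1.5), "0.6, 1.4")
  expect_error(gait_params(bounce = -0.1), ">= 0")
  expect_error(covariate_spec("NM", 400), "360")
  expect_error(simulate_sequence(draw_gait_params(1, "a"),
                                 duration = 0.01, fps = 30),
               "at least 2")
})
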